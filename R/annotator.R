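# fixed local-alignment scoring: match +2, mismatch -1, gap open -4, extend -1
.submat <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                     baseOnly = TRUE)
    m
  }
})

#' Locally align a query to a germline segment
#'
#' Deterministic optimal local (Smith-Waterman) alignment under the package's
#' fixed scoring: match +2, mismatch -1, gap open -4, gap extend -1 (a gap of
#' length k costs 4 + k). A best score <= 0 is reported as a no-hit.
#'
#' @param query rearranged nucleotide sequence (character or DNAString).
#' @param segment germline segment sequence (character or DNAString).
#' @return list with `score`, `no_hit`, and the 0-based half-open aligned
#'   intervals `segment_range` and `query_range`.
#' @export
alignToGermline <- function(query, segment) {
  query <- as.character(query); segment <- as.character(segment)
  if (!nchar(query) || !nchar(segment)) stop("empty input sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(segment), Biostrings::DNAString(query),
    type = "local", substitutionMatrix = .submat(),
    gapOpening = 4, gapExtension = 1)
  sc <- Biostrings::score(aln)
  pr <- IRanges::ranges(Biostrings::pattern(aln))
  sr <- IRanges::ranges(Biostrings::subject(aln))
  list(score = sc, no_hit = sc <= 0,
       segment_range = c(start = IRanges::start(pr) - 1L, end = IRanges::end(pr)),
       query_range = c(start = IRanges::start(sr) - 1L, end = IRanges::end(sr)))
}

# per-column view of one gapped pairwise alignment, 0-based positions; gap
# columns dropped. pstart/sstart are 0-based starts of the aligned regions;
# subjOffset shifts query coordinates into the full-sequence frame.
.alignmentColumns <- function(patStr, subjStr, pstart, sstart,
                              subjOffset = 0L) {
  p <- strsplit(patStr, "")[[1]]
  s <- strsplit(subjStr, "")[[1]]
  ppos <- pstart + cumsum(p != "-") - 1L
  spos <- sstart + cumsum(s != "-") - 1L
  keep <- p != "-" & s != "-"
  data.frame(germ_pos = ppos[keep],
             query_pos = spos[keep] + subjOffset,
             germ_base = p[keep], query_base = s[keep],
             stringsAsFactors = FALSE)
}

# Trim a junction-facing alignment end ("right" = V 3', "left" = J 5') back
# so the terminal 4 columns are all matches; stops once <= 4 columns remain.
.trimJunctionEnd <- function(cols, end = c("right", "left")) {
  end <- match.arg(end)
  mm <- cols$germ_base != cols$query_base
  if (end == "right") {
    while (nrow(cols) > 4 && any(utils::tail(mm, 4))) {
      cut <- max(which(utils::tail(mm, 4))) + nrow(cols) - 4L
      cols <- cols[seq_len(cut - 1L), , drop = FALSE]
      mm <- mm[seq_len(cut - 1L)]
    }
  } else {
    while (nrow(cols) > 4 && any(mm[1:4])) {
      cut <- max(which(mm[1:4]))
      cols <- cols[-seq_len(cut), , drop = FALSE]
      mm <- mm[-seq_len(cut)]
    }
  }
  cols
}

# best segment of one class by (score, genomic rank, name); returns index
# into `names` plus scores, or NA if all no-hit
.bestByScore <- function(scores, names, ranks) {
  ord <- order(-scores, ranks, names)
  ord[1]
}

# longest exact common substring of `window` in any D segment; simple DP,
# both strings are short. Returns run length and 0-based starts.
.longestRun <- function(window, dseq) {
  n <- nchar(window); m <- nchar(dseq)
  if (n == 0 || m == 0) return(list(len = 0L))
  a <- strsplit(window, "")[[1]]; b <- strsplit(dseq, "")[[1]]
  best <- 0L; bw <- 0L; bd <- 0L
  prev <- integer(m)
  for (i in seq_len(n)) {
    cur <- integer(m)
    match <- a[i] == b
    cur[match] <- c(0L, prev)[seq_len(m)][match] + 1L
    mx <- max(cur)
    if (mx > best) {
      best <- mx
      j <- which.max(cur)
      bw <- i - mx; bd <- j - mx
    }
    prev <- cur
  }
  list(len = best, window_start = bw, d_start = bd)
}

#' Assign germline V, D and J segments to a rearranged sequence
#'
#' V is the highest-scoring local alignment over all germline V segments; J is
#' the highest-scoring J constrained strictly downstream of the V match end; D
#' is searched only inside the inter-segment window and requires at least
#' `dMinMatch` consecutive exact matches, otherwise it is reported
#' `"unassigned"`. Ties are broken by higher score, then lower genomic rank,
#' then lexicographic name. Queries whose best V or J score falls below
#' `minScore` are annotation failures (`failed = TRUE` with a reason), which
#' callers record rather than abort on.
#'
#' @param query rearranged nucleotide sequence.
#' @param reference a [GermlineReference].
#' @param minScore minimum acceptable V and J alignment score.
#' @param dMinMatch minimum exact-match run for a D call.
#' @return list with `v_call`, `d_call`, `j_call`, `v_score`, `j_score`,
#'   `d_match_len`, 0-based half-open `*_germ_range`/`*_query_range`
#'   coordinates, per-column tables `v_cols`/`j_cols`, and
#'   `failed`/`fail_reason`.
#' @details The junction-facing alignment ends (V 3', J 5') are trimmed back
#'   so they terminate in a run of 4 consecutive matches: a locally optimal
#'   alignment otherwise chance-extends a trimmed germline end across
#'   non-templated junction bases, which would both misplace the junction and
#'   manufacture spurious mutation calls there.
#' @export
assignSegments <- function(query, reference, minScore = 40, dMinMatch = 5) {
  query <- as.character(query)
  if (!nchar(query)) stop("empty query sequence")
  info <- segmentInfo(reference)
  qDNA <- Biostrings::DNAString(query)
  failed <- function(reason)
    list(v_call = NA_character_, d_call = NA_character_,
         j_call = NA_character_, failed = TRUE, fail_reason = reason)

  alignClass <- function(cl, subj, offset) {
    nms <- segmentNames(reference, cl)
    alns <- Biostrings::pairwiseAlignment(
      segmentSeq(reference, nms), subj, type = "local",
      substitutionMatrix = .submat(), gapOpening = 4, gapExtension = 1)
    scores <- Biostrings::score(alns)
    i <- .bestByScore(scores, nms, genomicRank(reference, nms))
    pat <- Biostrings::pattern(alns)
    sub <- Biostrings::subject(alns)
    cols <- .alignmentColumns(as.character(pat)[i], as.character(sub)[i],
                              IRanges::start(pat)[i] - 1L,
                              IRanges::start(sub)[i] - 1L, subjOffset = offset)
    cols <- .trimJunctionEnd(cols, end = if (cl == "V") "right" else "left")
    list(name = nms[i], score = scores[i], cols = cols,
         germ_range = c(cols$germ_pos[1], cols$germ_pos[nrow(cols)] + 1L),
         query_range = c(cols$query_pos[1], cols$query_pos[nrow(cols)] + 1L))
  }

  v <- alignClass("V", qDNA, 0L)
  if (v$score < minScore) return(failed("no V above minimum score"))
  if (v$query_range[2] >= nchar(query))
    return(failed("no sequence downstream of V for J"))
  downstream <- Biostrings::subseq(qDNA, v$query_range[2] + 1L)
  j <- alignClass("J", downstream, v$query_range[2])
  if (j$score < minScore) return(failed("no J above minimum score"))

  window <- substr(query, v$query_range[2] + 1L, j$query_range[1])
  dn <- segmentNames(reference, "D")
  runs <- lapply(as.character(segmentSeq(reference, dn)), .longestRun,
                 window = window)
  lens <- vapply(runs, function(r) r$len, 0L)
  dCall <- "unassigned"; dLen <- 0L
  dGermRange <- c(NA_integer_, NA_integer_)
  dQueryRange <- c(NA_integer_, NA_integer_)
  if (any(lens >= dMinMatch)) {
    i <- .bestByScore(lens, dn, genomicRank(reference, dn))
    dCall <- dn[i]; dLen <- lens[i]
    dGermRange <- c(runs[[i]]$d_start, runs[[i]]$d_start + dLen)
    dQueryRange <- c(v$query_range[2] + runs[[i]]$window_start,
                     v$query_range[2] + runs[[i]]$window_start + dLen)
  }
  list(v_call = v$name, d_call = dCall, j_call = j$name,
       v_score = v$score, j_score = j$score, d_match_len = dLen,
       v_germ_range = unname(v$germ_range), v_query_range = unname(v$query_range),
       j_germ_range = unname(j$germ_range), j_query_range = unname(j$query_range),
       d_germ_range = unname(dGermRange), d_query_range = unname(dQueryRange),
       v_cols = v$cols, j_cols = j$cols,
       failed = FALSE, fail_reason = "none")
}

#' Extract the N-region strings between assigned segments
#'
#' `n1` is the query sequence strictly between the V match end and the D match
#' start; `n2` between the D match end and the J match start. When D is
#' unassigned the whole V-to-J insert is reported as `n1` with `n2` empty.
#' Overlapping matches yield empty junctions with `overlap = TRUE`.
#'
#' @param query the rearranged sequence.
#' @param boundaries result of [assignSegments()].
#' @return list with `n1`, `n2` and `overlap`.
#' @export
delineateJunctions <- function(query, boundaries) {
  query <- as.character(query)
  b <- boundaries
  vEnd <- b$v_query_range[2]; jStart <- b$j_query_range[1]
  if (jStart < vEnd) return(list(n1 = "", n2 = "", overlap = TRUE))
  if (b$d_call == "unassigned" || is.na(b$d_query_range[1]))
    return(list(n1 = substr(query, vEnd + 1, jStart), n2 = "",
                overlap = FALSE))
  dStart <- b$d_query_range[1]; dEnd <- b$d_query_range[2]
  if (dStart < vEnd || jStart < dEnd)
    return(list(n1 = "", n2 = "", overlap = TRUE))
  list(n1 = substr(query, vEnd + 1, dStart),
       n2 = substr(query, dEnd + 1, jStart), overlap = FALSE)
}

#' Classify the productivity of an annotated rearrangement
#'
#' A rearrangement is `out_of_frame` when the conserved J Trp codon does not
#' fall in the V reading frame (junction length not a multiple of 3),
#' `stop_codon` when any in-frame stop lies between the V FR2 start and the J
#' end, `no_j_anchor` when the J alignment does not cover the conserved Trp
#' codon, and productive otherwise.
#'
#' @param query the rearranged sequence.
#' @param boundaries result of [assignSegments()].
#' @param reference a [GermlineReference].
#' @return list with `productive` (logical) and `nonfunctional_reason`
#'   (`"none"`, `"stop_codon"`, `"out_of_frame"` or `"no_j_anchor"`).
#' @export
classifyProductivity <- function(query, boundaries, reference) {
  query <- as.character(query)
  b <- boundaries
  info <- segmentInfo(reference)
  jAnchor <- info$j_trp_anchor[info$name == b$j_call]
  trpQ <- .queryPosOf(b$j_cols, jAnchor)
  if (is.na(trpQ) || trpQ < 0 || trpQ + 3 > nchar(query))
    return(list(productive = FALSE, nonfunctional_reason = "no_j_anchor"))
  # query position carrying germline V position 0, from the modal aligned
  # offset (robust to an occasional gap column)
  offsetV <- .modalOffset(b$v_cols)
  if ((trpQ - offsetV) %% 3 != 0)
    return(list(productive = FALSE, nonfunctional_reason = "out_of_frame"))
  fr2 <- info$fr2_start[info$name == b$v_call]
  from <- offsetV + fr2
  if (from + 3 <= b$j_query_range[2]) {
    starts <- seq(from + 1, b$j_query_range[2] - 2, by = 3)
    if (any(substring(query, starts, starts + 2) %in% .STOPS))
      return(list(productive = FALSE, nonfunctional_reason = "stop_codon"))
  }
  list(productive = TRUE, nonfunctional_reason = "none")
}

#' Call somatic mutations against the assigned germline
#'
#' Reports mismatches within germline-aligned columns -- N-region bases are
#' never counted -- over the FR2-to-J window the assay amplifies: V columns
#' from the FR2 start, the exact-matched D columns (mismatch-free by
#' construction) and all J columns. Each mutation carries its 0-based query
#' and germline coordinates, the region label (FR2/CDR2/FR3/CDR3/FR4) and
#' whether its germline position lies in an RGYW/WRCY hotspot window. The
#' mutation frequency is mismatches / aligned germline columns x 100;
#' sequences at or above `mutatedThreshold` percent are flagged mutated.
#'
#' @param query the rearranged sequence.
#' @param boundaries result of [assignSegments()].
#' @param reference a [GermlineReference].
#' @param hotspotConvention `"any_position"` (default) or `"aid_target"`; see
#'   [scanHotspots()].
#' @param mutatedThreshold percent threshold for `mutated_status`.
#' @return list with `mutations` (data.frame: `query_pos`, `germ_pos`,
#'   `segment`, `region`, `germline_base`, `observed_base`, `in_hotspot`),
#'   `aligned_cols`, `mutation_frequency` (percent), `mutated_status`,
#'   `cdr_len` and `fr_len` (aligned column counts per region class).
#' @export
callMutations <- function(query, boundaries, reference,
                          hotspotConvention = "any_position",
                          mutatedThreshold = 2.0) {
  b <- boundaries
  info <- segmentInfo(reference)
  fr2 <- info$fr2_start[info$name == b$v_call]
  jAnchor <- info$j_trp_anchor[info$name == b$j_call]

  vCols <- b$v_cols[b$v_cols$germ_pos >= fr2, , drop = FALSE]
  vCols$region <- vRegionLabels(reference, b$v_call)[vCols$germ_pos + 1L]
  vCols$segment <- b$v_call

  jCols <- b$j_cols
  jCols$region <- ifelse(jCols$germ_pos < jAnchor, "CDR3", "FR4")
  jCols$segment <- b$j_call

  cols <- rbind(vCols, jCols)
  dLen <- if (b$d_call != "unassigned") b$d_match_len else 0L

  mism <- cols[cols$germ_base != cols$query_base, , drop = FALSE]
  alignedCols <- nrow(cols) + dLen
  freq <- if (alignedCols > 0) nrow(mism) / alignedCols * 100 else NA_real_

  inHot <- logical(nrow(mism))
  if (nrow(mism)) {
    for (seg in unique(mism$segment)) {
      mask <- scanHotspots(as.character(segmentSeq(reference, seg))[[1]],
                           convention = hotspotConvention)
      sel <- mism$segment == seg
      inHot[sel] <- mask[mism$germ_pos[sel] + 1L]
    }
  }
  mutations <- data.frame(
    query_pos = mism$query_pos, germ_pos = mism$germ_pos,
    segment = mism$segment, region = mism$region,
    germline_base = mism$germ_base, observed_base = mism$query_base,
    in_hotspot = inHot, stringsAsFactors = FALSE)
  mutations <- mutations[order(mutations$query_pos), , drop = FALSE]
  rownames(mutations) <- NULL

  cdrLen <- sum(cols$region %in% c("CDR2", "CDR3")) + dLen
  frLen <- sum(cols$region %in% c("FR2", "FR3", "FR4"))
  list(mutations = mutations, aligned_cols = alignedCols,
       mutation_frequency = freq,
       mutated_status = !is.na(freq) && freq >= mutatedThreshold,
       cdr_len = cdrLen, fr_len = frLen)
}

# map a germline position to its query position through the column table,
# extrapolating from the nearest aligned column when it is not itself aligned
.queryPosOf <- function(cols, germPos) {
  if (is.na(germPos) || nrow(cols) == 0) return(NA_integer_)
  i <- which(cols$germ_pos == germPos)
  if (length(i)) return(cols$query_pos[i[1]])
  k <- which.min(abs(cols$germ_pos - germPos))
  cols$query_pos[k] + (germPos - cols$germ_pos[k])
}

# modal (query_pos - germ_pos) offset over the aligned columns
.modalOffset <- function(cols) {
  off <- cols$query_pos - cols$germ_pos
  as.integer(names(which.max(table(off))))
}

# CDR3 delineation (IMGT: codon after the conserved Cys up to the codon
# before the conserved J Trp, anchors excluded)
.delineateCdr3 <- function(query, boundaries, reference, productive) {
  b <- boundaries
  info <- segmentInfo(reference)
  cys <- info$cdr3_anchor[info$name == b$v_call]
  jAnchor <- info$j_trp_anchor[info$name == b$j_call]
  start <- .queryPosOf(b$v_cols, cys) + 3L
  trpQ <- .queryPosOf(b$j_cols, jAnchor)
  if (is.na(start) || is.na(trpQ) || start > trpQ || trpQ + 3 > nchar(query))
    return(list(cdr3_nt = NA_character_, cdr3_aa = NA_character_,
                junction = NA_character_))
  nt <- substr(query, start + 1L, trpQ)
  junction <- substr(query, start - 3L + 1L, trpQ + 3L)
  aa <- if (productive && nchar(nt) %% 3 == 0 && nchar(nt) > 0)
    as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  else NA_character_
  list(cdr3_nt = nt, cdr3_aa = aa, junction = junction)
}

#' Annotate a single rearranged sequence
#'
#' Runs the full annotation for one query: segment assignment, junction
#' delineation, CDR3 extraction, productivity classification and mutation
#' calling. See the individual operations for conventions.
#'
#' @inheritParams assignSegments
#' @inheritParams callMutations
#' @return a one-element list of annotation fields (see
#'   [annotateRepertoire()] for the tabular layout).
#' @export
annotateSequence <- function(query, reference, minScore = 40, dMinMatch = 5,
                             hotspotConvention = "any_position",
                             mutatedThreshold = 2.0) {
  query <- as.character(query)
  b <- assignSegments(query, reference, minScore, dMinMatch)
  if (b$failed)
    return(list(v_call = NA_character_, d_call = NA_character_,
                j_call = NA_character_, v_score = NA_real_, j_score = NA_real_,
                n1_seq = NA_character_, n2_seq = NA_character_,
                junction = NA_character_, cdr3_nt = NA_character_,
                cdr3_aa = NA_character_, productive = FALSE,
                nonfunctional_reason = "annotation_failed",
                fail_reason = b$fail_reason,
                mutation_frequency = NA_real_, mutated_status = NA,
                aligned_cols = NA_integer_, cdr_len = NA_integer_,
                fr_len = NA_integer_,
                mutations = list(NULL)))
  jn <- delineateJunctions(query, b)
  prod <- classifyProductivity(query, b, reference)
  cdr3 <- .delineateCdr3(query, b, reference, prod$productive)
  mut <- callMutations(query, b, reference, hotspotConvention,
                       mutatedThreshold)
  list(v_call = b$v_call, d_call = b$d_call, j_call = b$j_call,
       v_score = b$v_score, j_score = b$j_score,
       n1_seq = jn$n1, n2_seq = jn$n2, junction = cdr3$junction,
       cdr3_nt = cdr3$cdr3_nt, cdr3_aa = cdr3$cdr3_aa,
       productive = prod$productive,
       nonfunctional_reason = prod$nonfunctional_reason,
       fail_reason = "none",
       mutation_frequency = mut$mutation_frequency,
       mutated_status = mut$mutated_status,
       aligned_cols = mut$aligned_cols, cdr_len = mut$cdr_len,
       fr_len = mut$fr_len, mutations = list(mut$mutations))
}

#' Annotate a set of rearranged sequences
#'
#' Vectorized driver over [annotateSequence()]. Sequence ids of the form
#' `"<donor>-<cell>_col<k>"` (as emitted by [simulateRepertoire()]) are parsed
#' into `donor_id`/`cell_id`; other ids leave those columns `NA`. Per-sequence
#' annotation failures are recorded in `nonfunctional_reason`/`fail_reason`
#' and do not abort the run.
#'
#' @param sequences a named [Biostrings::DNAStringSet] or named character
#'   vector of rearranged sequences.
#' @inheritParams assignSegments
#' @inheritParams callMutations
#' @return a [S4Vectors::DataFrame] with one row per input sequence: calls,
#'   scores, junction strings, CDR3, productivity, mutation summary columns
#'   and a `mutations` list-column of per-sequence mutation data.frames.
#' @export
annotateRepertoire <- function(sequences, reference, minScore = 40,
                               dMinMatch = 5,
                               hotspotConvention = "any_position",
                               mutatedThreshold = 2.0) {
  seqs <- as.character(sequences)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (length(seqs) == 0) {
    out <- S4Vectors::DataFrame(
      sequence_id = character(), donor_id = character(),
      cell_id = character(), v_call = character(), d_call = character(),
      j_call = character(), v_score = numeric(), j_score = numeric(),
      n1_seq = character(), n2_seq = character(), junction = character(),
      cdr3_nt = character(), cdr3_aa = character(), productive = logical(),
      nonfunctional_reason = character(), mutation_frequency = numeric(),
      mutated_status = logical(), aligned_cols = integer(),
      cdr_len = integer(), fr_len = integer())
    out$mutations <- list()
    return(out)
  }
  anns <- lapply(seqs, annotateSequence, reference = reference,
                 minScore = minScore, dMinMatch = dMinMatch,
                 hotspotConvention = hotspotConvention,
                 mutatedThreshold = mutatedThreshold)
  field <- function(nm, cast) unname(vapply(anns, function(a) {
    v <- a[[nm]]
    if (is.null(v) || length(v) != 1) cast(NA) else cast(v)
  }, cast(NA)))
  m <- regmatches(ids, regexec("^([^-]+)-([^_]+)_col[0-9]+$", ids))
  donor <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_, "")
  cell <- vapply(m, function(x) if (length(x) == 3)
    paste0(x[2], "-", x[3]) else NA_character_, "")
  out <- S4Vectors::DataFrame(
    sequence_id = ids, donor_id = donor, cell_id = cell,
    v_call = field("v_call", as.character),
    d_call = field("d_call", as.character),
    j_call = field("j_call", as.character),
    v_score = field("v_score", as.numeric),
    j_score = field("j_score", as.numeric),
    n1_seq = field("n1_seq", as.character),
    n2_seq = field("n2_seq", as.character),
    junction = field("junction", as.character),
    cdr3_nt = field("cdr3_nt", as.character),
    cdr3_aa = field("cdr3_aa", as.character),
    productive = field("productive", as.logical),
    nonfunctional_reason = field("nonfunctional_reason", as.character),
    mutation_frequency = field("mutation_frequency", as.numeric),
    mutated_status = field("mutated_status", as.logical),
    aligned_cols = field("aligned_cols", as.integer),
    cdr_len = field("cdr_len", as.integer),
    fr_len = field("fr_len", as.integer))
  out$mutations <- lapply(anns, function(a) a$mutations[[1]])
  rownames(out) <- NULL
  out
}

#' Collapse colony sequences of one cell into distinct rearrangement patterns
#'
#' Colony sequences from the same cell that share the pattern key
#' `(v_call, d_call, j_call, n1_seq, n2_seq)` are one rearrangement pattern;
#' differences due only to somatic hypermutation do not split a pattern.
#' Colonies that failed annotation are dropped; a cell with no annotated
#' colonies yields no rows (counted Ig-negative upstream).
#'
#' @param annotations rows of an [annotateRepertoire()] result belonging to
#'   one cell (or several cells; grouping uses `cell_id`).
#' @return data.frame with one row per distinct pattern per cell: `donor_id`,
#'   `cell_id`, the key columns and `n_colonies`.
#' @export
dedupeCellPatterns <- function(annotations) {
  df <- as.data.frame(annotations[, c("donor_id", "cell_id", "v_call",
                                      "d_call", "j_call", "n1_seq", "n2_seq")])
  df <- df[!is.na(df$v_call) & !is.na(df$j_call), , drop = FALSE]
  if (nrow(df) == 0)
    return(data.frame(donor_id = character(), cell_id = character(),
                      v_call = character(), d_call = character(),
                      j_call = character(), n1_seq = character(),
                      n2_seq = character(), n_colonies = integer(),
                      stringsAsFactors = FALSE))
  key <- paste(df$cell_id, df$v_call, df$d_call, df$j_call, df$n1_seq,
               df$n2_seq, sep = "|")
  agg <- df[!duplicated(key), , drop = FALSE]
  agg$n_colonies <- as.integer(table(key)[key[!duplicated(key)]])
  agg <- agg[order(agg$cell_id, agg$v_call, agg$d_call, agg$j_call,
                   agg$n1_seq, agg$n2_seq), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
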
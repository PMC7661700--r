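.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

.randNt <- function(n) {
  if (n == 0) return("")
  paste0(sample(.BASES, n, replace = TRUE), collapse = "")
}

# uniform integer draw on [lo, hi], immune to sample()'s scalar surprise
.runifInt <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# Usage presets. The "ptec-like" preset encodes the heavily VH1-biased,
# 3'-concentrated usage reported for proximal tubular epithelial cells
# (VH1 71% with IGHV1-24/1-18/1-69 at 16.8/15.4/11.8%, VH5/VH6 absent,
# DH2-15 and JH4 favoured); "bcell-like" encodes diverse B-cell usage
# (VH3 47.5%, VH4 21.2%, IGHV3-30/3-23/4-39 at 7.1/6.7/6.6%).
.usagePreset <- function(reference, preset) {
  info <- segmentInfo(reference)
  vn <- segmentNames(reference, "V")
  dn <- segmentNames(reference, "D")
  jn <- segmentNames(reference, "J")
  vfam <- familyOf(vn)
  spread <- function(w, names, total) {
    extra <- setdiff(names, names(w))
    if (length(extra)) w <- c(w, setNames(rep(total / length(extra), length(extra)), extra))
    w
  }
  if (preset == "ptec-like") {
    v <- c("IGHV1-24" = 16.8, "IGHV1-18" = 15.4, "IGHV1-69" = 11.8,
           "IGHV1-2" = 9, "IGHV1-3" = 8, "IGHV1-8" = 6,
           "IGHV1-45" = 2, "IGHV1-46" = 2)
    v <- spread(v, vn[vfam == "VH3"], 15)
    v <- spread(v, vn[vfam == "VH4"], 9)
    v <- spread(v, vn[vfam == "VH2"], 3)
    v <- spread(v, vn[vfam == "VH7"], 2)
    v <- c(v, setNames(rep(0, sum(vfam %in% c("VH5", "VH6"))),
                       vn[vfam %in% c("VH5", "VH6")]))
    d <- setNames(rep(0.80 / (length(dn) - 1), length(dn)), dn)
    d["IGHD2-15"] <- 0.20
    j <- c(IGHJ1 = 0.05, IGHJ2 = 0.08, IGHJ3 = 0.10, IGHJ4 = 0.45,
           IGHJ5 = 0.12, IGHJ6 = 0.20)
  } else {
    v <- c("IGHV3-30" = 7.1, "IGHV3-23" = 6.7, "IGHV4-39" = 6.6)
    v <- spread(v, setdiff(vn[vfam == "VH3"], names(v)), 47.5 - 7.1 - 6.7)
    v <- spread(v, setdiff(vn[vfam == "VH4"], names(v)), 21.2 - 6.6)
    v <- spread(v, vn[vfam == "VH1"], 12)
    v <- spread(v, vn[vfam == "VH2"], 6)
    v <- spread(v, vn[vfam == "VH5"], 5)
    v <- spread(v, vn[vfam == "VH6"], 4)
    v <- spread(v, vn[vfam == "VH7"], 4.3)
    d <- setNames(rep(1 / length(dn), length(dn)), dn)
    j <- c(IGHJ1 = 0.07, IGHJ2 = 0.08, IGHJ3 = 0.13, IGHJ4 = 0.35,
           IGHJ5 = 0.15, IGHJ6 = 0.22)
  }
  v <- v[vn]
  names(v) <- vn
  list(v = v / sum(v), d = d[dn] / sum(d), j = j[jn] / sum(j))
}

# Hotspot-bias multiplier that makes the expected fraction of mutations inside
# RGYW/WRCY windows equal `fraction`, given the mean masked fraction f of the
# reference V segments: b f / (b f + 1 - f) = fraction.
.hotspotBiasFor <- function(reference, fraction = 0.9) {
  vseqs <- as.character(segmentSeq(reference, segmentNames(reference, "V")))
  f <- mean(vapply(vseqs, function(s) mean(scanHotspots(s)), 0))
  (fraction / (1 - fraction)) * ((1 - f) / f)
}

#' Build a simulation configuration
#'
#' Returns a validated [SimulationConfig] for [simulateRepertoire()]. Two
#' presets encode the study conditions the simulator emulates:
#'
#' * `"ptec-like"`: 2 donors of ~50 cells, 4-8 cloned colonies per cell,
#'   VH1-heavy 3'-concentrated V usage, per-sequence SHM drawn from a mixture
#'   with 60% of its mass on 5-10% (range 2.9-20.5%), hotspot bias calibrated
#'   so ~90% of mutations fall in RGYW/WRCY windows, CDR bias 3, 5.8%
#'   nonfunctional rearrangements, patterns-per-cell probabilities
#'   0.868/0.110/0.022, and clonal sharing (`pSharedClone = 0.1`) producing
#'   identical-junction clonotypes within and across donors.
#' * `"bcell-like"`: the diverse B-cell baseline -- VH3/VH4-dominated usage,
#'   no clonal sharing, 3.9% nonfunctional, patterns-per-cell 0.972/0.028/0.
#'
#' Any slot can be overridden by name through `...`, e.g.
#' `simulationConfig(ref, seed = 7, pSharedClone = 0, shmRateRange = c(0, 0))`.
#'
#' @param reference a [GermlineReference]; usage vectors are built over its
#'   gene names.
#' @param preset `"ptec-like"` or `"bcell-like"`.
#' @param seed integer RNG seed; all simulator randomness flows from it.
#' @param ... named overrides for any `SimulationConfig` slot.
#' @return a validated [SimulationConfig].
#' @export
simulationConfig <- function(reference, preset = c("ptec-like", "bcell-like"),
                             seed = 1L, ...) {
  preset <- match.arg(preset)
  usage <- .usagePreset(reference, preset)
  ptec <- preset == "ptec-like"
  cfg <- new("SimulationConfig",
    seed = as.integer(seed), nDonors = 2L, cellsPerDonor = 50L,
    coloniesPerCell = c(4L, 8L),
    vUsage = usage$v, dUsage = usage$d, jUsage = usage$j,
    trimMax = 5L, nAdditionMean = 6,
    shmRateRange = c(0.029, 0.205),
    shmRateModel = if (ptec) "ptec" else "uniform",
    hotspotBias = .hotspotBiasFor(reference, 0.9),
    cdrBias = 3,
    pNonfunctional = if (ptec) 0.058 else 0.039,
    patternsPerCellDist = if (ptec) c(0.868, 0.110, 0.022) else c(0.972, 0.028, 0),
    pSharedClone = if (ptec) 0.10 else 0,
    colonyErrorRate = 0, preset = preset)
  over <- list(...)
  bad <- setdiff(names(over), slotNames("SimulationConfig"))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    slot(cfg, nm) <- if (is(slot(cfg, nm), "integer")) as.integer(over[[nm]])
                     else over[[nm]]
  }
  validObject(cfg)
  cfg
}

#' Assemble one V(D)J rearrangement from germline parts
#'
#' Joins trimmed germline segments with the supplied non-templated N-region
#' strings: `V[0, |V|-v_trim3) + n1 + D[d_trim5, |D|-d_trim3) + n2 +
#' J[j_trim5, |J|)`. Returns both the nucleotide sequence and a junction
#' record with 0-based half-open coordinates of every assembled part, the
#' position of the conserved Cys codon (CDR3 anchor) and of the conserved J
#' Trp codon in the assembled sequence.
#'
#' @param reference a [GermlineReference].
#' @param vName,dName,jName germline gene names.
#' @param vTrim3,dTrim5,dTrim3,jTrim5 non-negative exonucleolytic trims (nt).
#' @param n1,n2 N-addition strings over ACGT at the V-D and D-J junctions
#'   (may be empty).
#' @return a list with elements `sequence` (character) and `record` (list of
#'   segment names, trims, N strings and assembled coordinates `v_end`,
#'   `d_start`, `d_end`, `j_start`, `cys_pos`, `trp_pos`).
#' @examples
#' ref <- exampleReference()
#' asm <- recombineSegments(ref, "IGHV1-24", "IGHD2-15", "IGHJ4",
#'                          n1 = "TT", n2 = "ACCCGATCCGAC")
#' nchar(asm$sequence)
#' @export
recombineSegments <- function(reference, vName, dName, jName,
                              vTrim3 = 0L, dTrim5 = 0L, dTrim3 = 0L,
                              jTrim5 = 0L, n1 = "", n2 = "") {
  for (s in c(n1, n2))
    if (nchar(s) && !grepl("^[ACGT]+$", s))
      stop("N-region strings must be over {A,C,G,T}")
  unknown <- setdiff(c(vName, dName, jName), segmentInfo(reference)$name)
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  .recombineCore(.refCache(reference, labels = FALSE), vName, dName, jName,
                 vTrim3, dTrim5, dTrim3, jTrim5, n1, n2)
}

# logical mask of CDR positions (0-based positions i marked at index i+1)
# over an assembled rearrangement: V CDR1 + CDR2 labels, and the whole CDR3
# (germline V tail after the Cys codon, N regions, D, J head before Trp).
.cdrMask <- function(cache, assembly) {
  rec <- assembly$record
  L <- nchar(assembly$sequence)
  lab <- cache$vlab[[rec$v_name]][seq_len(rec$v_end)]
  mask <- rep(FALSE, L)
  mask[seq_len(rec$v_end)] <- lab %in% c("CDR1", "CDR2", "CDR3")
  if (!is.na(rec$trp_pos)) {
    if (rec$trp_pos > rec$v_end) mask[(rec$v_end + 1):rec$trp_pos] <- TRUE
  } else {
    if (L > rec$v_end) mask[(rec$v_end + 1):L] <- TRUE
  }
  mask
}

#' Apply somatic hypermutation to a sequence
#'
#' Introduces point substitutions with per-position probability proportional to
#' `hotspotBias` for positions inside RGYW/WRCY hotspot windows of the
#' unmutated (germline-context) sequence and `cdrBias` for CDR positions,
#' scaled so the expected per-sequence mutation rate equals `targetRate`.
#' Substituted bases are drawn uniformly from the three alternatives. Motif
#' windows are scanned on the input sequence, so a mutation can neither create
#' nor destroy its own hotspot status. Draws come from the R session RNG;
#' callers seed once per run.
#'
#' @param sequence nucleotide string over ACGT.
#' @param targetRate expected per-position mutation rate, in `[0, 0.25]`.
#' @param hotspotBias,cdrBias relative rate multipliers (1 = off).
#' @param cdrMask optional logical vector (one per position) marking CDR
#'   positions; required only when `cdrBias != 1`.
#' @return list with `sequence` (mutated string) and `mutations`, a data.frame
#'   with columns `position` (0-based), `germline_base`, `mutated_base`.
#' @export
applySHM <- function(sequence, targetRate, hotspotBias = 1, cdrBias = 1,
                     cdrMask = NULL) {
  if (targetRate < 0 || targetRate > 0.25)
    stop("targetRate must lie in [0, 0.25]")
  empty <- data.frame(position = integer(), germline_base = character(),
                      mutated_base = character(), stringsAsFactors = FALSE)
  L <- nchar(sequence)
  if (targetRate == 0 || L == 0)
    return(list(sequence = sequence, mutations = empty))
  s <- strsplit(sequence, "")[[1]]
  w <- rep(1, L)
  hot <- scanHotspots(sequence)
  w[hot] <- w[hot] * hotspotBias
  if (cdrBias != 1) {
    if (is.null(cdrMask) || length(cdrMask) != L)
      stop("cdrBias != 1 requires a per-position cdrMask")
    w[cdrMask] <- w[cdrMask] * cdrBias
  }
  # scale the weights so the expected count equals targetRate * L even when
  # heavily weighted positions saturate at probability 1 (water-filling)
  target <- targetRate * L
  lo <- 0; hi <- target / sum(w)
  while (sum(pmin(1, hi * w)) < target) hi <- hi * 2
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (sum(pmin(1, mid * w)) < target) lo <- mid else hi <- mid
  }
  p <- pmin(1, hi * w)
  hit <- which(stats::runif(L) < p)
  if (!length(hit)) return(list(sequence = sequence, mutations = empty))
  germ <- s[hit]
  s[hit] <- vapply(germ, function(b) sample(setdiff(.BASES, b), 1), "")
  list(sequence = paste0(s, collapse = ""),
       mutations = data.frame(position = hit - 1L, germline_base = germ,
                              mutated_base = s[hit], stringsAsFactors = FALSE))
}

# any in-frame stop codon between pos 0 and the end of the sequence,
# checked up to the last complete codon
.hasStop <- function(sequence) {
  L <- nchar(sequence)
  if (L < 3) return(FALSE)
  starts <- seq(1, L - 2, by = 3)
  any(substring(sequence, starts, starts + 2) %in% .STOPS)
}

#' Make a rearrangement nonfunctional
#'
#' Deliberately breaks an assembled rearrangement: `kind = "stop"` replaces one
#' in-frame codon between the V FR2 start and the J Trp anchor with a random
#' stop codon (the changed bases are returned as mutation records so the truth
#' table still reconstructs the sequence exactly); `kind = "frameshift"`
#' changes the D-J N-region length by one nucleotide so the V-to-J reading
#' frame is broken; `kind = "none"` is a pass-through.
#'
#' @param reference a [GermlineReference].
#' @param assembly result of [recombineSegments()].
#' @param kind `"none"`, `"stop"` or `"frameshift"`.
#' @return list with `sequence`, `record` (updated) and `mutations` (stop-codon
#'   substitutions, if any).
#' @export
makeNonfunctional <- function(reference, assembly,
                              kind = c("none", "stop", "frameshift")) {
  .makeNonfunctionalCore(.refCache(reference, labels = FALSE), assembly,
                         match.arg(kind))
}

.makeNonfunctionalCore <- function(cache, assembly,
                                   kind = c("none", "stop", "frameshift")) {
  kind <- match.arg(kind)
  empty <- data.frame(position = integer(), germline_base = character(),
                      mutated_base = character(), stringsAsFactors = FALSE)
  if (kind == "none")
    return(list(sequence = assembly$sequence, record = assembly$record,
                mutations = empty))
  rec <- assembly$record
  if (kind == "frameshift") {
    n2 <- rec$n2_seq
    n2 <- if (nchar(n2) == 0) .randNt(1)
          else if (stats::runif(1) < 0.5) paste0(n2, .randNt(1))
          else substr(n2, 1, nchar(n2) - 1)
    out <- .recombineCore(cache, rec$v_name, rec$d_name, rec$j_name,
                          rec$v_trim3, rec$d_trim5, rec$d_trim3,
                          rec$j_trim5, rec$n1_seq, n2)
    return(c(out, list(mutations = empty)))
  }
  fr2 <- cache$fr2[[rec$v_name]]
  lastCodon <- (if (is.na(rec$trp_pos)) nchar(assembly$sequence)
                else rec$trp_pos) %/% 3 - 1L
  codon <- .runifInt(fr2 %/% 3, lastCodon)
  s <- strsplit(assembly$sequence, "")[[1]]
  stopC <- strsplit(sample(.STOPS, 1), "")[[1]]
  pos <- codon * 3 + 1:3
  changed <- which(s[pos] != stopC)
  muts <- data.frame(position = pos[changed] - 1L,
                     germline_base = s[pos][changed],
                     mutated_base = stopC[changed], stringsAsFactors = FALSE)
  s[pos] <- stopC
  list(sequence = paste0(s, collapse = ""), record = rec, mutations = muts)
}

# draw a per-sequence SHM rate from the configured range
.drawShmRate <- function(model, range) {
  if (model == "uniform" || range[2] <= 0.05 || range[1] >= 0.10)
    return(stats::runif(1, range[1], range[2]))
  # "ptec" mixture: 60% of mass on the central 5-10% band (clipped to the
  # configured range), the rest on the flanks, proportional to flank width
  cl <- max(range[1], 0.05); ch <- min(range[2], 0.10)
  if (stats::runif(1) < 0.6) return(stats::runif(1, cl, ch))
  wl <- max(cl - range[1], 0); wh <- max(range[2] - ch, 0)
  if (wl + wh == 0) return(stats::runif(1, cl, ch))
  if (stats::runif(1) < wl / (wl + wh)) stats::runif(1, range[1], cl)
  else stats::runif(1, ch, range[2])
}

# precomputed per-reference lookups so the per-clone loops avoid repeated
# DataFrame conversions
.refCache <- function(reference, labels = TRUE) {
  info <- as.data.frame(reference@info)
  vlab <- NULL
  if (labels) {
    vNames <- info$name[info$segment_class == "V"]
    vlab <- lapply(vNames, vRegionLabels, reference = reference)
    names(vlab) <- vNames
  }
  list(info = info, seqs = setNames(as.character(reference@sequences),
                                    info$name),
       cys = setNames(info$cdr3_anchor, info$name),
       jAnchor = setNames(info$j_trp_anchor, info$name),
       fr2 = setNames(info$fr2_start, info$name), vlab = vlab)
}

# assembly core shared by recombineSegments and the clone sampler
.recombineCore <- function(cache, vName, dName, jName, vTrim3, dTrim5,
                           dTrim3, jTrim5, n1, n2) {
  v <- cache$seqs[[vName]]; d <- cache$seqs[[dName]]; j <- cache$seqs[[jName]]
  if (vTrim3 < 0 || dTrim5 < 0 || dTrim3 < 0 || jTrim5 < 0)
    stop("trims must be non-negative")
  if (vTrim3 >= nchar(v)) stop("vTrim3 exceeds V length")
  if (dTrim5 + dTrim3 >= nchar(d)) stop("D trims exceed D length")
  if (jTrim5 >= nchar(j)) stop("jTrim5 exceeds J length")
  vPart <- substr(v, 1, nchar(v) - vTrim3)
  dPart <- substr(d, dTrim5 + 1, nchar(d) - dTrim3)
  jPart <- substr(j, jTrim5 + 1, nchar(j))
  seq <- paste0(vPart, n1, dPart, n2, jPart)
  cys <- cache$cys[[vName]]
  jAnchor <- cache$jAnchor[[jName]]
  vEnd <- nchar(vPart)
  dStart <- vEnd + nchar(n1)
  dEnd <- dStart + nchar(dPart)
  jStart <- dEnd + nchar(n2)
  list(sequence = seq,
       record = list(v_name = vName, d_name = dName, j_name = jName,
                     v_trim3 = as.integer(vTrim3), d_trim5 = as.integer(dTrim5),
                     d_trim3 = as.integer(dTrim3), j_trim5 = as.integer(jTrim5),
                     n1_seq = n1, n2_seq = n2,
                     v_end = vEnd, d_start = dStart, d_end = dEnd,
                     j_start = jStart,
                     cys_pos = if (cys < vEnd) as.integer(cys) else NA_integer_,
                     trp_pos = if (jTrim5 <= jAnchor)
                       as.integer(jStart + jAnchor - jTrim5) else NA_integer_))
}

# sample a new productive clone: segments by usage, then trims and N strings
# with the V-to-J frame fixed; junction bases introducing an in-frame stop are
# resampled (segments kept, so usage frequencies stay unbiased)
.newClone <- function(cache, config) {
  geomLen <- function() stats::rgeom(1, 1 / (config@nAdditionMean + 1))
  vName <- sample(names(config@vUsage), 1, prob = config@vUsage)
  dName <- sample(names(config@dUsage), 1, prob = config@dUsage)
  jName <- sample(names(config@jUsage), 1, prob = config@jUsage)
  vLen <- nchar(cache$seqs[[vName]])
  dLen <- nchar(cache$seqs[[dName]])
  cys <- cache$cys[[vName]]
  jAnchor <- cache$jAnchor[[jName]]
  for (try in 1:200) {
    vTrim3 <- .runifInt(0L, min(config@trimMax, vLen - cys - 4L))
    dTrim5 <- .runifInt(0L, min(config@trimMax, dLen - 2L))
    dTrim3 <- .runifInt(0L, min(config@trimMax, dLen - dTrim5 - 1L))
    jTrim5 <- .runifInt(0L, min(config@trimMax, jAnchor))
    n1 <- .randNt(geomLen())
    n2 <- .randNt(geomLen())
    # pad n2 so the conserved J Trp codon lands in frame with the V start
    trp <- (vLen - vTrim3) + nchar(n1) + (dLen - dTrim5 - dTrim3) +
      nchar(n2) + (jAnchor - jTrim5)
    n2 <- paste0(n2, .randNt((3 - trp %% 3) %% 3))
    asm <- .recombineCore(cache, vName, dName, jName, vTrim3, dTrim5,
                          dTrim3, jTrim5, n1, n2)
    if (!.hasStop(asm$sequence)) return(asm)
  }
  stop("could not sample a stop-free productive rearrangement")
}

.cloneKey <- function(rec) {
  paste(rec$v_name, rec$d_name, rec$j_name, rec$n1_seq, rec$n2_seq,
        rec$v_trim3, rec$d_trim5, rec$d_trim3, rec$j_trim5, sep = "|")
}

.encodeMutations <- function(m) {
  if (nrow(m) == 0) return("")
  m <- m[order(m$position), , drop = FALSE]
  paste(sprintf("%d:%s>%s", m$position, m$germline_base, m$mutated_base),
        collapse = ";")
}

#' Decode a truth-table mutation string
#'
#' Parses the `mutations` column of the simulator truth table
#' (`"12:A>G;40:C>T"`) back into a data.frame.
#'
#' @param x character scalar as stored in the truth table.
#' @return data.frame with `position` (0-based), `germline_base`,
#'   `mutated_base`.
#' @export
decodeMutations <- function(x) {
  if (is.na(x) || x == "")
    return(data.frame(position = integer(), germline_base = character(),
                      mutated_base = character(), stringsAsFactors = FALSE))
  parts <- strsplit(strsplit(x, ";")[[1]], "[:>]")
  data.frame(position = as.integer(vapply(parts, `[`, "", 1)),
             germline_base = vapply(parts, `[`, "", 2),
             mutated_base = vapply(parts, `[`, "", 3), stringsAsFactors = FALSE)
}

#' Reconstruct a simulated sequence from its truth row
#'
#' Reassembles the rearrangement from the recorded segments, trims and
#' N-region strings, then replays the recorded substitutions. For every
#' emitted record this reproduces the FASTA sequence exactly.
#'
#' @param reference a [GermlineReference].
#' @param truthRow one row of the truth table from [simulateRepertoire()].
#' @return the reconstructed nucleotide string.
#' @export
reconstructFromTruth <- function(reference, truthRow) {
  asm <- recombineSegments(reference, truthRow$v_name, truthRow$d_name,
                           truthRow$j_name, truthRow$v_trim3, truthRow$d_trim5,
                           truthRow$d_trim3, truthRow$j_trim5,
                           truthRow$n1_seq, truthRow$n2_seq)
  s <- strsplit(asm$sequence, "")[[1]]
  m <- decodeMutations(truthRow$mutations)
  if (nrow(m)) {
    stopifnot(all(s[m$position + 1] == m$germline_base))
    s[m$position + 1] <- m$mutated_base
  }
  paste0(s, collapse = "")
}

#' Simulate a single-cell heavy-chain repertoire
#'
#' Generates a synthetic single-cell IgG heavy-chain repertoire with the
#' structure assumed by the annotation pipeline: each cell carries 1-3
#' distinct V(D)J rearrangement patterns, each pattern is cloned into several
#' colony sequences, rearrangements draw their segments from the configured
#' usage vectors, junctions carry exonucleolytic trims and non-templated N
#' additions, somatic hypermutation is applied with hotspot and CDR biases, a
#' configured fraction of rearrangements is made nonfunctional (stop codon or
#' frameshift), and clonal sharing within and across donors is injected by
#' reuse from a global clone pool. Output is deterministic given the config
#' seed.
#'
#' @param reference a [GermlineReference].
#' @param config a [SimulationConfig] from [simulationConfig()].
#' @return a list with `sequences` (named [Biostrings::DNAStringSet], ids
#'   `"<donor>-<cell>_col<k>"`), `truth` (data.frame, one row per colony
#'   sequence: ids, clone id, segments, trims, N strings, encoded mutation
#'   list, `nonfunctional_kind`, `shm_rate`, `full_sequence`) and `config`.
#' @examples
#' ref <- exampleReference()
#' sim <- simulateRepertoire(ref, simulationConfig(ref, "ptec-like", seed = 1,
#'                                                 cellsPerDonor = 3))
#' head(sim$truth[, c("sequence_id", "v_name", "d_name", "j_name")])
#' @export
simulateRepertoire <- function(reference, config) {
  validObject(config)
  if (!all(names(config@vUsage) %in% segmentNames(reference, "V")) ||
      !all(names(config@dUsage) %in% segmentNames(reference, "D")) ||
      !all(names(config@jUsage) %in% segmentNames(reference, "J")))
    stop("usage vector references gene(s) absent from the reference")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config@seed)
  cache <- .refCache(reference)

  pool <- list()        # shared clone pool (assemblies)
  rows <- list()
  seqs <- character()
  cloneCounter <- 0L

  for (donor in seq_len(config@nDonors)) {
    for (cell in seq_len(config@cellsPerDonor)) {
      cellId <- paste0(donor, "-", cell)
      nPat <- sample(1:3, 1, prob = config@patternsPerCellDist)
      patterns <- list()
      keys <- character()
      for (p in seq_len(nPat)) {
        for (try in 1:50) {
          if (length(pool) && stats::runif(1) < config@pSharedClone) {
            pick <- .runifInt(1L, length(pool))
            cand <- pool[[pick]]
          } else {
            cand <- .newClone(cache, config)
            cand$clone_id <- paste0("clone", cloneCounter + 1L)
            cloneCounter <- cloneCounter + 1L
            pool[[length(pool) + 1L]] <- cand
          }
          if (!.cloneKey(cand$record) %in% keys) break
        }
        keys <- c(keys, .cloneKey(cand$record))
        patterns[[p]] <- cand
      }
      nCol <- .runifInt(config@coloniesPerCell[1], config@coloniesPerCell[2])
      nCol <- max(nCol, nPat)  # every pattern is seen in >=1 colony
      patOfCol <- c(seq_len(nPat), if (nCol > nPat)
        sample(seq_len(nPat), nCol - nPat, replace = TRUE))
      # per-pattern mutated master sequence for this cell
      master <- vector("list", nPat)
      for (p in seq_len(nPat)) {
        asm <- patterns[[p]]
        kind <- if (stats::runif(1) < config@pNonfunctional)
          sample(c("stop", "frameshift"), 1) else "none"
        broken <- if (kind == "frameshift")
          .makeNonfunctionalCore(cache, asm, "frameshift")
        else list(sequence = asm$sequence, record = asm$record,
                  mutations = NULL)
        rate <- .drawShmRate(config@shmRateModel, config@shmRateRange)
        mask <- .cdrMask(cache, broken)
        for (draw in 1:50) {
          shm <- applySHM(broken$sequence, rate, config@hotspotBias,
                          config@cdrBias, mask)
          if (kind != "none" || !.hasStop(shm$sequence)) break
        }
        muts <- shm$mutations
        seqFinal <- shm$sequence
        if (kind == "stop") {
          st <- .makeNonfunctionalCore(cache,
                                  list(sequence = asm$sequence,
                                       record = asm$record), "stop")
          s <- strsplit(seqFinal, "")[[1]]
          g <- strsplit(asm$sequence, "")[[1]]
          keep <- !muts$position %in% st$mutations$position
          muts <- muts[keep, , drop = FALSE]
          s[st$mutations$position + 1] <- st$mutations$mutated_base
          stopMut <- st$mutations
          stopMut$germline_base <- g[stopMut$position + 1]
          muts <- rbind(muts, stopMut)
          seqFinal <- paste0(s, collapse = "")
        }
        master[[p]] <- list(record = broken$record, sequence = seqFinal,
                            mutations = muts, kind = kind, rate = rate,
                            clone_id = patterns[[p]]$clone_id)
      }
      for (k in seq_len(nCol)) {
        m <- master[[patOfCol[k]]]
        seqOut <- m$sequence
        mutsOut <- m$mutations
        if (config@colonyErrorRate > 0) {
          err <- applySHM(seqOut, config@colonyErrorRate)
          # colony errors recorded like substitutions so truth still rebuilds
          if (nrow(err$mutations)) {
            seqOut <- err$sequence
            g <- strsplit(m$sequence, "")[[1]]
            add <- err$mutations
            overlap <- add$position %in% mutsOut$position
            for (i in which(overlap)) {
              j <- which(mutsOut$position == add$position[i])
              mutsOut$mutated_base[j] <- add$mutated_base[i]
            }
            mutsOut <- rbind(mutsOut, add[!overlap, , drop = FALSE])
            drop <- mutsOut$germline_base == mutsOut$mutated_base
            mutsOut <- mutsOut[!drop, , drop = FALSE]
          }
        }
        rec <- m$record
        sid <- paste0(cellId, "_col", k)
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = sid, donor_id = as.character(donor), cell_id = cellId,
          clone_id = m$clone_id, v_name = rec$v_name, d_name = rec$d_name,
          j_name = rec$j_name, v_trim3 = rec$v_trim3, d_trim5 = rec$d_trim5,
          d_trim3 = rec$d_trim3, j_trim5 = rec$j_trim5, n1_seq = rec$n1_seq,
          n2_seq = rec$n2_seq, mutations = .encodeMutations(mutsOut),
          nonfunctional_kind = m$kind, shm_rate = m$rate,
          full_sequence = seqOut, stringsAsFactors = FALSE)
        seqs[sid] <- seqOut
      }
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  dss <- Biostrings::DNAStringSet(seqs)
  list(sequences = dss, truth = truth, config = config)
}

#' The packaged example germline reference
#'
#' Convenience loader for the synthetic germline reference shipped under
#' `inst/extdata` (see [loadGermlineReference()] for what it contains).
#'
#' @return a [GermlineReference].
#' @export
exampleReference <- function() {
  loadGermlineReference(
    system.file("extdata", "germline_synthetic.fasta", package = "scIgRep"),
    system.file("extdata", "germline_synthetic_meta.tsv", package = "scIgRep"))
}
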
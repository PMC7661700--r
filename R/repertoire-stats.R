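#' Curated shared-rearrangement cell patterns
#'
#' Loads the packaged table of ten predominant heavy-chain V(D)J
#' rearrangements with identical V-D and D-J junction strings that were
#' carried by multiple single proximal tubular epithelial cells from two
#' different donors, expanded to one row per (cell, rearrangement) in the
#' [dedupeCellPatterns()] layout (cell ids are `"<donor>-<cell>"`).
#'
#' @return data.frame with columns `donor_id`, `cell_id`, `v_call`, `d_call`,
#'   `j_call`, `n1_seq`, `n2_seq`.
#' @examples
#' sharedRearrangements(examplePublicClonotypes())
#' @export
examplePublicClonotypes <- function() {
  path <- system.file("extdata", "ptec_shared_rearrangements.tsv",
                      package = "scIgRep")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  tab$n1_seq[is.na(tab$n1_seq)] <- ""
  tab$n2_seq[is.na(tab$n2_seq)] <- ""
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    cells <- strsplit(tab$cells[i], ",")[[1]]
    data.frame(donor_id = sub("-.*$", "", cells), cell_id = cells,
               v_call = tab$v_call[i], d_call = tab$d_call[i],
               j_call = tab$j_call[i], n1_seq = tab$n1_seq[i],
               n2_seq = tab$n2_seq[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' IgG detection rate per donor and pooled
#'
#' A cell counts positive when at least one rearrangement pattern was
#' annotated in it. Percentages follow the reporting convention of
#' single-cell Ig surveys: pooled to the nearest integer, per-donor to one
#' decimal; exact values are retained alongside.
#'
#' @param cells data.frame with columns `donor_id` and `positive` (logical),
#'   one row per assayed cell.
#' @return list with `per_donor` (data.frame: `donor_id`, `positive`, `total`,
#'   `percent`, `percent_exact`) and `pooled` (list: `positive`, `total`,
#'   `percent`, `percent_exact`).
#' @examples
#' cells <- data.frame(donor_id = rep(c("1", "2"), c(49, 62)),
#'                     positive = c(rep(c(TRUE, FALSE), c(45, 4)),
#'                                  rep(c(TRUE, FALSE), c(46, 16))))
#' detectionRate(cells)$pooled$percent  # 82
#' @export
detectionRate <- function(cells) {
  if (nrow(cells) == 0) stop("no cells supplied")
  pos <- tapply(cells$positive, cells$donor_id, sum)
  tot <- tapply(cells$positive, cells$donor_id, length)
  perDonor <- data.frame(donor_id = names(pos),
                         positive = as.integer(pos), total = as.integer(tot),
                         percent = as.numeric(round(100 * pos / tot, 1)),
                         percent_exact = as.numeric(100 * pos / tot),
                         stringsAsFactors = FALSE)
  rownames(perDonor) <- NULL
  p <- sum(cells$positive); n <- nrow(cells)
  list(per_donor = perDonor,
       pooled = list(positive = p, total = n,
                     percent = round(100 * p / n),
                     percent_exact = 100 * p / n))
}

#' Segment-usage frequency table
#'
#' Counts gene or family usage of one segment class over distinct cell
#' rearrangement patterns (one count per pattern, so clonal colony resampling
#' does not inflate frequencies). Unassigned D calls are excluded from the D
#' table and reported separately.
#'
#' @param patterns a [dedupeCellPatterns()] result (or any data.frame with
#'   `v_call`, `d_call`, `j_call`).
#' @param level `"gene"` or `"family"`.
#' @param segmentClass `"V"`, `"D"` or `"J"`.
#' @return list with `level`, `segment_class`, `table` (data.frame: `label`,
#'   `count`, `frequency`), `n` and `n_unassigned`.
#' @export
usageFrequencies <- function(patterns, level = c("gene", "family"),
                             segmentClass = c("V", "D", "J")) {
  level <- match.arg(level)
  segmentClass <- match.arg(segmentClass)
  col <- c(V = "v_call", D = "d_call", J = "j_call")[[segmentClass]]
  calls <- patterns[[col]]
  calls <- calls[!is.na(calls)]
  unass <- sum(calls == "unassigned")
  calls <- calls[calls != "unassigned"]
  if (length(calls) == 0) {
    if (unass > 0)
      return(list(level = level, segment_class = segmentClass,
                  table = data.frame(label = character(), count = integer(),
                                     frequency = numeric()),
                  n = 0L, n_unassigned = unass))
    stop("no assigned ", segmentClass, " calls to tabulate")
  }
  if (level == "family") calls <- familyOf(calls)
  tab <- table(calls)
  out <- data.frame(label = names(tab), count = as.integer(tab),
                    frequency = as.numeric(tab) / length(calls),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$label), ]
  rownames(out) <- NULL
  list(level = level, segment_class = segmentClass, table = out,
       n = length(calls), n_unassigned = unass)
}

#' Chi-square comparison of two usage tables
#'
#' Pearson chi-square on the 2 x k contingency table of counts from two
#' repertoires over the union of their labels (zero-filled), as used to
#' compare VH/DH/JH family usage between cell types; `df = k - 1`.
#'
#' @param tableA,tableB [usageFrequencies()] results (or their `$table`
#'   data.frames).
#' @return list with `statistic`, `df`, `p_value`, `labels`.
#' @export
chiSquareUsage <- function(tableA, tableB) {
  getTab <- function(x) if (is.list(x) && !is.null(x$table)) x$table else x
  a <- getTab(tableA); b <- getTab(tableB)
  labels <- sort(union(a$label, b$label))
  ca <- setNames(rep(0L, length(labels)), labels)
  cb <- ca
  ca[a$label] <- a$count; cb[b$label] <- b$count
  m <- rbind(ca, cb)
  zeroRow <- rowSums(m) == 0
  zeroCol <- colSums(m) == 0
  if (any(zeroRow) || any(zeroCol))
    stop("zero margin in contingency table: ",
         paste(c(c("repertoire A", "repertoire B")[zeroRow],
                 labels[zeroCol]), collapse = ", "))
  if (length(labels) < 2) stop("need at least 2 labels to compare")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), labels = labels)
}

#' Distribution of rearrangement patterns per cell
#'
#' Bins cells by how many distinct V(D)J rearrangement patterns they display:
#' one, two, or more than two. Percentages are reported to one decimal.
#'
#' @param patterns a [dedupeCellPatterns()] result covering all positive
#'   cells.
#' @return list with `counts` (named: `"1"`, `"2"`, `">2"`), `percent`,
#'   `n_cells`.
#' @export
patternsPerCell <- function(patterns) {
  if (nrow(patterns) == 0) stop("no cell patterns supplied")
  per <- table(patterns$cell_id)
  counts <- c(`1` = sum(per == 1), `2` = sum(per == 2), `>2` = sum(per > 2))
  list(counts = counts,
       percent = round(100 * counts / sum(counts), 1),
       percent_exact = 100 * counts / sum(counts),
       n_cells = as.integer(sum(counts)))
}

#' Detect shared identical-junction rearrangements
#'
#' Groups cell patterns by the full rearrangement key
#' `(v_call, d_call, j_call, n1_seq, n2_seq)` and reports every key carried by
#' two or more cells -- the public-clonotype structure of a repertoire. Sets
#' spanning two or more donors are flagged `cross_donor`. Output ordering is
#' deterministic by key, invariant to input cell order.
#'
#' @param patterns a [dedupeCellPatterns()] result.
#' @return data.frame with one row per shared set: the key columns,
#'   `n_cells`, `n_donors`, `cross_donor`, and `member_cells`
#'   (comma-separated cell ids, sorted).
#' @export
sharedRearrangements <- function(patterns) {
  empty <- data.frame(v_call = character(), d_call = character(),
                      j_call = character(), n1_seq = character(),
                      n2_seq = character(), n_cells = integer(),
                      n_donors = integer(), cross_donor = logical(),
                      member_cells = character(), stringsAsFactors = FALSE)
  if (nrow(patterns) == 0) return(empty)
  key <- paste(patterns$v_call, patterns$d_call, patterns$j_call,
               patterns$n1_seq, patterns$n2_seq, sep = "|")
  keep <- key %in% names(which(table(key) >= 2))
  if (!any(keep)) return(empty)
  pat <- patterns[keep, , drop = FALSE]
  key <- key[keep]
  rows <- lapply(sort(unique(key)), function(k) {
    g <- pat[key == k, , drop = FALSE]
    cells <- sort(unique(g$cell_id))
    if (length(cells) < 2) return(NULL)
    data.frame(v_call = g$v_call[1], d_call = g$d_call[1],
               j_call = g$j_call[1], n1_seq = g$n1_seq[1],
               n2_seq = g$n2_seq[1], n_cells = length(cells),
               n_donors = length(unique(g$donor_id)),
               cross_donor = length(unique(g$donor_id)) >= 2,
               member_cells = paste(cells, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$v_call, out$d_call, out$j_call, out$n1_seq,
                   out$n2_seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gaussian fit to a CDR3 amino-acid length distribution
#'
#' Histograms CDR3 amino-acid lengths, fits `A * exp(-(x - mu)^2 / (2
#' sigma^2))` to the length-frequency histogram by least squares
#' (Levenberg-Marquardt, deterministic initialization: `A` = max frequency,
#' `mu` = weighted mean, `sigma` = weighted sd) and reports `R^2 = 1 -
#' SS_res / SS_tot`. A diverse repertoire yields a near-Gaussian length
#' profile (high `R^2`); clonally restricted repertoires depart from it.
#'
#' @param lengths integer vector of CDR3 amino-acid lengths (one per
#'   productive sequence or pattern).
#' @return list with `histogram` (data.frame: `length`, `count`, `frequency`),
#'   `amplitude`, `mean`, `sd`, `r_squared`, `n`.
#' @export
cdr3GaussianFit <- function(lengths) {
  lengths <- lengths[!is.na(lengths)]
  if (length(unique(lengths)) < 3)
    stop("need at least 3 distinct CDR3 lengths to fit")
  tab <- table(factor(lengths, levels = seq(min(lengths), max(lengths))))
  hist <- data.frame(length = as.integer(names(tab)),
                     count = as.integer(tab),
                     frequency = as.integer(tab) / length(lengths))
  x <- hist$length; y <- hist$frequency
  mu0 <- sum(x * y) / sum(y)
  sd0 <- sqrt(sum(y * (x - mu0)^2) / sum(y))
  if (sd0 == 0) stop("degenerate length distribution")
  fit <- minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
                           start = list(A = max(y), mu = mu0, s = sd0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  pred <- stats::predict(fit)
  ssRes <- sum((y - pred)^2)
  ssTot <- sum((y - mean(y))^2)
  co <- stats::coef(fit)
  list(histogram = hist, amplitude = unname(co["A"]),
       mean = unname(co["mu"]), sd = abs(unname(co["s"])),
       r_squared = 1 - ssRes / ssTot, n = length(lengths))
}

#' Genomic-position profile of V-gene usage
#'
#' Orders gene-level V usage by genomic rank along the IGH locus and computes
#' a concentration statistic: the usage-weighted mean normalized rank in
#' `[0, 1]`, where 0 means usage fully concentrated on the most 3'
#' (JH-proximal) gene. Restricted 3'-biased repertoires score lower than
#' diverse ones.
#'
#' @param usage a gene-level [usageFrequencies()] result for class V.
#' @param reference a [GermlineReference].
#' @return list with `by_rank` (data.frame: `label`, `rank`,
#'   `normalized_rank`, `frequency`) and `concentration` (numeric).
#' @export
genomicDistribution <- function(usage, reference) {
  tab <- usage$table
  ranks <- genomicRank(reference, tab$label)
  nV <- sum(segmentInfo(reference)$segment_class == "V")
  norm <- if (nV > 1) ranks / (nV - 1) else rep(0, length(ranks))
  out <- data.frame(label = tab$label, rank = ranks, normalized_rank = norm,
                    frequency = tab$frequency, stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  list(by_rank = out, concentration = sum(out$frequency * out$normalized_rank))
}

#' Nonfunctional fraction of a repertoire
#'
#' @param annotations an [annotateRepertoire()] result, or a logical vector of
#'   per-sequence `productive` flags.
#' @return list with `nonfunctional`, `total`, `percent` (1 decimal),
#'   `percent_exact`.
#' @examples
#' productivityFraction(rep(c(FALSE, TRUE), c(27, 442)))$percent  # 5.8
#' @export
productivityFraction <- function(annotations) {
  prod <- if (is.logical(annotations)) annotations else annotations$productive
  if (length(prod) == 0) stop("no annotations supplied")
  nf <- sum(!prod)
  list(nonfunctional = nf, total = length(prod),
       percent = round(100 * nf / length(prod), 1),
       percent_exact = 100 * nf / length(prod))
}
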
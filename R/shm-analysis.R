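#' Scan a germline sequence for RGYW/WRCY hotspot positions
#'
#' Marks every position that lies inside at least one 4-mer window matching
#' the somatic-hypermutation hotspot motifs RGYW or WRCY (R = A/G, Y = C/T,
#' W = A/T); overlapping windows are unioned. Under
#' `convention = "aid_target"` only the mutable target base of a matching
#' window is marked -- the G of RGYW and the C of WRCY -- so the mask is
#' always a subset of the default. Scanning is meant to be performed on the
#' germline (pre-mutation) sequence: a mutation can neither create nor destroy
#' its own hotspot status.
#'
#' @param sequence nucleotide string over ACGT.
#' @param convention `"any_position"` (default) or `"aid_target"`.
#' @return logical vector, one element per position.
#' @examples
#' scanHotspots("AGCT")  # one RGYW window: all four positions
#' scanHotspots("CCCC")  # no window matches
#' @export
scanHotspots <- function(sequence, convention = c("any_position", "aid_target")) {
  convention <- match.arg(convention)
  sequence <- as.character(sequence)
  s <- strsplit(sequence, "")[[1]]
  L <- length(s)
  if (L && !all(s %in% c("A", "C", "G", "T")))
    stop("sequence must be over {A,C,G,T}")
  mask <- rep(FALSE, L)
  if (L < 4) return(mask)
  i <- seq_len(L - 3)
  R <- s %in% c("A", "G"); Y <- s %in% c("C", "T"); W <- s %in% c("A", "T")
  rgyw <- R[i] & (s[i + 1] == "G") & Y[i + 2] & W[i + 3]
  wrcy <- W[i] & R[i + 1] & (s[i + 2] == "C") & Y[i + 3]
  if (convention == "any_position") {
    for (k in 0:3) {
      hit <- which(rgyw | wrcy)
      mask[hit + k] <- TRUE
    }
  } else {
    mask[which(rgyw) + 1L] <- TRUE  # the G of RGYW
    mask[which(wrcy) + 2L] <- TRUE  # the C of WRCY
  }
  mask
}

#' Fraction of mutations falling in hotspot motifs
#'
#' Pools all mutation records and returns the fraction flagged `in_hotspot`,
#' together with per-sequence fractions. Zero mutations give a missing value,
#' not 0.
#'
#' @param annotations an [annotateRepertoire()] result, or a data.frame with
#'   columns `sequence_id` and `in_hotspot` (one row per mutation).
#' @return list with `pooled` (numeric, `NA` when there are no mutations),
#'   `n_mutations`, and `per_sequence` (named numeric vector).
#' @export
hotspotFraction <- function(annotations) {
  muts <- .pooledMutations(annotations)
  if (nrow(muts) == 0)
    return(list(pooled = NA_real_, n_mutations = 0L,
                per_sequence = setNames(numeric(), character())))
  per <- tapply(muts$in_hotspot, muts$sequence_id, mean)
  list(pooled = mean(muts$in_hotspot), n_mutations = nrow(muts),
       per_sequence = per[order(names(per))])
}

# flatten the mutations list-column (or accept an already-flat data.frame)
.pooledMutations <- function(annotations) {
  if (is.data.frame(annotations) && "in_hotspot" %in% colnames(annotations))
    return(annotations)
  stopifnot("mutations" %in% colnames(annotations))
  parts <- lapply(seq_len(nrow(annotations)), function(i) {
    m <- annotations$mutations[[i]]
    if (is.null(m) || nrow(m) == 0) return(NULL)
    m$sequence_id <- annotations$sequence_id[i]
    m
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(sequence_id = character(), in_hotspot = logical())
  out
}

#' Paired t-test from its closed formula
#'
#' Two-sided paired t-test on paired observations: with differences
#' `d = x - y`, `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of
#' freedom. Implemented directly so the statistic is unit-verifiable against
#' the formula.
#'
#' @param x,y paired numeric vectors.
#' @return list with `statistic`, `df`, `p_value`, `mean_difference`.
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  d <- x - y
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) stop("paired t-test needs at least 2 complete pairs")
  s <- stats::sd(d)
  t <- if (s == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else mean(d) / (s / sqrt(n))
  list(statistic = t, df = n - 1L,
       p_value = 2 * stats::pt(-abs(t), n - 1),
       mean_difference = mean(d))
}

#' CDR versus framework mutation rates with a paired t-test
#'
#' For each annotated sequence, computes the mutation rate of its CDR columns
#' (aligned CDR2 plus germline-aligned CDR3) and of its framework columns
#' (FR2, FR3, FR4 -- the FR2-to-JH window the assay covers), then compares the
#' paired per-sequence rates with the closed-form paired t-test.
#'
#' @param annotations an [annotateRepertoire()] result; sequences lacking
#'   aligned region columns are dropped.
#' @return list with `per_sequence` (data.frame: `sequence_id`, `cdr_rate`,
#'   `fr_rate`) and `paired_t` (see [pairedT()]).
#' @export
regionMutationRates <- function(annotations) {
  ok <- !is.na(annotations$cdr_len) & !is.na(annotations$fr_len) &
    annotations$cdr_len > 0 & annotations$fr_len > 0
  ann <- annotations[ok, , drop = FALSE]
  if (nrow(ann) < 2)
    stop("need at least 2 annotated sequences with region columns")
  rates <- t(vapply(seq_len(nrow(ann)), function(i) {
    m <- ann$mutations[[i]]
    nCdr <- if (is.null(m)) 0L else sum(m$region %in% c("CDR2", "CDR3"))
    nFr <- if (is.null(m)) 0L else sum(m$region %in% c("FR2", "FR3", "FR4"))
    c(nCdr / ann$cdr_len[i], nFr / ann$fr_len[i])
  }, c(0, 0)))
  per <- data.frame(sequence_id = ann$sequence_id,
                    cdr_rate = rates[, 1], fr_rate = rates[, 2],
                    stringsAsFactors = FALSE)
  list(per_sequence = per, paired_t = pairedT(per$cdr_rate, per$fr_rate))
}

#' Bin the per-sequence somatic hypermutation frequencies
#'
#' Summarizes per-sequence mutation frequencies (in percent) into the
#' reporting bins `< 2`, `[2, 5)`, `[5, 10]` and `> 10`, plus the observed
#' range. The inner edges are configurable; the third bin is closed on both
#' sides so a boundary-rate sequence counts toward the central mass.
#'
#' @param freqs numeric vector of per-sequence mutation frequencies, percent.
#' @param edges inner bin edges `c(low, mid, high)`.
#' @return list with `counts` (named integer vector), `fractions`, `range`
#'   and `n`.
#' @export
shmDistribution <- function(freqs, edges = c(2, 5, 10)) {
  freqs <- freqs[!is.na(freqs)]
  if (length(freqs) == 0) stop("no mutation frequencies supplied")
  labs <- c(paste0("<", edges[1]),
            paste0("[", edges[1], ",", edges[2], ")"),
            paste0("[", edges[2], ",", edges[3], "]"),
            paste0(">", edges[3]))
  counts <- c(sum(freqs < edges[1]),
              sum(freqs >= edges[1] & freqs < edges[2]),
              sum(freqs >= edges[2] & freqs <= edges[3]),
              sum(freqs > edges[3]))
  names(counts) <- labs
  list(counts = counts, fractions = counts / length(freqs),
       range = range(freqs), n = length(freqs))
}
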
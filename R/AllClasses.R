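#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' GermlineReference: a curated set of IGHV/IGHD/IGHJ germline segments
#'
#' Container for the germline gene-segment reference that all simulation and
#' annotation is performed against. Sequences are held as a
#' [Biostrings::DNAStringSet]; per-segment metadata (segment class, family,
#' genomic order along the IGH locus, and IMGT-style region boundaries) as a
#' [S4Vectors::DataFrame] keyed by gene name.
#'
#' Coordinates are 0-based half-open throughout. For V segments the metadata
#' carries the starts of FR1/CDR1/FR2/CDR2/FR3 plus `cdr3_anchor`, the position
#' of the conserved second-Cys codon ending FR3; CDR3 begins at the codon after
#' it. For J segments `j_trp_anchor` is the position of the conserved Trp codon
#' that closes CDR3 and opens FR4. `genomic_order_index` ranks segments along
#' the locus with 0 = most 3' (JH-proximal).
#'
#' @slot sequences DNAStringSet of germline segment sequences, named by gene.
#' @slot info DataFrame with columns `name`, `segment_class`, `family`,
#'   `genomic_order_index`, the V region-boundary columns and `j_trp_anchor`.
#' @slot provenance free-text description of where the reference came from.
#'
#' @seealso [loadGermlineReference()], [familyOf()], [genomicRank()]
#' @export
setClass("GermlineReference",
  slots = c(sequences = "DNAStringSet", info = "DataFrame",
            provenance = "character"))

setValidity("GermlineReference", function(object) {
  msg <- character()
  info <- object@info
  seqs <- object@sequences
  need <- c("name", "segment_class", "family", "genomic_order_index")
  if (!all(need %in% colnames(info)))
    return(paste("info is missing columns:",
                 paste(setdiff(need, colnames(info)), collapse = ", ")))
  if (length(seqs) != nrow(info) || !identical(names(seqs), info$name))
    msg <- c(msg, "sequences and info must be parallel and identically named")
  if (anyDuplicated(info$name))
    msg <- c(msg, "segment names must be unique")
  if (!all(info$segment_class %in% c("V", "D", "J")))
    msg <- c(msg, "segment_class must be one of V, D, J")
  for (cl in c("V", "D", "J")) {
    idx <- info$genomic_order_index[info$segment_class == cl]
    if (length(idx) == 0) {
      msg <- c(msg, paste0("no segments of class ", cl))
    } else if (!setequal(idx, seq_along(idx) - 1L)) {
      msg <- c(msg, paste0("genomic_order_index for class ", cl,
                           " is not a permutation of 0..", length(idx) - 1L))
    }
  }
  if (length(seqs)) {
    bad <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)[, "other"] > 0
    if (any(bad))
      msg <- c(msg, paste("non-ACGT characters in:",
                          paste(info$name[bad], collapse = ", ")))
    if (any(Biostrings::width(seqs) == 0))
      msg <- c(msg, "empty sequences are not allowed")
  }
  fam <- tryCatch(familyOf(info$name), error = function(e) NULL)
  if (is.null(fam)) {
    msg <- c(msg, "some segment names do not follow IGH[VDJ]<k> naming")
  } else if (!identical(fam, info$family)) {
    msg <- c(msg, "family column disagrees with familyOf(name)")
  }
  isV <- info$segment_class == "V"
  if (any(isV)) {
    b <- cbind(info$fr1_start, info$cdr1_start, info$fr2_start,
               info$cdr2_start, info$fr3_start, info$cdr3_anchor)[isV, , drop = FALSE]
    if (anyNA(b)) {
      msg <- c(msg, "every V segment needs complete region boundaries")
    } else {
      ordered <- apply(b, 1, function(x) all(diff(x) > 0)) & b[, 1] == 0
      within <- b[, 6] + 3 <= Biostrings::width(seqs)[isV]
      if (!all(ordered))
        msg <- c(msg, "V region boundaries must be increasing from 0")
      if (!all(within))
        msg <- c(msg, "cdr3_anchor codon must lie within the V sequence")
    }
  }
  isJ <- info$segment_class == "J"
  if (any(isJ)) {
    a <- info$j_trp_anchor[isJ]
    if (anyNA(a) || any(a + 3 > Biostrings::width(seqs)[isJ]))
      msg <- c(msg, "every J segment needs a j_trp_anchor within the sequence")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn GermlineReference-class compact summary of the reference
#' @param object a `GermlineReference`
#' @export
setMethod("show", "GermlineReference", function(object) {
  info <- object@info
  cat("GermlineReference with", nrow(info), "segments\n")
  for (cl in c("V", "D", "J")) {
    fams <- sort(unique(info$family[info$segment_class == cl]))
    cat(sprintf("  %s: %d genes, %d families (%s)\n", cl,
                sum(info$segment_class == cl), length(fams),
                paste(fams, collapse = ", ")))
  }
  cat("  provenance:", object@provenance, "\n")
})

#' SimulationConfig: parameters of a synthetic single-cell repertoire
#'
#' Holds every knob of the V(D)J repertoire simulator. Constructed with
#' [simulationConfig()], which supplies the calibrated presets; slots mirror
#' the biology being emulated:
#'
#' * `vUsage`/`dUsage`/`jUsage` -- segment-choice probabilities (named by gene).
#' * `trimMax` -- maximum exonucleolytic trim (nt) at each joined segment end.
#' * `nAdditionMean` -- mean of the geometric N-region length distribution at
#'   each junction.
#' * `shmRateRange`, `shmRateModel` -- per-sequence somatic hypermutation rate,
#'   drawn uniformly from the range or from the `"ptec"` mixture that places
#'   60% of its mass on 5-10%.
#' * `hotspotBias`, `cdrBias` -- relative mutation-rate multipliers for
#'   positions inside RGYW/WRCY hotspot motifs and inside CDRs.
#' * `pNonfunctional` -- probability a rearrangement is made nonfunctional
#'   (stop codon or frameshift, equiprobable).
#' * `patternsPerCellDist` -- probabilities that a cell carries 1, 2 or 3
#'   distinct rearrangement patterns.
#' * `pSharedClone` -- probability a new rearrangement reuses a clone from the
#'   global pool, producing identical-junction sharing within and across
#'   donors.
#' * `colonyErrorRate` -- optional per-base error applied independently per
#'   cloned colony (0 = exact copies).
#'
#' @seealso [simulationConfig()], [simulateRepertoire()]
#' @export
setClass("SimulationConfig",
  slots = c(seed = "integer", nDonors = "integer", cellsPerDonor = "integer",
            coloniesPerCell = "integer", vUsage = "numeric",
            dUsage = "numeric", jUsage = "numeric", trimMax = "integer",
            nAdditionMean = "numeric", shmRateRange = "numeric",
            shmRateModel = "character", hotspotBias = "numeric",
            cdrBias = "numeric", pNonfunctional = "numeric",
            patternsPerCellDist = "numeric", pSharedClone = "numeric",
            colonyErrorRate = "numeric", preset = "character"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  for (nm in c("vUsage", "dUsage", "jUsage")) {
    p <- slot(object, nm)
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      msg <- c(msg, paste(nm, "must be a named probability vector summing to 1"))
  }
  d <- object@patternsPerCellDist
  if (length(d) != 3 || any(d < 0) || abs(sum(d) - 1) > 1e-9)
    msg <- c(msg, "patternsPerCellDist must be 3 probabilities summing to 1")
  rates <- c(object@pNonfunctional, object@pSharedClone, object@colonyErrorRate,
             object@shmRateRange)
  if (any(rates < 0) || any(rates > 1))
    msg <- c(msg, "all rates must lie in [0, 1]")
  if (length(object@shmRateRange) != 2 ||
      object@shmRateRange[1] > object@shmRateRange[2])
    msg <- c(msg, "shmRateRange must be an increasing interval")
  if (object@trimMax < 0) msg <- c(msg, "trimMax must be >= 0")
  if (object@hotspotBias < 0 || object@cdrBias < 0)
    msg <- c(msg, "bias multipliers must be >= 0")
  if (length(object@coloniesPerCell) != 2 ||
      object@coloniesPerCell[1] > object@coloniesPerCell[2] ||
      object@coloniesPerCell[1] < 1)
    msg <- c(msg, "coloniesPerCell must be a valid integer range")
  if (!object@shmRateModel %in% c("uniform", "ptec"))
    msg <- c(msg, "shmRateModel must be 'uniform' or 'ptec'")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn SimulationConfig-class compact summary of the configuration
#' @param object a `SimulationConfig`
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig (preset:", object@preset, ")\n")
  cat(sprintf("  %d donors x %d cells, %d-%d colonies/cell, seed %d\n",
              object@nDonors, object@cellsPerDonor, object@coloniesPerCell[1],
              object@coloniesPerCell[2], object@seed))
  cat(sprintf("  SHM %.1f-%.1f%% (%s), hotspot bias %.1f, CDR bias %.1f\n",
              100 * object@shmRateRange[1], 100 * object@shmRateRange[2],
              object@shmRateModel, object@hotspotBias, object@cdrBias))
  cat(sprintf("  p(nonfunctional) %.3f, p(shared clone) %.2f, patterns/cell %s\n",
              object@pNonfunctional, object@pSharedClone,
              paste(round(object@patternsPerCellDist, 3), collapse = "/")))
})
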
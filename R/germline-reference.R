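#' Load a germline V/D/J segment reference
#'
#' Reads a reference FASTA of germline IGHV/IGHD/IGHJ sequences together with a
#' tab-separated metadata table and returns a validated [GermlineReference].
#' FASTA records and metadata rows are keyed by identical gene names; the
#' metadata supplies segment class, genomic order and region boundaries
#' (0-based half-open; see the class documentation for the column meanings).
#'
#' The package ships a small curated reference under
#' `system.file("extdata", package = "scIgRep")`: one allele per gene,
#' 28 V / 15 D / 6 J segments spanning VH families 1-7, DH1-7 and JH1-6 with
#' IMGT-style names and real-locus genomic ordering. Its sequences are
#' synthetic (deterministically generated with the IMGT region architecture and
#' conserved Cys/Trp anchors), as flagged by the `germline_synthetic.*`
#' filenames; gene-level analyses behave as with a curated biological set, but
#' it is a functional stand-in, not a database mirror.
#'
#' @param fastaPath path to the reference FASTA.
#' @param metadataPath path to the tab-separated metadata table with columns
#'   `name`, `segment_class`, `family`, `genomic_order_index`, the V boundary
#'   columns (`fr1_start`, `cdr1_start`, `fr2_start`, `cdr2_start`,
#'   `fr3_start`, `cdr3_anchor`) and `j_trp_anchor`.
#' @param provenance free-text description recorded in the object.
#' @return a validated [GermlineReference].
#' @examples
#' ref <- loadGermlineReference(
#'   system.file("extdata", "germline_synthetic.fasta", package = "scIgRep"),
#'   system.file("extdata", "germline_synthetic_meta.tsv", package = "scIgRep"))
#' ref
#' @export
loadGermlineReference <- function(fastaPath, metadataPath,
                                  provenance = "packaged synthetic reference") {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  if (length(seqs) == 0)
    stop("no segments: reference FASTA '", fastaPath, "' contains no records")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  meta <- utils::read.delim(metadataPath, stringsAsFactors = FALSE)
  missing <- setdiff(names(seqs), meta$name)
  if (length(missing))
    stop("missing metadata for FASTA record(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(meta$name, names(seqs))
  if (length(extra))
    stop("metadata row(s) without FASTA record: ", paste(extra, collapse = ", "))
  af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  if (any(af[, "other"] > 0)) {
    bad <- which(af[, "other"] > 0)[1]
    pos <- which(!strsplit(as.character(seqs[[bad]]), "")[[1]] %in%
                   c("A", "C", "G", "T"))[1]
    stop("alphabet violation in '", names(seqs)[bad], "' at position ", pos - 1L)
  }
  meta <- meta[match(names(seqs), meta$name), ]
  intcols <- intersect(c("genomic_order_index", "fr1_start", "cdr1_start",
                         "fr2_start", "cdr2_start", "fr3_start", "cdr3_anchor",
                         "j_trp_anchor"), colnames(meta))
  for (cc in intcols) meta[[cc]] <- as.integer(meta[[cc]])
  obj <- new("GermlineReference", sequences = seqs,
             info = S4Vectors::DataFrame(meta), provenance = provenance)
  validObject(obj)
  obj
}

#' Write a germline reference back to FASTA + metadata
#'
#' Inverse of [loadGermlineReference()]; a load -> write -> load round trip is
#' the identity on all fields.
#'
#' @param reference a [GermlineReference].
#' @param fastaPath,metadataPath output paths.
#' @return invisibly, the two paths.
#' @export
writeGermlineReference <- function(reference, fastaPath, metadataPath) {
  Biostrings::writeXStringSet(reference@sequences, fastaPath, width = 60)
  utils::write.table(as.data.frame(reference@info), metadataPath, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(c(fastaPath, metadataPath))
}

#' Gene family of an IMGT-style segment name
#'
#' Maps names like `"IGHV1-24"`, `"IGHD2-15"`, `"IGHJ4"` to the family labels
#' used in repertoire usage reports: `"VH1"`, `"DH2"`, `"JH4"`. The family
#' number is the integer immediately after the class letter.
#'
#' @param geneName character vector of IMGT-style names.
#' @return character vector of family labels.
#' @examples
#' familyOf(c("IGHV1-24", "IGHD2-15", "IGHJ4"))
#' @export
familyOf <- function(geneName) {
  m <- regmatches(geneName, regexec("^IGH([VDJ])([0-9]+)", geneName))
  bad <- lengths(m) != 3
  if (any(bad))
    stop("unparseable gene name(s): ", paste(geneName[bad], collapse = ", "))
  vapply(m, function(x) paste0(x[2], "H", x[3]), "")
}

#' Genomic rank of a gene along the IGH locus
#'
#' Returns the `genomic_order_index` of a gene: its rank along the locus within
#' its segment class, with 0 = most 3' (JH-proximal for V genes).
#'
#' @param reference a [GermlineReference].
#' @param geneName gene name(s) present in the reference.
#' @return integer vector of ranks.
#' @export
genomicRank <- function(reference, geneName) {
  idx <- match(geneName, reference@info$name)
  if (anyNA(idx))
    stop("unknown gene(s): ", paste(geneName[is.na(idx)], collapse = ", "))
  reference@info$genomic_order_index[idx]
}

#' Segment names of one class
#'
#' @param reference a [GermlineReference].
#' @param segmentClass `"V"`, `"D"` or `"J"`.
#' @return character vector of gene names.
#' @export
segmentNames <- function(reference, segmentClass = c("V", "D", "J")) {
  segmentClass <- match.arg(segmentClass)
  reference@info$name[reference@info$segment_class == segmentClass]
}

#' Sequence of one or more germline segments
#'
#' @param reference a [GermlineReference].
#' @param geneName gene name(s).
#' @return a [Biostrings::DNAStringSet].
#' @export
segmentSeq <- function(reference, geneName) {
  idx <- match(geneName, reference@info$name)
  if (anyNA(idx))
    stop("unknown gene(s): ", paste(geneName[is.na(idx)], collapse = ", "))
  reference@sequences[idx]
}

#' Per-segment metadata table
#'
#' @param reference a [GermlineReference].
#' @return the metadata as a base `data.frame`.
#' @export
segmentInfo <- function(reference) as.data.frame(reference@info)

# Region labels for each position of a V segment (internal).
# Returns a character vector over 0..width-1: FR1/CDR1/FR2/CDR2/FR3 per the
# boundary columns; the conserved Cys codon counts as FR3 and the germline
# CDR3 tail beyond it as CDR3.
vRegionLabels <- function(reference, vName) {
  i <- match(vName, reference@info$name)
  stopifnot(!is.na(i), reference@info$segment_class[i] == "V")
  inf <- reference@info[i, ]
  w <- Biostrings::width(reference@sequences)[i]
  lab <- character(w)
  lab[seq_len(w)] <- "CDR3"
  set <- function(lab, from, to, what) { lab[(from + 1):to] <- what; lab }
  lab <- set(lab, inf$fr1_start, inf$cdr1_start, "FR1")
  lab <- set(lab, inf$cdr1_start, inf$fr2_start, "CDR1")
  lab <- set(lab, inf$fr2_start, inf$cdr2_start, "FR2")
  lab <- set(lab, inf$cdr2_start, inf$fr3_start, "CDR2")
  lab <- set(lab, inf$fr3_start, min(inf$cdr3_anchor + 3L, w), "FR3")
  lab
}
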
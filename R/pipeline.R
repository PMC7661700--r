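#' Write annotations as an AIRR-style rearrangement TSV
#'
#' Serializes an [annotateRepertoire()] result to a tab-separated file using
#' AIRR community column names where the concept maps cleanly (`sequence_id`,
#' `v_call`, `d_call`, `j_call`, `junction`, `productive`, `np1`/`np2` for the
#' N regions); package-specific extensions (`cdr3_nt`, `mutation_frequency`,
#' `mutated_status`, `donor_id`, `cell_id`, region column counts) ride along.
#' The per-mutation list-column is flattened to `pos:ref>obs:region:hot`
#' tokens so the table round-trips through [readRearrangementTSV()].
#'
#' @param annotations an [annotateRepertoire()] result.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeRearrangementTSV <- function(annotations, path) {
  df <- as.data.frame(annotations[, setdiff(colnames(annotations), "mutations")])
  names(df)[names(df) == "n1_seq"] <- "np1"
  names(df)[names(df) == "n2_seq"] <- "np2"
  df$mutation_records <- vapply(annotations$mutations, function(m) {
    if (is.null(m) || nrow(m) == 0) return("")
    paste(sprintf("%d:%s>%s:%s:%d", m$query_pos, m$germline_base,
                  m$observed_base, m$region, as.integer(m$in_hotspot)),
          collapse = ";")
  }, "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read an AIRR-style rearrangement TSV written by this package
#'
#' @param path file path.
#' @return a [S4Vectors::DataFrame] mirroring the [annotateRepertoire()]
#'   layout, with the `mutations` list-column rebuilt.
#' @export
readRearrangementTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "v_call", "d_call", "j_call", "np1", "np2",
            "productive", "mutation_frequency")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("rearrangement TSV is missing column(s): ",
         paste(miss, collapse = ", "))
  if ("cdr3_aa" %in% colnames(df)) df$cdr3_aa <- as.character(df$cdr3_aa)
  for (cc in c("np1", "np2", "donor_id", "cell_id", "cdr3_nt", "junction")) {
    if (!cc %in% colnames(df)) next
    df[[cc]] <- as.character(df[[cc]])
    df[[cc]][is.na(df[[cc]])] <- ""
  }
  muts <- lapply(df$mutation_records, function(x) {
    if (is.na(x) || x == "")
      return(data.frame(query_pos = integer(), germline_base = character(),
                        observed_base = character(), region = character(),
                        in_hotspot = logical(), stringsAsFactors = FALSE))
    parts <- strsplit(strsplit(x, ";")[[1]], "[:>]")
    data.frame(query_pos = as.integer(vapply(parts, `[`, "", 1)),
               germline_base = vapply(parts, `[`, "", 2),
               observed_base = vapply(parts, `[`, "", 3),
               region = vapply(parts, `[`, "", 4),
               in_hotspot = vapply(parts, `[`, "", 5) == "1",
               stringsAsFactors = FALSE)
  })
  df$mutation_records <- NULL
  names(df)[names(df) == "np1"] <- "n1_seq"
  names(df)[names(df) == "np2"] <- "n2_seq"
  out <- S4Vectors::DataFrame(df)
  out$mutations <- muts
  out
}

.writeManifest <- function(dir, step, params, inputs = character()) {
  manifest <- list(
    step = step, package = "scIgRep",
    version = as.character(utils::packageVersion("scIgRep")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])))
  jsonlite::write_json(manifest, file.path(dir, paste0(step, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Simulate a repertoire and write it to files
#'
#' Runs [simulateRepertoire()] and writes `repertoire.fasta`, `truth.tsv` and
#' a provenance manifest (seed, preset, package version) into `outDir`.
#' Reruns with the same config produce byte-identical FASTA and truth tables.
#'
#' @param reference a [GermlineReference].
#' @param config a [SimulationConfig].
#' @param outDir output directory, created if needed.
#' @return invisibly, the [simulateRepertoire()] result.
#' @export
runSimulate <- function(reference, config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  sim <- simulateRepertoire(reference, config)
  Biostrings::writeXStringSet(sim$sequences, file.path(outDir, "repertoire.fasta"),
                              width = 70)
  utils::write.table(sim$truth, file.path(outDir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .writeManifest(outDir, "simulate",
                 list(seed = config@seed, preset = config@preset,
                      n_donors = config@nDonors,
                      cells_per_donor = config@cellsPerDonor,
                      n_sequences = length(sim$sequences)))
  invisible(sim)
}

#' Annotate a repertoire FASTA and write the rearrangement table
#'
#' Reads rearranged sequences, annotates them against the reference and
#' writes an AIRR-style TSV plus a manifest. When a simulator truth table is
#' supplied, an accuracy report (V/D/J call agreement and junction recovery
#' against truth) is also written.
#'
#' @param fastaPath input FASTA of rearranged sequences.
#' @param reference a [GermlineReference].
#' @param outPath output TSV path.
#' @param truthPath optional truth TSV from [runSimulate()].
#' @inheritParams assignSegments
#' @return invisibly, the annotation [S4Vectors::DataFrame] (with an
#'   `accuracy` attribute when truth was supplied).
#' @export
runAnnotate <- function(fastaPath, reference, outPath, truthPath = NULL,
                        minScore = 40, dMinMatch = 5) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  if (length(seqs) == 0) {
    warning("input FASTA has no records; writing header-only table")
    ann <- annotateRepertoire(Biostrings::DNAStringSet(), reference)
  } else {
    ann <- annotateRepertoire(seqs, reference, minScore = minScore,
                              dMinMatch = dMinMatch)
  }
  writeRearrangementTSV(ann, outPath)
  outDir <- dirname(outPath)
  acc <- NULL
  if (!is.null(truthPath)) {
    truth <- utils::read.delim(truthPath, stringsAsFactors = FALSE,
                               colClasses = c(n1_seq = "character",
                                              n2_seq = "character",
                                              donor_id = "character"))
    truth$n1_seq[is.na(truth$n1_seq)] <- ""
    truth$n2_seq[is.na(truth$n2_seq)] <- ""
    i <- match(ann$sequence_id, truth$sequence_id)
    ok <- !is.na(i)
    acc <- list(
      n = sum(ok),
      v_accuracy = mean(ann$v_call[ok] == truth$v_name[i][ok], na.rm = TRUE),
      j_accuracy = mean(ann$j_call[ok] == truth$j_name[i][ok], na.rm = TRUE),
      d_accuracy = mean((ann$d_call[ok] == truth$d_name[i][ok])[
        ann$d_call[ok] != "unassigned"], na.rm = TRUE),
      junction_recovery = mean(ann$n1_seq[ok] == truth$n1_seq[i][ok] &
                                 ann$n2_seq[ok] == truth$n2_seq[i][ok],
                               na.rm = TRUE))
    jsonlite::write_json(acc, file.path(outDir, "accuracy.json"),
                         auto_unbox = TRUE, digits = NA)
    attr(ann, "accuracy") <- acc
  }
  .writeManifest(outDir, "annotate",
                 list(min_score = minScore, d_min_match = dMinMatch,
                      n_sequences = nrow(ann)),
                 inputs = c(fastaPath, truthPath))
  invisible(ann)
}

#' Analyze an annotated repertoire and write summary reports
#'
#' Drives the downstream statistics over a rearrangement table: productivity,
#' patterns per cell, shared identical-junction sets, gene- and family-level
#' usage, genomic V distribution, SHM frequency distribution, hotspot
#' fraction, CDR-versus-FR rates and the CDR3 length Gaussian fit. Writes
#' `summary.json`, `patterns.tsv`, `shared_sets.tsv`, usage tables, and, when
#' a comparison table is given, a chi-square family-usage comparison block.
#'
#' @param annPath rearrangement TSV from [runAnnotate()].
#' @param outDir output directory.
#' @param reference a [GermlineReference].
#' @param comparePath optional second rearrangement TSV to compare usage
#'   against.
#' @return invisibly, the summary list.
#' @export
runAnalyze <- function(annPath, outDir, reference, comparePath = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ann <- readRearrangementTSV(annPath)
  if (nrow(ann) == 0) stop("no rearrangements in ", annPath)
  patterns <- dedupeCellPatterns(ann)
  shared <- sharedRearrangements(patterns)
  summary <- list(
    n_sequences = nrow(ann),
    productivity = productivityFraction(ann),
    patterns_per_cell = patternsPerCell(patterns),
    n_shared_sets = nrow(shared),
    n_shared_cross_donor = sum(shared$cross_donor),
    shm = tryCatch(shmDistribution(ann$mutation_frequency),
                   error = function(e) NULL),
    hotspot = hotspotFraction(ann)[c("pooled", "n_mutations")],
    region_rates = tryCatch({
      rr <- regionMutationRates(ann)
      c(list(mean_cdr_rate = mean(rr$per_sequence$cdr_rate),
             mean_fr_rate = mean(rr$per_sequence$fr_rate)), rr$paired_t)
    }, error = function(e) NULL),
    cdr3_fit = tryCatch({
      lens <- nchar(ann$cdr3_aa[ann$productive & !is.na(ann$cdr3_aa) &
                                  nchar(ann$cdr3_aa) > 0])
      fit <- cdr3GaussianFit(lens)
      fit[c("amplitude", "mean", "sd", "r_squared", "n")]
    }, error = function(e) NULL))
  vUse <- usageFrequencies(patterns, "gene", "V")
  vFam <- usageFrequencies(patterns, "family", "V")
  summary$v_family_usage <- setNames(as.list(vFam$table$frequency),
                                     vFam$table$label)
  summary$genomic_concentration <-
    genomicDistribution(vUse, reference)$concentration
  if (!is.null(comparePath)) {
    cmp <- readRearrangementTSV(comparePath)
    cmpPat <- dedupeCellPatterns(cmp)
    summary$chi_square_v_family <- chiSquareUsage(
      vFam, usageFrequencies(cmpPat, "family", "V"))[
        c("statistic", "df", "p_value")]
  }
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.table(patterns, file.path(outDir, "patterns.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(shared, file.path(outDir, "shared_sets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (cl in c("V", "D", "J")) {
    u <- tryCatch(usageFrequencies(patterns, "family", cl),
                  error = function(e) NULL)
    if (!is.null(u))
      utils::write.table(u$table,
                         file.path(outDir, paste0("usage_", cl, "_family.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .writeManifest(outDir, "analyze", list(annotations = basename(annPath)),
                 inputs = c(annPath, comparePath))
  invisible(summary)
}
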
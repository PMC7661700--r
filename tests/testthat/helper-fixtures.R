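# Shared fixtures, memoized so expensive simulations/annotations run once
# per test session.
.fx <- new.env(parent = emptyenv())

fxRef <- function() {
  if (is.null(.fx$ref)) .fx$ref <- exampleReference()
  .fx$ref
}

# clean repertoire: no SHM, all productive -- exact-recovery oracle
fxSim0 <- function() {
  if (is.null(.fx$sim0)) {
    cfg <- simulationConfig(fxRef(), "ptec-like", seed = 12,
                            cellsPerDonor = 10, shmRateRange = c(0, 0),
                            pNonfunctional = 0)
    .fx$sim0 <- simulateRepertoire(fxRef(), cfg)
  }
  .fx$sim0
}

fxAnn0 <- function() {
  if (is.null(.fx$ann0)) .fx$ann0 <- annotateRepertoire(fxSim0()$sequences, fxRef())
  .fx$ann0
}

# hypermutated repertoire under study-condition defaults (hotspot + CDR bias,
# clonal sharing, nonfunctional fraction)
fxSimShm <- function() {
  if (is.null(.fx$simShm)) {
    cfg <- simulationConfig(fxRef(), "ptec-like", seed = 11, cellsPerDonor = 15)
    .fx$simShm <- simulateRepertoire(fxRef(), cfg)
  }
  .fx$simShm
}

fxAnnShm <- function() {
  if (is.null(.fx$annShm))
    .fx$annShm <- annotateRepertoire(fxSimShm()$sequences, fxRef())
  .fx$annShm
}

# independent brute-force hotspot oracle: test every 4-nt window of the
# sequence against the degenerate motifs by explicit set membership
bruteHotspotMask <- function(seq, aidTarget = FALSE) {
  s <- strsplit(seq, "")[[1]]
  L <- length(s)
  mask <- rep(FALSE, L)
  isR <- function(b) b == "A" || b == "G"
  isY <- function(b) b == "C" || b == "T"
  isW <- function(b) b == "A" || b == "T"
  if (L < 4) return(mask)
  for (i in 1:(L - 3)) {
    w <- s[i:(i + 3)]
    rgyw <- isR(w[1]) && w[2] == "G" && isY(w[3]) && isW(w[4])
    wrcy <- isW(w[1]) && isR(w[2]) && w[3] == "C" && isY(w[4])
    if (aidTarget) {
      if (rgyw) mask[i + 1] <- TRUE
      if (wrcy) mask[i + 2] <- TRUE
    } else if (rgyw || wrcy) {
      mask[i:(i + 3)] <- TRUE
    }
  }
  mask
}

randSeq <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

randSeqWithSeed <- function(n, seed) {
  set.seed(seed)
  randSeq(n)
}

# integer range that is empty when from > to
seq2 <- function(from, to) if (from > to) integer() else seq(from, to)

# patterns-per-cell layout straight from a simulator truth table (one row per
# distinct clone per cell), for generator-recovery checks that do not need
# the annotator
truthPatterns <- function(truth) {
  key <- paste(truth$cell_id, truth$clone_id, truth$v_name, truth$d_name,
               truth$j_name, truth$n1_seq, truth$n2_seq, sep = "|")
  out <- truth[!duplicated(key),
               c("donor_id", "cell_id", "v_name", "d_name", "j_name",
                 "n1_seq", "n2_seq")]
  names(out) <- c("donor_id", "cell_id", "v_call", "d_call", "j_call",
                  "n1_seq", "n2_seq")
  rownames(out) <- NULL
  out
}
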
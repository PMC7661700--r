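test_that("recombination with zero trims and empty N is exact concatenation", {
  ref <- fxRef()
  v <- unname(as.character(segmentSeq(ref, "IGHV1-24")))
  d <- unname(as.character(segmentSeq(ref, "IGHD2-15")))
  j <- unname(as.character(segmentSeq(ref, "IGHJ4")))
  asm <- recombineSegments(ref, "IGHV1-24", "IGHD2-15", "IGHJ4")
  expect_identical(asm$sequence, paste0(v, d, j))
  expect_identical(nchar(asm$sequence), nchar(v) + nchar(d) + nchar(j))
  expect_identical(asm$record$v_end, nchar(v))
  expect_identical(asm$record$d_start, nchar(v))
})

test_that("junction strings sit verbatim between the retained segment parts", {
  ref <- fxRef()
  asm <- recombineSegments(ref, "IGHV1-24", "IGHD2-15", "IGHJ4",
                           n1 = "TT", n2 = "ACCCGATCCGAC")
  rec <- asm$record
  expect_identical(substr(asm$sequence, rec$v_end + 1, rec$d_start), "TT")
  expect_identical(substr(asm$sequence, rec$d_end + 1, rec$j_start),
                   "ACCCGATCCGAC")
  expect_true(grepl("TT", asm$sequence, fixed = TRUE))
  expect_true(grepl("ACCCGATCCGAC", asm$sequence, fixed = TRUE))
})

test_that("invalid trims and N alphabets are rejected", {
  ref <- fxRef()
  dLen <- nchar(as.character(segmentSeq(ref, "IGHD2-15")))
  expect_error(recombineSegments(ref, "IGHV1-24", "IGHD2-15", "IGHJ4",
                                 dTrim5 = dLen, dTrim3 = 1), "D trims")
  expect_error(recombineSegments(ref, "IGHV1-24", "IGHD2-15", "IGHJ4",
                                 vTrim3 = -1), "non-negative")
  expect_error(recombineSegments(ref, "IGHV1-24", "IGHD2-15", "IGHJ4",
                                 n1 = "TN"), "A,C,G,T")
  expect_error(recombineSegments(ref, "IGHV9-99", "IGHD2-15", "IGHJ4"),
               "IGHV9-99")
})

test_that("zero-rate SHM is the identity with an empty mutation list", {
  s <- randSeq(300)
  out <- applySHM(s, targetRate = 0)
  expect_identical(out$sequence, s)
  expect_identical(nrow(out$mutations), 0L)
  expect_error(applySHM(s, targetRate = 0.5), "0.25")
})

test_that("unbiased SHM matches the binomial expectation", {
  set.seed(401)
  L <- 300; r <- 0.08; reps <- 1000
  s <- randSeq(L)
  counts <- replicate(reps, nrow(applySHM(s, r)$mutations))
  # per sequence the count is Binomial(L, r); compare the Monte-Carlo mean
  expect_lt(abs(mean(counts) - r * L), 3 * sd(counts) / sqrt(reps))
  # substitutions never keep the germline base
  one <- applySHM(s, 0.15)$mutations
  expect_true(all(one$germline_base != one$mutated_base))
  expect_identical(substring(s, one$position + 1, one$position + 1),
                   one$germline_base)
})

test_that("hotspot weighting concentrates mutations per the closed form", {
  set.seed(402)
  s <- randSeq(600)
  f <- mean(scanHotspots(s))
  bias <- 10
  expectedFrac <- bias * f / (bias * f + (1 - f))
  hot <- 0; tot <- 0
  for (k in 1:400) {
    m <- applySHM(s, 0.05, hotspotBias = bias)$mutations
    if (nrow(m) == 0) next
    hot <- hot + sum(scanHotspots(s)[m$position + 1])
    tot <- tot + nrow(m)
  }
  se <- sqrt(expectedFrac * (1 - expectedFrac) / tot)
  expect_lt(abs(hot / tot - expectedFrac), 3 * se)
})

test_that("deliberate nonfunctionalization produces the advertised defects", {
  ref <- fxRef()
  set.seed(403)
  asm <- recombineSegments(ref, "IGHV1-18", "IGHD3-3", "IGHJ6",
                           n1 = "AC", n2 = "GGA")
  none <- makeNonfunctional(ref, asm, "none")
  expect_identical(none$sequence, asm$sequence)

  st <- makeNonfunctional(ref, asm, "stop")
  starts <- seq(1, nchar(st$sequence) - 2, by = 3)
  codons <- substring(st$sequence, starts, starts + 2)
  trpCodon <- asm$record$trp_pos %/% 3
  expect_true(any(codons[seq_len(trpCodon)] %in% c("TAA", "TAG", "TGA")))
  # recorded substitutions reproduce the broken sequence from the clean one
  s <- strsplit(asm$sequence, "")[[1]]
  s[st$mutations$position + 1] <- st$mutations$mutated_base
  expect_identical(paste0(s, collapse = ""), st$sequence)

  fs <- makeNonfunctional(ref, asm, "frameshift")
  delta <- nchar(fs$record$n2_seq) - nchar(asm$record$n2_seq)
  expect_true(abs(delta) == 1)
  # a one-base junction change must move the conserved Trp out of the
  # original reading frame
  expect_true(fs$record$trp_pos %% 3 != asm$record$trp_pos %% 3)
})

test_that("simulation is byte-deterministic given the seed", {
  ref <- fxRef()
  cfg <- simulationConfig(ref, "ptec-like", seed = 7, cellsPerDonor = 4)
  s1 <- simulateRepertoire(ref, cfg)
  s2 <- simulateRepertoire(ref, cfg)
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  expect_identical(s1$truth, s2$truth)
})

test_that("every truth row reconstructs its emitted sequence exactly", {
  ref <- fxRef()
  sim <- fxSimShm()
  rebuilt <- vapply(seq_len(nrow(sim$truth)), function(i)
    reconstructFromTruth(ref, sim$truth[i, ]), "")
  expect_identical(rebuilt, sim$truth$full_sequence)
  expect_identical(unname(as.character(sim$sequences)),
                   sim$truth$full_sequence)
})

test_that("colony noise is recorded so truth still reconstructs", {
  ref <- fxRef()
  cfg <- simulationConfig(ref, "ptec-like", seed = 8, cellsPerDonor = 3,
                          colonyErrorRate = 0.01)
  sim <- simulateRepertoire(ref, cfg)
  rebuilt <- vapply(seq_len(nrow(sim$truth)), function(i)
    reconstructFromTruth(ref, sim$truth[i, ]), "")
  expect_identical(rebuilt, sim$truth$full_sequence)
})

test_that("per-sequence SHM rates follow the configured model", {
  ref <- fxRef()
  cfg <- simulationConfig(ref, "ptec-like", seed = 9, cellsPerDonor = 150,
                          coloniesPerCell = c(1, 1),
                          patternsPerCellDist = c(1, 0, 0))
  sim <- simulateRepertoire(ref, cfg)
  r <- sim$truth$shm_rate
  expect_true(all(r >= 0.029 & r <= 0.205))
  inBand <- mean(r >= 0.05 & r <= 0.10)
  se <- sqrt(0.6 * 0.4 / length(r))
  expect_lt(abs(inBand - 0.6), 3 * se)
  # uniform model spans the range evenly
  cfgU <- simulationConfig(ref, "bcell-like", seed = 9, cellsPerDonor = 100,
                           coloniesPerCell = c(1, 1))
  rU <- simulateRepertoire(ref, cfgU)$truth$shm_rate
  expect_true(all(rU >= 0.029 & rU <= 0.205))
})

test_that("usage vectors naming unknown genes are rejected", {
  ref <- fxRef()
  cfg <- simulationConfig(ref, "ptec-like", seed = 1, cellsPerDonor = 2)
  v <- cfg@vUsage
  names(v)[1] <- "IGHV9-99"
  cfg@vUsage <- v
  expect_error(simulateRepertoire(ref, cfg), "absent from the reference")
})

test_that("config validity catches malformed probability inputs", {
  ref <- fxRef()
  expect_error(simulationConfig(ref, "ptec-like",
                                patternsPerCellDist = c(0.9, 0.2, 0.1)),
               "summing to 1")
  expect_error(simulationConfig(ref, "ptec-like", pNonfunctional = 1.5),
               "\\[0, 1\\]")
  expect_error(simulationConfig(ref, "ptec-like", nonsense = 1), "nonsense")
})
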
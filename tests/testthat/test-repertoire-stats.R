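test_that("detection rates reproduce the single-cell survey arithmetic", {
  cells <- data.frame(
    donor_id = rep(c("1", "2"), c(49, 62)),
    positive = c(rep(c(TRUE, FALSE), c(45, 4)), rep(c(TRUE, FALSE), c(46, 16))))
  dr <- detectionRate(cells)
  expect_identical(dr$pooled$positive, 91L)
  expect_identical(dr$pooled$total, 111L)
  expect_identical(dr$pooled$percent, 82)
  expect_identical(dr$per_donor$percent, c(91.8, 74.2))
  # exact rational values retained alongside the printed rounding
  expect_equal(dr$pooled$percent_exact, 91 / 111 * 100)

  none <- detectionRate(data.frame(donor_id = "1", positive = rep(FALSE, 10)))
  expect_identical(none$per_donor$percent, 0)
  expect_error(detectionRate(data.frame(donor_id = character(),
                                        positive = logical())), "no cells")
})

test_that("usage tables count per pattern with unassigned D set aside", {
  pat <- data.frame(
    donor_id = "1", cell_id = c("1-1", "1-2", "1-3"),
    v_call = c("IGHV1-24", "IGHV1-18", "IGHV3-23"),
    d_call = c("IGHD2-15", "unassigned", "IGHD3-3"),
    j_call = c("IGHJ4", "IGHJ6", "IGHJ4"), stringsAsFactors = FALSE)
  fam <- usageFrequencies(pat, "family", "V")
  expect_equal(fam$table$frequency[fam$table$label == "VH1"], 2 / 3)
  expect_equal(fam$table$frequency[fam$table$label == "VH3"], 1 / 3)
  expect_equal(sum(fam$table$frequency), 1)

  d <- usageFrequencies(pat, "gene", "D")
  expect_identical(d$n, 2L)
  expect_identical(d$n_unassigned, 1L)

  allUn <- pat; allUn$d_call <- "unassigned"
  dEmpty <- usageFrequencies(allUn, "gene", "D")
  expect_identical(nrow(dEmpty$table), 0L)
  expect_identical(dEmpty$n_unassigned, 3L)
  expect_error(usageFrequencies(pat[0, ], "gene", "V"), "no assigned")
})

test_that("usage recovered from a simulated preset matches its parameters", {
  ref <- fxRef()
  cfg <- simulationConfig(ref, "ptec-like", seed = 21, cellsPerDonor = 250,
                          coloniesPerCell = c(1, 1),
                          patternsPerCellDist = c(1, 0, 0), pSharedClone = 0)
  sim <- simulateRepertoire(ref, cfg)
  pat <- truthPatterns(sim$truth)
  fam <- usageFrequencies(pat, "family", "V")
  n <- fam$n
  famTarget <- tapply(cfg@vUsage, familyOf(names(cfg@vUsage)), sum)
  for (f in names(famTarget)) {
    p <- famTarget[[f]]
    obs <- fam$table$frequency[fam$table$label == f]
    obs <- if (length(obs)) obs else 0
    if (p == 0) expect_identical(obs, 0)
    else expect_lt(abs(obs - p), max(3 * sqrt(p * (1 - p) / n), 3 / n),
                   label = f)
  }
  # VH1 dominance as printed for this cell type
  expect_lt(abs(famTarget[["VH1"]] - 0.71), 0.005)
})

test_that("chi-square usage comparison follows the Pearson formula", {
  a <- data.frame(label = c("VH1", "VH3"), count = c(10L, 20L))
  b <- data.frame(label = c("VH1", "VH3"), count = c(20L, 10L))
  res <- chiSquareUsage(a, b)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_identical(res$df, 1L)
  # symmetry
  expect_equal(chiSquareUsage(b, a)$statistic, res$statistic)

  same <- chiSquareUsage(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  bad <- data.frame(label = c("VH1", "VH9"), count = c(5L, 0L))
  expect_error(chiSquareUsage(a, bad), "VH9")
})

test_that("patterns-per-cell distribution reproduces printed proportions", {
  cells <- c(rep(1, 79), rep(2, 10), rep(3, 2))
  pat <- do.call(rbind, lapply(seq_along(cells), function(i)
    data.frame(cell_id = paste0("c", i), v_call = paste0("v", seq_len(cells[i])),
               stringsAsFactors = FALSE)))
  pp <- patternsPerCell(pat)
  expect_identical(unname(pp$counts), c(79L, 10L, 2L))
  expect_identical(unname(pp$percent), c(86.8, 11.0, 2.2))
  expect_identical(pp$n_cells, 91L)

  single <- patternsPerCell(data.frame(cell_id = c("a", "b"), v_call = "v"))
  expect_identical(unname(single$percent), c(100, 0, 0))
})

test_that("shared identical-junction sets are found and ordered stably", {
  pat <- examplePublicClonotypes()
  sets <- sharedRearrangements(pat)
  expect_identical(nrow(sets), 10L)
  expect_true(all(sets$cross_donor))
  expect_true(all(sets$n_cells >= 2))
  # the predominant rearrangement spans 13 cells across both donors
  big <- sets[sets$v_call == "IGHV1-24" & sets$d_call == "IGHD2-15", ]
  expect_identical(big$n_cells, 13L)
  expect_identical(big$n1_seq, "TT")
  expect_identical(big$n2_seq, "ACCCGATCCGAC")

  # invariant to input row order
  perm <- sharedRearrangements(pat[sample(nrow(pat)), ])
  expect_identical(perm, sets)

  # all-unique keys produce an empty result
  uniq <- pat[!duplicated(paste(pat$v_call, pat$n1_seq)), ]
  uniq$n1_seq <- paste0(uniq$n1_seq, seq_len(nrow(uniq)))
  expect_identical(nrow(sharedRearrangements(uniq)), 0L)
})

test_that("shared sets detected in simulations are truth-consistent", {
  sim <- fxSimShm()
  pat <- truthPatterns(sim$truth)
  sets <- sharedRearrangements(pat)
  expect_gt(nrow(sets), 0)
  # members of a reported set carry the same truth clone
  for (i in seq_len(nrow(sets))) {
    cells <- strsplit(sets$member_cells[i], ",")[[1]]
    rows <- sim$truth[sim$truth$cell_id %in% cells &
                        sim$truth$v_name == sets$v_call[i] &
                        sim$truth$n1_seq == sets$n1_seq[i] &
                        sim$truth$n2_seq == sets$n2_seq[i], ]
    expect_identical(length(unique(rows$clone_id)), 1L)
  }
})

test_that("Gaussian CDR3 length profiles fit tightly, restricted ones do not", {
  # self-fit: a histogram exactly proportional to a discretized Gaussian
  x <- 5:25
  counts <- round(1000 * dnorm(x, 15, 2.5))
  lens <- rep(x, counts)
  self <- cdr3GaussianFit(lens)
  expect_gte(self$r_squared, 0.999)
  expect_equal(self$mean, 15, tolerance = 0.05)

  set.seed(701)
  sampled <- cdr3GaussianFit(pmax(1, round(rnorm(3000, 15, 2))))
  expect_gte(sampled$r_squared, 0.95)

  bimodal <- cdr3GaussianFit(c(rep(8, 450), rep(9, 80), rep(21, 80),
                               rep(22, 450)))
  expect_lt(bimodal$r_squared, sampled$r_squared)
  expect_lte(bimodal$r_squared, 1)
  expect_error(cdr3GaussianFit(rep(12, 50)), "distinct")
})

test_that("genomic concentration separates 3'-restricted from diverse usage", {
  ref <- fxRef()
  vn <- segmentNames(ref, "V")
  rank0 <- vn[genomicRank(ref, vn) == 0]
  solo <- list(table = data.frame(label = rank0, count = 10L, frequency = 1))
  expect_equal(genomicDistribution(solo, ref)$concentration, 0)

  unif <- list(table = data.frame(label = vn, count = 1L,
                                  frequency = 1 / length(vn)))
  expect_equal(genomicDistribution(unif, ref)$concentration, 0.5)

  # preset-level comparison: restricted epithelial usage sits closer to the
  # 3' end than the diverse baseline
  conc <- function(preset) {
    cfg <- simulationConfig(ref, preset, seed = 1)
    u <- list(table = data.frame(label = names(cfg@vUsage),
                                 count = 1L, frequency = unname(cfg@vUsage)))
    genomicDistribution(u, ref)$concentration
  }
  expect_lt(conc("ptec-like"), conc("bcell-like"))

  bad <- list(table = data.frame(label = "IGHV9-99", count = 1L,
                                 frequency = 1))
  expect_error(genomicDistribution(bad, ref), "IGHV9-99")
})

test_that("productivity fractions match printed worked examples", {
  expect_identical(productivityFraction(rep(c(FALSE, TRUE),
                                            c(27, 442)))$percent, 5.8)
  expect_identical(productivityFraction(rep(c(FALSE, TRUE),
                                            c(130, 3170)))$percent, 3.9)
  expect_identical(productivityFraction(rep(TRUE, 10))$percent, 0)
  expect_error(productivityFraction(logical(0)), "no annotations")
})
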
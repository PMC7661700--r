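test_that("local alignment scores follow the fixed scheme", {
  seg <- randSeqWithSeed(300, 501)
  expect_identical(alignToGermline(seg, seg)$score, 600)
  full <- alignToGermline(seg, seg)
  expect_identical(unname(full$segment_range), c(0L, 300L))

  # one internal mismatch: 299 matches minus one mismatch
  q <- seg
  substr(q, 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                 substr(seg, 150, 150))[1]
  expect_identical(alignToGermline(q, seg)$score, 2 * 299 - 1)

  # disjoint content is a no-hit
  noHit <- alignToGermline(strrep("A", 50), strrep("C", 50))
  expect_true(noHit$no_hit)
  expect_lte(noHit$score, 0)
  expect_error(alignToGermline("", "ACGT"), "empty")
})

test_that("clean simulated repertoires are assigned back to truth exactly", {
  sim <- fxSim0(); ann <- fxAnn0()
  expect_identical(ann$sequence_id, sim$truth$sequence_id)
  expect_true(all(ann$v_call == sim$truth$v_name))
  expect_true(all(ann$j_call == sim$truth$j_name))
  # D agrees with truth whenever the retained germline D reaches the 5-nt
  # evidence floor (below it, a chance 5-mer elsewhere is legitimate evidence)
  dLen <- nchar(as.character(segmentSeq(fxRef(), sim$truth$d_name)))
  retained <- dLen - sim$truth$d_trim5 - sim$truth$d_trim3
  solid <- retained >= 5
  expect_true(all(ann$d_call[solid] != "unassigned"))
  expect_true(all(ann$d_call[solid] == sim$truth$d_name[solid]))
  # no mutations were simulated, none may be called
  expect_true(all(ann$mutation_frequency == 0))
  expect_true(all(!ann$mutated_status))
  expect_true(all(ann$productive))
})

test_that("a published predominant rearrangement annotates to its parts", {
  ref <- fxRef()
  asm <- recombineSegments(ref, "IGHV1-24", "IGHD2-15", "IGHJ4",
                           n1 = "TT", n2 = "ACCCGATCCGAC")
  a <- annotateSequence(asm$sequence, ref)
  expect_identical(a$v_call, "IGHV1-24")
  expect_identical(a$d_call, "IGHD2-15")
  expect_identical(a$j_call, "IGHJ4")
  expect_identical(a$n1_seq, "TT")
  expect_identical(a$n2_seq, "ACCCGATCCGAC")
})

test_that("a retained D below 5 nt stays unassigned with the insert as n1", {
  ref <- fxRef()
  dLen <- nchar(as.character(segmentSeq(ref, "IGHD1-1")))
  asm <- recombineSegments(ref, "IGHV1-24", "IGHD1-1", "IGHJ4",
                           dTrim5 = dLen - 10L, dTrim3 = 6L,
                           n1 = "GG", n2 = "AA")
  b <- assignSegments(asm$sequence, ref)
  expect_identical(b$d_call, "unassigned")
  jn <- delineateJunctions(asm$sequence, b)
  expect_identical(jn$n1, substr(asm$sequence, asm$record$v_end + 1,
                                 asm$record$j_start))
  expect_identical(jn$n2, "")

  # blunt join: no trims, no N additions
  blunt <- recombineSegments(ref, "IGHV1-18", "IGHD3-3", "IGHJ6")
  jb <- delineateJunctions(blunt$sequence, assignSegments(blunt$sequence, ref))
  expect_identical(jb$n1, "")
  expect_identical(jb$n2, "")
})

test_that("productivity classification matches the constructed defect", {
  ref <- fxRef()
  set.seed(502)
  for (k in 1:5) {
    asm <- scIgRep:::.newClone(scIgRep:::.refCache(ref),
                               simulationConfig(ref, "ptec-like", seed = k))
    clean <- annotateSequence(asm$sequence, ref)
    expect_true(clean$productive)
    expect_identical(clean$nonfunctional_reason, "none")

    st <- makeNonfunctional(ref, asm, "stop")
    expect_identical(annotateSequence(st$sequence, ref)$nonfunctional_reason,
                     "stop_codon")

    fs <- makeNonfunctional(ref, asm, "frameshift")
    expect_identical(annotateSequence(fs$sequence, ref)$nonfunctional_reason,
                     "out_of_frame")
  }
})

test_that("the mutated-status threshold sits exactly at 2 percent", {
  ref <- fxRef()
  asm <- recombineSegments(ref, "IGHV1-69", "IGHD3-22", "IGHJ5",
                           n1 = "CT", n2 = "GAA")
  base <- annotateSequence(asm$sequence, ref)
  A <- base$aligned_cols
  k <- ceiling(0.02 * A)
  # mutate k interior FR3 positions (safely inside the aligned window)
  info <- segmentInfo(ref)
  pos <- info$fr3_start[info$name == "IGHV1-69"] + seq(5, by = 7,
                                                       length.out = k)
  s <- strsplit(asm$sequence, "")[[1]]
  s[pos + 1] <- vapply(s[pos + 1], function(b)
    setdiff(c("A", "G"), b)[1], "")
  mut <- annotateSequence(paste0(s, collapse = ""), ref)
  expect_identical(nrow(mut$mutations[[1]]), as.integer(k))
  expect_equal(mut$mutation_frequency, 100 * k / A, tolerance = 1e-12)
  expect_true(mut$mutated_status)
  expect_true(all(mut$mutations[[1]]$region == "FR3"))

  # one fewer mutation drops below the threshold
  s2 <- strsplit(asm$sequence, "")[[1]]
  s2[pos[-1] + 1] <- s[pos[-1] + 1]
  below <- annotateSequence(paste0(s2, collapse = ""), ref)
  expect_false(below$mutated_status)
})

test_that("mutation calls agree with simulator truth where alignment is solid", {
  ref <- fxRef()
  sim <- fxSimShm(); ann <- fxAnnShm()
  info <- segmentInfo(ref)
  checkedFP <- 0L; checkedFN <- 0L
  for (i in seq_len(nrow(ann))) {
    tr <- sim$truth[i, ]
    truthMut <- decodeMutations(tr$mutations)
    called <- ann$mutations[[i]]
    if (is.null(called) || nrow(called) == 0) next
    # the exact column-level oracle applies to gapless alignments; a rare
    # spurious gap under heavy hypermutation shifts coordinates legitimately
    b <- assignSegments(tr$full_sequence, ref)
    if (b$failed ||
        length(unique(b$v_cols$query_pos - b$v_cols$germ_pos)) != 1 ||
        length(unique(b$j_cols$query_pos - b$j_cols$germ_pos)) != 1) next
    # no false positives: every called mutation is a recorded substitution
    key <- paste(truthMut$position, truthMut$germline_base,
                 truthMut$mutated_base)
    ckey <- paste(called$query_pos, called$germline_base,
                  called$observed_base)
    expect_true(all(ckey %in% key), label = ann$sequence_id[i])
    checkedFP <- checkedFP + nrow(called)
    # no false negatives deep inside V (FR2 start .. 8 nt before the V end)
    # and inside J FR4 (past the conserved Trp), where alignment cannot be
    # junction-ambiguous
    asm <- recombineSegments(ref, tr$v_name, tr$d_name, tr$j_name,
                             tr$v_trim3, tr$d_trim5, tr$d_trim3, tr$j_trim5,
                             tr$n1_seq, tr$n2_seq)
    fr2 <- info$fr2_start[info$name == tr$v_name]
    trp <- asm$record$trp_pos
    solid <- truthMut$position >= fr2 &
      truthMut$position < nchar(tr$full_sequence) - 6 &  # terminal clipping
      ((truthMut$position < asm$record$v_end - 8) |
         (!is.na(trp) & truthMut$position >= trp + 6))
    expect_true(all(key[solid] %in% ckey), label = ann$sequence_id[i])
    checkedFN <- checkedFN + sum(solid)
  }
  expect_gt(checkedFP, 100)
  expect_gt(checkedFN, 100)
})

test_that("mutations are never called inside annotated N regions", {
  sim <- fxSimShm(); ann <- fxAnnShm()
  for (i in seq_len(nrow(ann))) {
    b <- assignSegments(sim$truth$full_sequence[i], fxRef())
    called <- ann$mutations[[i]]
    if (is.null(called) || nrow(called) == 0 || b$failed) next
    vEnd <- b$v_query_range[2]; jStart <- b$j_query_range[1]
    nRegion <- if (b$d_call == "unassigned") {
      seq(vEnd, jStart - 1)
    } else {
      c(seq2(vEnd, b$d_query_range[1] - 1),
        seq2(b$d_query_range[2], jStart - 1))
    }
    expect_false(any(called$query_pos %in% nRegion),
                 label = ann$sequence_id[i])
  }
})

test_that("cell patterns deduplicate by segment+junction key", {
  sim <- fxSim0(); ann <- fxAnn0()
  pat <- dedupeCellPatterns(ann)
  # against simulator truth: one pattern per distinct clone per cell
  # (V/J compared; D attribution may legitimately differ when the retained
  # germline D is below the 5-nt evidence floor)
  truthPat <- truthPatterns(sim$truth)
  expect_identical(nrow(pat), nrow(truthPat))
  expect_setequal(paste(pat$cell_id, pat$v_call, pat$j_call),
                  paste(truthPat$cell_id, truthPat$v_call, truthPat$j_call))
  # colony multiplicities add up
  expect_identical(sum(pat$n_colonies), nrow(as.data.frame(ann)))

  # a cell with several identical colonies collapses to one pattern
  one <- ann[ann$cell_id == ann$cell_id[1], ]
  expect_identical(nrow(dedupeCellPatterns(one)),
                   length(unique(paste(one$v_call, one$d_call, one$j_call,
                                       one$n1_seq, one$n2_seq))))

  # annotation output is invariant to colony order within a cell
  rev <- dedupeCellPatterns(one[rev(seq_len(nrow(one))), ])
  expect_identical(dedupeCellPatterns(one), rev)

  # no annotated colonies -> empty pattern table
  empty <- ann[0, ]
  expect_identical(nrow(dedupeCellPatterns(empty)), 0L)
})

test_that("CDR3 follows the anchor-exclusive delimitation and translates", {
  ref <- fxRef()
  sim <- fxSim0(); ann <- fxAnn0()
  info <- segmentInfo(ref)
  for (i in seq_len(min(nrow(ann), 40))) {
    tr <- sim$truth[i, ]
    asm <- recombineSegments(ref, tr$v_name, tr$d_name, tr$j_name,
                             tr$v_trim3, tr$d_trim5, tr$d_trim3, tr$j_trim5,
                             tr$n1_seq, tr$n2_seq)
    cys <- asm$record$cys_pos; trp <- asm$record$trp_pos
    expected <- substr(tr$full_sequence, cys + 4, trp)
    expect_identical(ann$cdr3_nt[i], expected, label = tr$sequence_id)
    expect_identical(nchar(ann$cdr3_nt[i]) %% 3L, 0L)
    expect_identical(nchar(ann$cdr3_aa[i]), nchar(ann$cdr3_nt[i]) %/% 3L)
  }
})
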
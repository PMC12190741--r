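arch <- tiny_arch()
refp <- simulate_reference_pair(arch, seed = 7)

test_that("PAR reads multi-map on the default reference and resolve under SCC", {
  # a read drawn from inside X PAR1 has an identical Y PAR1 copy
  read <- substr(refp$sequences[["X"]], 1001, 1150)
  def <- align_read(read, build_reference("default", refp, arch))
  expect_true(def$aligned)
  expect_identical(def$mapq, 0L)
  expect_gte(def$n_best, 2L)
  expect_identical(def$nm, 0L)

  scc <- align_read(read, build_reference("xy_scc", refp, arch))
  expect_identical(scc$chrom, "X")
  expect_identical(scc$start0, 1000L)
  expect_identical(scc$mapq, 60L)
  expect_identical(scc$n_best, 1L)
})

test_that("degenerate reads are unaligned", {
  expect_false(align_read(strrep("N", 150), refp$sequences)$aligned)
  # a read longer than every chromosome cannot be placed
  tiny <- c(Z = strrep("ACGT", 10))
  expect_false(align_read(strrep("A", 150), tiny)$aligned)
  # random sequence exceeding max_mm everywhere is unaligned
  set.seed(1)
  junk <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  expect_false(align_read(junk, refp$sequences, max_mm = 10)$aligned)
})

test_that("seeded-index mapping equals the exhaustive-scan oracle", {
  march <- micro_arch()
  mref <- simulate_reference_pair(march, seed = 13)
  coh <- simulate_cohort(march, mref, n_xy = 1, theta = 0.001, seed = 2)
  reads <- simulate_reads(coh[[1]], mref, march, policy = coverage_policy(1),
                          seed = 3)
  reads <- reads[sample.int(nrow(reads), 120), ]
  aln <- map_reads(reads, mref$sequences, seed = 5)
  for (i in seq_len(nrow(reads))) {
    o <- oracle_map(reads$seq[i], mref$sequences)
    expect_identical(aln$aligned[i], o$aligned)
    if (!o$aligned) next
    expect_identical(aln$nm[i], o$nm)
    expect_identical(aln$n_best[i], o$n_best)
    expect_identical(aln$mapq[i], o$mapq)
    # the chosen placement is one of the oracle's co-optimal placements
    expect_true(any(o$best_set$chrom == aln$chrom[i] &
                      o$best_set$start0 == aln$start0[i] &
                      o$best_set$strand == aln$strand[i]))
  }
})

test_that("tie-breaking is seeded, per-read, and uniform-ish across copies", {
  read <- substr(refp$sequences[["X"]], 2001, 2150)  # PAR1 duplicate
  a1 <- align_read(read, refp$sequences, seed = 1)
  a2 <- align_read(read, refp$sequences, seed = 1)
  expect_identical(a1$chrom, a2$chrom)  # deterministic under the same seed
  picks <- vapply(1:40, function(s)
    align_read(read, refp$sequences, seed = s)$chrom, character(1))
  expect_setequal(unique(picks), c("X", "Y"))  # both placements reachable
})

test_that("masking re-routes Y-XTR reads into the X XTR", {
  coh <- simulate_cohort(arch, refp, n_xy = 1, theta = 0.001, seed = 6)
  reads <- simulate_reads(coh[[1]], refp, arch, seed = 8)
  yxtr <- arch_regions(arch, "Y", "XTR")
  orig <- reads[reads$chrom == "Y" &
                  reads$start0 >= yxtr$start & reads$start0 < yxtr$end, ]
  masked <- build_reference("xy_scc_yxtr_masked", refp, arch)
  aln <- map_reads(orig, masked, seed = 9)
  xxtr <- arch_regions(arch, "X", "XTR")
  in_x_xtr <- aln$aligned & aln$chrom == "X" &
    aln$start0 >= xxtr$start - 150 & aln$start0 < xxtr$end
  expect_gte(mean(in_x_xtr), 0.95)
})

test_that("pileup depth conserves aligned bases", {
  march <- micro_arch()
  mref <- simulate_reference_pair(march, seed = 13)
  coh <- simulate_cohort(march, mref, n_xy = 1, theta = 0.001, seed = 2)
  reads <- simulate_reads(coh[[1]], mref, march, policy = coverage_policy(2),
                          seed = 3)
  aln <- map_reads(reads, mref$sequences, seed = 5)
  counts <- pileup_base_counts(aln, reads, mref$sequences)
  total_depth <- sum(vapply(counts, sum, numeric(1)))
  expect_equal(total_depth, sum(aln$length[aln$aligned]))
  # full column extraction agrees with the count matrices
  cols <- build_pileups(aln, reads, mref$sequences)
  expect_identical(nrow(cols), as.integer(total_depth))
})

test_that("sites covered only by multi-mappers have zero calling depth", {
  coh <- simulate_cohort(arch, refp, n_xx = 1, theta = 0.001, seed = 6)
  reads <- simulate_reads(coh[[1]], refp, arch, policy = coverage_policy(2),
                          seed = 8)
  aln <- map_reads(reads, refp$sequences, seed = 9)
  # interior PAR1 positions: identical X/Y copies, so all reads are MAPQ 0
  pos <- list(X = 1500:2500, Y = integer(0), A = integer(0))
  cols_raw <- build_pileups(aln, reads, refp$sequences, positions = pos)
  cols_called <- build_pileups(aln, reads, refp$sequences, positions = pos,
                               min_mapq = 20, drop_mapq0 = TRUE)
  expect_gt(nrow(cols_raw), 0L)
  expect_identical(nrow(cols_called), 0L)
})
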
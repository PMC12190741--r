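arch <- tiny_arch()
refp <- simulate_reference_pair(arch, seed = 7)

test_that("genotype likelihoods follow the biallelic substitution model", {
  # 10 clean alt reads at Q20 (e = 0.01), haploid: the log10 likelihood gap
  # is 10 * log10(0.99 / (0.01 / 3))
  gl <- genotype_likelihoods(rep("G", 10), rep(20L, 10), ref = "A",
                             alt = "G", ploidy = 1L)
  expect_equal(gl[["alt"]] - gl[["ref"]], 10 * log10(0.99 / (0.01 / 3)),
               tolerance = 1e-10)
  expect_equal(gl[["alt"]] - gl[["ref"]], 24.727, tolerance = 1e-3)

  # balanced diploid column: the heterozygote maximises the likelihood
  gl2 <- genotype_likelihoods(rep(c("A", "G"), 5), rep(20L, 10), "A", "G",
                              ploidy = 2L)
  expect_identical(names(which.max(gl2)), "ref_alt")

  # zero reads: uniform, flagged
  gl0 <- genotype_likelihoods(character(0), integer(0), "A", "G", 2L)
  expect_true(attr(gl0, "no_data"))
  expect_true(all(gl0 == 0))

  # bases matching neither allele contribute e/3 under every genotype
  gl3 <- genotype_likelihoods("T", 20L, "A", "G", 1L)
  expect_equal(gl3[["ref"]], gl3[["alt"]])
})

test_that("joint genotyping matches the enumeration oracle at depth <= 12", {
  set.seed(42)
  ref1 <- c(X = paste(sample(c("A", "C", "G", "T"), 30000, TRUE),
                      collapse = ""))
  arch1 <- genome_architecture(regions = data.frame(
    chrom = "X", start = 0L, end = 30000L, class = "NONPAR"),
    chrom_lengths = c(X = 30000L))
  for (rep_i in 1:25) {
    pos <- sample(100:29000, 1)
    refb <- substr(ref1[["X"]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    depth <- sample(1:12, 1)
    bases <- sample(c(refb, alt), depth, TRUE)
    quals <- sample(c(12L, 20L, 25L, 30L), depth, TRUE)
    kar <- c(S1 = sample(c("XX", "XY"), 1))
    ploidy <- if (kar == "XX") 2L else 1L
    col <- make_column("X", pos, bases, quals, "S1")
    calls <- joint_genotype(col, kar, ref1, arch1)
    post <- oracle_genotype_posterior(bases, quals, refb, alt, ploidy)
    map_idx <- which.max(post)
    gt_exp <- if (ploidy == 1L) c("0", "1")[map_idx] else
      c("0/0", "0/1", "1/1")[map_idx]
    emitted <- nrow(calls$sites) == 1L
    if (grepl("1", gt_exp)) {
      expect_true(emitted)
      expect_identical(unname(calls$gt[1, "S1"]), gt_exp)
      expect_equal(calls$sites$QUAL, -10 * log10(post[[1]]),
                   tolerance = 1e-6)
      expect_identical(calls$sites$ref, refb)
      expect_identical(calls$sites$alt, alt)
    } else {
      expect_false(emitted)  # AC = 0 sites are not emitted
    }
  }
})

test_that("allele number is the ploidy-weighted count of genotyped samples", {
  ref1 <- refp$sequences
  # site on Y non-PAR: 1 XY sample with 10 clean alt reads, 9 XY refs
  pos <- 30001L
  refb <- substr(ref1[["Y"]], pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  samples <- sprintf("XY_%02d", 1:10)
  cols <- do.call(rbind, c(
    list(make_column("Y", pos, rep(alt, 10), 25L, samples[1])),
    lapply(samples[-1], function(s)
      make_column("Y", pos, rep(refb, 10), 25L, s))))
  kar <- setNames(rep("XY", 10), samples)
  calls <- joint_genotype(cols, kar, ref1, arch)
  expect_identical(nrow(calls$sites), 1L)
  expect_identical(calls$sites$AC, 1L)
  expect_identical(calls$sites$AN, 10L)

  # mixed ploidy at one X non-PAR site: 4 diploid XX + 2 haploid XY
  pos <- 20001L
  refb <- substr(ref1[["X"]], pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  samples <- c(sprintf("XX_%02d", 1:4), sprintf("XY_%02d", 1:2))
  kar <- setNames(c(rep("XX", 4), rep("XY", 2)), samples)
  cols <- do.call(rbind, lapply(seq_along(samples), function(i)
    make_column("X", pos, c(rep(alt, 5), rep(refb, 5 * (i > 1))), 25L,
                samples[i])))
  calls <- joint_genotype(cols, kar, ref1, arch)
  expect_identical(calls$sites$AN, 4L * 2L + 2L * 1L)
  expect_identical(unname(nchar(calls$gt[1, kar == "XY"])), c(1L, 1L))

  # all-reference cohorts emit nothing
  cols_ref <- make_column("X", pos, rep(refb, 10), 30L, "XX_01")
  expect_identical(nrow(joint_genotype(cols_ref, c(XX_01 = "XX"), ref1,
                                       arch)$sites), 0L)
})

test_that("annotations follow their definitions", {
  ref1 <- refp$sequences
  pos <- 25001L
  refb <- substr(ref1[["X"]], pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  # balanced strands: 5 ref / 5 alt on each strand -> FS = 0 (Fisher p = 1)
  col <- make_column("X", pos, c(rep(refb, 10), rep(alt, 10)), 25L, "XX_01",
                     mapq = 60L,
                     strand = rep(c("+", "-"), 10))
  calls <- joint_genotype(col, c(XX_01 = "XX"), ref1, arch)
  s <- calls$sites
  expect_identical(s$DP, 20L)
  expect_equal(s$MQ, 60)           # RMS of a constant
  expect_equal(s$FS, 0)            # no strand bias
  expect_equal(s$QD, s$QUAL / 20)  # all depth is in the variant sample
  expect_equal(s$MQRankSum, 0)     # identical MAPQ distributions
  # mixed MAPQ: alt reads mapped worse -> negative MQRankSum
  col2 <- make_column("X", pos, c(rep(refb, 10), rep(alt, 10)),
                      25L, "XX_01", mapq = c(rep(60L, 10), rep(30L, 10)))
  s2 <- joint_genotype(col2, c(XX_01 = "XX"), ref1, arch)$sites
  expect_lt(s2$MQRankSum, 0)
  expect_equal(s2$MQ, sqrt(mean(c(rep(3600, 10), rep(900, 10)))))
})

test_that("haploid calling never emits heterozygotes; error-free diploid agrees", {
  coh <- simulate_cohort(arch, refp, n_xy = 2, theta = 0.001, seed = 31)
  reads <- list()
  for (i in 1:2)
    reads[[coh[[i]]$sample_id]] <-
      simulate_reads(coh[[i]], refp, arch,
                     params = read_params(error_rate = 0), seed = 60 + i)
  kar <- setNames(rep("XY", 2), names(reads))
  refs <- build_reference("xy_scc", refp, arch)
  ch <- call_cohort(reads, kar, refs, arch, mode = "matched", seed = 3)
  cd <- call_cohort(reads, kar, refs, arch, mode = "force_diploid", seed = 3)
  hap <- ploidy_at(arch, "XY", ch$sites$chrom, ch$sites$pos) == 1L
  expect_false(any(grepl("/", ch$gt[hap, ], fixed = TRUE)))
  # with no sequencing errors and unique mapping, the two modes call the
  # same sites with the same per-sample variant status outside the XTR
  # (XTR multi-mapping ties still drop reads in both modes)
  keep <- function(x) {
    cls <- region_class_at(arch, x$sites$chrom, x$sites$pos)
    which(cls != "XTR")
  }
  sh <- calls_subset(ch, keep(ch)); sd <- calls_subset(cd, keep(cd))
  expect_identical(paste(sh$sites$chrom, sh$sites$pos, sh$sites$alt),
                   paste(sd$sites$chrom, sd$sites$pos, sd$sites$alt))
  expect_identical(grepl("1", sh$gt, fixed = TRUE),
                   grepl("1", sd$gt, fixed = TRUE))
})
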
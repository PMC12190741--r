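arch <- tiny_arch()
refp <- simulate_reference_pair(arch, seed = 7)

test_that("realized depth from truth placements matches the coverage policy", {
  coh <- simulate_cohort(arch, refp, n_xx = 1, n_xy = 1, theta = 0.001,
                         seed = 4)
  xx <- coh[[1]]; xy <- coh[[2]]
  rxx <- simulate_reads(xx, refp, arch, seed = 21)
  rxy <- simulate_reads(xy, refp, arch, seed = 22)
  np <- arch_regions(arch, "X", "NONPAR")
  # diploid X non-PAR in XX: 20x; haploid X and Y non-PAR in XY: 10x each
  expect_lt(abs(truth_depth(rxx, "X", np$start, np$end) - 20) / 20, 0.1)
  expect_lt(abs(truth_depth(rxy, "X", np$start, np$end) - 10) / 10, 0.1)
  ynp <- arch_regions(arch, "Y", "NONPAR")
  expect_lt(abs(truth_depth(rxy, "Y", ynp$start, ynp$end) - 10) / 10, 0.1)
  # PARs diploid on X for both karyotypes, nothing simulated on Y PARs
  p1 <- arch_regions(arch, "X", "PAR1")
  expect_lt(abs(truth_depth(rxy, "X", p1$start, p1$end) - 20) / 20, 0.1)
  expect_identical(truth_depth(rxy, "Y", 0, 4000), 0)
  # XX never yields Y reads
  expect_false("Y" %in% rxx$chrom)
})

test_that("error-free reads are exact substrings of their haplotype", {
  coh <- simulate_cohort(arch, refp, n_xx = 1, theta = 0, seed = 1)
  reads <- simulate_reads(coh[[1]], refp, arch,
                          policy = coverage_policy(2),
                          params = read_params(error_rate = 0), seed = 5)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in sample.int(nrow(reads), 200)) {
    src <- substr(refp$sequences[[reads$chrom[i]]], reads$start0[i] + 1L,
                  reads$start0[i] + nchar(reads$seq[i]))
    if (reads$strand[i] == "+") {
      expect_identical(reads$seq[i], src)
    } else {
      rc <- paste(rev(comp[strsplit(src, "")[[1]]]), collapse = "")
      expect_identical(reads$seq[i], rc)
    }
  }
})

test_that("mismatch rate recovers the quality-implied error rate", {
  # constant Q20 means per-base error 0.01
  coh <- simulate_cohort(arch, refp, n_xx = 1, theta = 0, seed = 1)
  reads <- simulate_reads(coh[[1]], refp, arch,
                          policy = coverage_policy(2),
                          params = read_params(qual_high = 20L,
                                               low_frac = 0), seed = 6)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mism <- 0L; tot <- 0L
  for (i in seq_len(nrow(reads))) {
    src <- substr(refp$sequences[[reads$chrom[i]]], reads$start0[i] + 1L,
                  reads$start0[i] + nchar(reads$seq[i]))
    obs <- reads$seq[i]
    if (reads$strand[i] == "-")
      obs <- paste(rev(comp[strsplit(obs, "")[[1]]]), collapse = "")
    mism <- mism + hamming(src, obs)
    tot <- tot + nchar(src)
  }
  ci <- qbinom(c(0.0005, 0.9995), tot, 0.01) / tot
  expect_gte(mism / tot, ci[1])
  expect_lte(mism / tot, ci[2])
})

test_that("trimming applies the end-trim, length, and mean-quality rules", {
  q <- function(ints) intToUtf8(ints + 33L)
  mk <- function(seqs, quals, ids = seq_along(seqs), mates = 1L)
    structure(data.frame(read_id = as.character(ids),
                         mate = rep_len(mates, length(seqs)), seq = seqs,
                         qual = quals, chrom = "X", hap = 1L,
                         start0 = 0L, strand = "+"),
              class = c("read_set", "data.frame"))
  b150 <- strrep("A", 150)
  rs <- mk(
    seqs = c(b150, b150, b150, b150),
    quals = c(q(rep(30L, 150)),                      # untouched
              q(c(rep(10L, 80), rep(30L, 70))),      # 70 bp post-trim < 75
              q(rep(19L, 150)),                      # everything below trimq
              q(c(rep(25L, 30), rep(12L, 110), rep(25L, 10)))))  # maq fail
  tr <- trim_reads(rs)
  expect_identical(tr$log$action,
                   c("kept", "dropped_short", "dropped_short", "dropped_maq"))
  expect_identical(tr$reads$seq, b150)
  # mean-quality rule: ends above trimq, interior drags mean below 20
  mq <- mean(c(rep(25L, 30), rep(12L, 110), rep(25L, 10)))
  expect_lt(mq, 20)
})

test_that("mates are dropped jointly when either fails", {
  q <- function(ints) intToUtf8(ints + 33L)
  rs <- structure(data.frame(
    read_id = c("p1", "p1"), mate = c(1L, 2L),
    seq = c(strrep("A", 150), strrep("C", 150)),
    qual = c(q(rep(30L, 150)), q(rep(10L, 150))),
    chrom = "X", hap = 1L, start0 = 0L, strand = c("+", "-")),
    class = c("read_set", "data.frame"))
  tr <- trim_reads(rs)
  expect_identical(nrow(tr$reads), 0L)
  expect_setequal(tr$log$action, c("dropped_mate", "dropped_short"))
})

test_that("trimming is idempotent and adjusts truth coordinates", {
  coh <- simulate_cohort(arch, refp, n_xx = 1, theta = 0.001, seed = 4)
  reads <- simulate_reads(coh[[1]], refp, arch,
                          policy = coverage_policy(3), seed = 31)
  t1 <- trim_reads(reads)
  t2 <- trim_reads(t1$reads)
  expect_identical(t1$reads, t2$reads)
  expect_true(all(t2$log$action == "kept"))
  # truth coordinates still point at the right reference window: error-free
  # reads from a variant-free sample must match the reference after trimming
  coh0 <- simulate_cohort(arch, refp, n_xx = 1, theta = 0, seed = 1)
  reads0 <- simulate_reads(coh0[[1]], refp, arch,
                           policy = coverage_policy(2),
                           params = read_params(error_rate = 0), seed = 32)
  tr <- trim_reads(reads0)$reads
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  idx <- c(which(tr$strand == "+")[1:20], which(tr$strand == "-")[1:20])
  for (i in idx) {
    src <- substr(refp$sequences[[tr$chrom[i]]], tr$start0[i] + 1L,
                  tr$start0[i] + nchar(tr$seq[i]))
    obs <- tr$seq[i]
    if (tr$strand[i] == "-")
      obs <- paste(rev(comp[strsplit(obs, "")[[1]]]), collapse = "")
    expect_identical(obs, src)
  }
})

test_that("FASTQ output round-trips through Biostrings", {
  coh <- simulate_cohort(arch, refp, n_xx = 1, theta = 0.001, seed = 4)
  reads <- simulate_reads(coh[[1]], refp, arch, policy = coverage_policy(1),
                          seed = 41)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f1, f2)
  back <- Biostrings::readDNAStringSet(f1, format = "fastq",
                                       with.qualities = TRUE)
  m1 <- reads[reads$mate == 1L, ]
  expect_identical(as.character(unname(back)), m1$seq)
  expect_identical(as.character(unname(S4Vectors::mcols(back)$qualities)),
                   m1$qual)
})
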
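test_that("hard filters use strict inequalities and ignore missing values", {
  sites <- data.frame(
    chrom = "X", pos = c(100L, 200L, 300L, 400L, 500L),
    ref = "A", alt = "G",
    QD = c(1.5, 20, 2.0, 20, NA),
    QUAL = c(100, 100, 100, 25, 100),
    MQ = c(60, 40.0, 60, 60, 60),
    FS = c(0, 0, 0, 61, 0),
    SOR = c(0.7, 3.0, 0.7, 0.7, 0.7),
    MQRankSum = c(0, 0, NA, -13, 0),
    ReadPosRankSum = c(0, 0, 0, 0, 0))
  calls <- apply_hard_filters(make_calls(sites))
  f <- calls$sites$FILTER
  expect_identical(f[1], "QD")                # QD = 1.5 fails QD < 2.0
  expect_identical(f[2], "PASS")              # MQ = 40.0 passes (strict <)
  expect_identical(f[3], "PASS")              # QD = 2.0 passes; NA ignored
  expect_setequal(strsplit(f[4], ";")[[1]],
                  c("QUAL", "FS", "MQRankSum"))  # conjunctive labels
  expect_identical(f[5], "PASS")              # missing QD never fails
  expect_identical(nrow(pass_sites(calls)$sites), 3L)
})

test_that("depth band is inclusive and its mean source changes the verdict", {
  sites <- data.frame(chrom = "X", pos = c(1L, 2L, 3L, 4L, 5L),
                      ref = "A", alt = "G",
                      DP = c(9L, 10L, 30L, 31L, 8L))
  calls <- make_calls(sites)
  kept <- dp_band_filter(calls, mean_dp = 20)
  expect_identical(kept$sites$DP, c(10L, 30L))
  # a haploid site at DP 8: removed under a diploid-derived mean of 20,
  # retained under a haploid-derived mean of 10 (band [5, 15])
  expect_false(8L %in% dp_band_filter(calls, 20)$sites$DP)
  expect_true(8L %in% dp_band_filter(calls, 10)$sites$DP)
  expect_error(dp_band_filter(calls, 0))
})

test_that("AN filtering is monotone and wipes haploid cohorts above n", {
  set.seed(3)
  sites <- data.frame(chrom = "X", pos = seq_len(40L), ref = "A", alt = "G",
                      AN = sample(1:10, 40, TRUE))
  calls <- make_calls(sites)
  kept_prev <- an_filter(calls, 1)
  expect_identical(nrow(kept_prev$sites), 40L)  # k = 1 keeps everything
  for (k in c(2, 3, 5, 10, 20)) {
    kept <- an_filter(calls, k)
    expect_true(all(kept$sites$pos %in% kept_prev$sites$pos))  # nested
    kept_prev <- kept
  }
  # 10 haploid-called samples can reach AN at most 10: the diploid-based
  # threshold of 20 removes every site, the haploid-based 10 keeps full-AN
  sites10 <- data.frame(chrom = "X", pos = 1:5, ref = "A", alt = "G",
                        AN = c(10L, 9L, 10L, 7L, 10L))
  expect_identical(nrow(an_filter(make_calls(sites10), 20)$sites), 0L)
  expect_identical(nrow(an_filter(make_calls(sites10), 10)$sites), 3L)
})

test_that("threshold sweeps are monotone and match single-threshold runs", {
  arch <- tiny_arch()
  set.seed(8)
  n <- 60L
  pos <- sort(sample(17001:57000, n))
  sites <- data.frame(chrom = "X", pos = pos, ref = "A", alt = "G",
                      QD = runif(n, 0, 30), AN = sample(1:20, n, TRUE),
                      DP = rpois(n, 20))
  gt <- matrix(sample(c("0/1", "0/0"), n, TRUE, prob = c(0.8, 0.2)), n, 1,
               dimnames = list(NULL, "S1"))
  calls <- make_calls(sites, gt = gt, samples = "S1")
  golden <- list(S1 = data.frame(chrom = "X", pos = pos[1:30], ref = "A",
                                 alt = "G"))
  sweep <- threshold_sweep(calls, golden, arch, "QD",
                           c(0, 1, 1.5, 2, 12, 16, 20, 28))
  tot <- aggregate(cbind(TP, FP) ~ value, data = sweep, sum)
  tot <- tot[order(tot$value), ]
  expect_true(all(diff(tot$TP) <= 0))   # retained TPs non-increasing
  expect_true(all(diff(tot$FP) <= 0))
  # QD threshold 0 retains all emitted sites: TP + FP equals a no-filter run
  lab0 <- classify_calls(golden$S1, sample_called_sites(calls, "S1"))
  expect_identical(tot$TP[1] + tot$FP[1],
                   sum(lab0$label %in% c("TP", "FP")))
  # sweep value 12 equals a direct single-threshold subset
  direct <- calls_subset(calls, calls$sites$QD >= 12)
  lab12 <- classify_calls(golden$S1, sample_called_sites(direct, "S1"))
  s12 <- sweep[sweep$value == 12, ]
  expect_identical(sum(s12$TP), sum(lab12$label == "TP"))
  expect_identical(sum(s12$FP), sum(lab12$label == "FP"))
})

test_that("filter composition is order-independent", {
  sites <- data.frame(chrom = "X", pos = 1:6, ref = "A", alt = "G",
                      QD = c(1, 25, 1, 25, 25, 25),
                      MQ = c(30, 30, 60, 60, 60, 60),
                      QUAL = c(100, 100, 100, 100, 20, 100))
  calls <- make_calls(sites)
  lab <- apply_hard_filters(calls)$sites$FILTER
  # re-applying after another filter config pass gives the same labels
  lab2 <- apply_hard_filters(apply_hard_filters(calls))$sites$FILTER
  expect_identical(lab, lab2)
  expect_setequal(strsplit(lab[1], ";")[[1]], c("QD", "MQ"))
})
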
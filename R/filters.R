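#' Hard-filter configuration
#'
#' The default thresholds are the conventional autosomal hard-filter
#' recommendations for SNPs: fail a site when `QD < 2.0`, `QUAL < 30.0`,
#' `SOR > 3.0`, `FS > 60.0`, `MQ < 40.0`, `MQRankSum < -12.5`, or
#' `ReadPosRankSum < -8.0` (strict inequalities; a missing annotation never
#' fails its filter).
#'
#' @param qd,qual,sor,fs,mq,mqranksum,readposranksum Thresholds as above.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(qd = 2.0, qual = 30.0, sor = 3.0, fs = 60.0,
                          mq = 40.0, mqranksum = -12.5,
                          readposranksum = -8.0) {
  structure(list(qd = qd, qual = qual, sor = sor, fs = fs, mq = mq,
                 mqranksum = mqranksum, readposranksum = readposranksum),
            class = "filter_config")
}

#' Apply the hard-filter expressions
#'
#' Labels each site `PASS` or with the semicolon-joined names of every
#' filter whose inequality it satisfies. Comparisons are strict, exactly as
#' written in the expressions (`MQ = 40.0` passes `MQ < 40.0`); `NA`
#' annotations do not fail a filter. Filter composition is conjunctive and
#' therefore order-independent.
#'
#' @param calls A `site_calls` object.
#' @param cfg A [filter_config()].
#' @return `calls` with the `FILTER` column populated.
#' @export
apply_hard_filters <- function(calls, cfg = filter_config()) {
  s <- calls$sites
  fail <- cbind(
    QD = s$QD < cfg$qd,
    QUAL = s$QUAL < cfg$qual,
    SOR = s$SOR > cfg$sor,
    FS = s$FS > cfg$fs,
    MQ = s$MQ < cfg$mq,
    MQRankSum = s$MQRankSum < cfg$mqranksum,
    ReadPosRankSum = s$ReadPosRankSum < cfg$readposranksum)
  fail[is.na(fail)] <- FALSE
  lab <- apply(fail, 1L, function(f)
    if (any(f)) paste(colnames(fail)[f], collapse = ";") else "PASS")
  calls$sites$FILTER <- if (nrow(s)) lab else character(0)
  calls
}

#' Retain only PASS sites
#'
#' @param calls A `site_calls` with `FILTER` populated.
#' @return Subset `site_calls` with only `PASS` (or unfiltered `"."`) sites.
#' @export
pass_sites <- function(calls) {
  calls_subset(calls, calls$sites$FILTER %in% c("PASS", "."))
}

#' Depth-band filter
#'
#' Retains sites whose total depth lies between `lo` and `hi` times a mean
#' depth (inclusive bounds). The mean is conventionally derived either from
#' autosomal variant sites ("diploid-based") or from X/Y non-PAR sites of XY
#' samples ("haploid-based"); see [mean_site_dp()].
#'
#' @param calls A `site_calls`.
#' @param mean_dp The reference mean depth (> 0).
#' @param lo,hi Band fractions (defaults 0.5 and 1.5).
#' @return Subset `site_calls` of retained sites.
#' @export
dp_band_filter <- function(calls, mean_dp, lo = 0.5, hi = 1.5) {
  stopifnot(mean_dp > 0, lo < hi)
  dp <- calls$sites$DP
  calls_subset(calls, dp >= lo * mean_dp & dp <= hi * mean_dp)
}

#' Mean DP over emitted sites of selected chromosomes/regions
#'
#' @param calls A `site_calls`.
#' @param chroms Chromosomes to average over (e.g. `"A"` for the
#'   diploid-based mean, `c("X", "Y")` for the haploid-based mean).
#' @param arch Optional [genome_architecture()]; when given, PAR sites are
#'   excluded (the band source is the non-PAR sequence).
#' @return Mean site DP.
#' @export
mean_site_dp <- function(calls, chroms, arch = NULL) {
  s <- calls$sites
  keep <- s$chrom %in% chroms
  if (!is.null(arch) && any(keep)) {
    cls <- region_class_at(arch, s$chrom[keep], s$pos[keep])
    keep[keep] <- !(cls %in% c("PAR1", "PAR2"))
  }
  if (!any(keep)) return(NA_real_)
  mean(s$DP[keep])
}

#' Allele-number filter
#'
#' Retains sites with `AN >= k`. AN counts successfully genotyped allele
#' copies (ploidy-weighted), so with `n` XY samples called haploid on X/Y
#' non-PARs, AN can never exceed `n` there and any `k > n` removes every
#' site.
#'
#' @param calls A `site_calls`.
#' @param k Minimum allele number.
#' @return Subset `site_calls` of retained sites.
#' @export
an_filter <- function(calls, k) {
  calls_subset(calls, calls$sites$AN >= k)
}

#' Threshold sweep with golden-truth scoring
#'
#' Applies each threshold of one filter dimension and counts retained true
#' and false positives per region class, using per-sample classification
#' against the golden truth.
#'
#' @param calls A `site_calls`.
#' @param golden Named list of golden site data.frames (from
#'   [golden_sites()]), one per sample in `calls$samples`.
#' @param arch The [genome_architecture()].
#' @param dimension `"QD"`, `"AN"`, or `"DP"`.
#' @param values Thresholds to test. Conventional sweeps: QD in
#'   `c(1, 1.5, 2, 12, 16, 20, 28)` (retain `QD >= value`), AN in
#'   `c(20, 15, 10, 5, 4, 3, 2, 1)` (retain `AN >= value`), DP as multiples
#'   of a mean depth via [dp_band_filter()] — for `"DP"` the values are mean
#'   depths and the 0.5-1.5 band is applied around each.
#' @return data.frame with `dimension`, `value`, `region`, `TP`, `FP`
#'   (summed over samples).
#' @export
threshold_sweep <- function(calls, golden, arch,
                            dimension = c("QD", "AN", "DP"), values) {
  dimension <- match.arg(dimension)
  out <- list()
  for (v in values) {
    kept <- switch(dimension,
      QD = calls_subset(calls, !is.na(calls$sites$QD) & calls$sites$QD >= v),
      AN = an_filter(calls, v),
      DP = dp_band_filter(calls, v))
    counts <- NULL
    for (smp in names(golden)) {
      lab <- classify_calls(golden[[smp]], sample_called_sites(kept, smp))
      cc <- stratify_by_region(lab, arch)
      cc <- cc[cc$region != "ALL", , drop = FALSE]
      counts <- if (is.null(counts)) cc[, c("chrom", "region", "TP", "FP")]
        else {
          counts$TP <- counts$TP + cc$TP
          counts$FP <- counts$FP + cc$FP
          counts
        }
    }
    counts$dimension <- dimension
    counts$value <- v
    out[[length(out) + 1L]] <- counts
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("dimension", "value", "chrom", "region", "TP", "FP")]
}
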
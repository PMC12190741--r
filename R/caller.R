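#' Genotype log-likelihoods for one pileup column
#'
#' Biallelic substitution model: a read with base `b` and per-base error
#' probability `e` (from its quality, floored at `eps_floor`) has
#' `P(b | allele a) = 1 - e` if `b == a` and `e / 3` otherwise. Haploid
#' likelihoods multiply `P(b | a)` over reads; diploid genotypes average the
#' two allele likelihoods per read, `P(b | a1 a2) = (P(b|a1) + P(b|a2)) / 2`.
#'
#' @param bases Character vector of observed bases at the column.
#' @param quals Integer Phred base qualities.
#' @param ref,alt The two alleles considered.
#' @param ploidy 1 or 2.
#' @param eps_floor Lower bound on the per-base error probability, guarding
#'   against zero likelihoods at high qualities.
#' @return Named numeric vector of log10-likelihoods: `ref`/`alt` for
#'   haploid, `ref_ref`/`ref_alt`/`alt_alt` for diploid. Zero reads give
#'   uniform (all-zero) log-likelihoods with attribute `no_data = TRUE`.
#' @export
genotype_likelihoods <- function(bases, quals, ref, alt, ploidy = 2L,
                                 eps_floor = 1e-4) {
  stopifnot(ploidy %in% c(1L, 2L))
  if (length(bases) == 0L) {
    out <- if (ploidy == 1L) c(ref = 0, alt = 0) else
      c(ref_ref = 0, ref_alt = 0, alt_alt = 0)
    attr(out, "no_data") <- TRUE
    return(out)
  }
  e <- pmax(10^(-quals / 10), eps_floor)
  p_ref <- ifelse(bases == ref, 1 - e, e / 3)
  p_alt <- ifelse(bases == alt, 1 - e, e / 3)
  if (ploidy == 1L)
    c(ref = sum(log10(p_ref)), alt = sum(log10(p_alt)))
  else
    c(ref_ref = sum(log10(p_ref)),
      ref_alt = sum(log10((p_ref + p_alt) / 2)),
      alt_alt = sum(log10(p_alt)))
}

# map log10-likelihoods + priors to normalized posteriors
.posteriors <- function(l10, prior) {
  lp <- l10 + log10(prior)
  lp <- lp - max(lp)
  p <- 10^lp
  p / sum(p)
}

#' Joint genotyping across a cohort from multi-sample pileups
#'
#' Calls biallelic SNPs directly from cohort pileup columns. Per site the
#' alternate allele is the most frequent non-reference base across the cohort
#' (ties broken alphabetically; lower-count non-reference bases are dropped,
#' keeping every site biallelic). Per sample the MAP genotype is taken under
#' a prior of `het_prior` for each variant genotype, at the ploidy the
#' region-ploidy map assigns to (karyotype, chromosome, position) — or 2
#' everywhere under the `"force_diploid"` override. Site QUAL is the
#' phred-scaled posterior probability that all samples are homozygous or
#' hemizygous reference (independence across samples); sites with `QUAL > 0`
#' and at least one alternate allele in the genotypes are emitted and
#' annotated via [annotate_sites()].
#'
#' @param pileups A `pileup` data.frame with an additional `sample` column
#'   (multi-sample stack). Reads below the caller's MAPQ floor must already
#'   have been excluded (see [build_pileups()]).
#' @param karyotypes Named character vector, `"XX"`/`"XY"` per sample id.
#' @param reference Named character vector of reference sequences (for
#'   reference bases).
#' @param arch The [genome_architecture()] behind the reference.
#' @param mode `"matched"` or `"force_diploid"` ploidy mode.
#' @param het_prior Prior probability of each variant genotype (default
#'   1e-3, the conventional human heterozygosity prior).
#' @param eps_floor Error-probability floor, see [genotype_likelihoods()].
#' @return A `site_calls` object: list with `sites` (data.frame of annotated
#'   emitted sites with FILTER column), `gt` (sites x samples genotype
#'   matrix; `"."` = no data), `sample_dp` and `sample_gq` matrices, and
#'   `samples`.
#' @export
joint_genotype <- function(pileups, karyotypes, reference, arch,
                           mode = c("matched", "force_diploid"),
                           het_prior = 1e-3, eps_floor = 1e-4) {
  mode <- match.arg(mode)
  samples <- names(karyotypes)
  empty <- .empty_calls(samples)
  if (nrow(pileups) == 0L) return(empty)
  dt <- data.table::as.data.table(pileups)
  dt[, refb := substring(reference[chrom], pos, pos)]
  # alt allele per site: top non-ref base across the cohort
  altdt <- dt[base != refb, .N, by = .(chrom, pos, base)]
  if (nrow(altdt) == 0L) return(empty)
  data.table::setorder(altdt, chrom, pos, -N, base)
  altdt <- altdt[, .(alt = base[1L]), by = .(chrom, pos)]
  dt <- merge(dt, altdt, by = c("chrom", "pos"))
  # per-sample ploidy at each site
  dt[, ploidy := ploidy_at(arch, karyotypes[[.BY$sample]], chrom, pos, mode),
     by = sample]
  dt <- dt[ploidy > 0L]
  if (nrow(dt) == 0L) return(empty)
  e <- pmax(10^(-dt$qual / 10), eps_floor)
  p_ref <- ifelse(dt$base == dt$refb, 1 - e, e / 3)
  p_alt <- ifelse(dt$base == dt$alt, 1 - e, e / 3)
  dt[, `:=`(lp_rr = log10(p_ref), lp_ra = log10((p_ref + p_alt) / 2),
            lp_aa = log10(p_alt))]
  g <- dt[, .(L_rr = sum(lp_rr), L_ra = sum(lp_ra), L_aa = sum(lp_aa),
              dp = .N, ploidy = ploidy[1L], refb = refb[1L],
              alt = alt[1L]),
          by = .(chrom, pos, sample)]
  hp <- het_prior
  post <- t(vapply(seq_len(nrow(g)), function(i) {
    if (g$ploidy[i] == 1L)
      c(.posteriors(c(g$L_rr[i], g$L_aa[i]), c(1 - hp, hp)), NA_real_)
    else
      .posteriors(c(g$L_rr[i], g$L_ra[i], g$L_aa[i]), c(1 - 2 * hp, hp, hp))
  }, numeric(3)))
  g[, post_ref := post[, 1L]]
  g[, gt_idx := max.col(ifelse(is.na(post), -Inf, post))]  # 1=ref,2=het/alt,3=hom-alt
  g[, n_alt := ifelse(ploidy == 1L, as.integer(gt_idx == 2L),
                      as.integer(gt_idx - 1L))]
  g[, gq := pmin(99L, as.integer(round(-10 * log10(pmax(
    1 - post[cbind(seq_len(.N), gt_idx)], 1e-10)))))]
  site <- g[, .(QUAL = -10 * sum(log10(pmax(post_ref, 1e-300))),
                AC = sum(n_alt), AN = sum(ploidy),
                var_dp = sum(dp[n_alt > 0L]),
                ref = refb[1L], alt = alt[1L]),
            by = .(chrom, pos)]
  site <- site[AC >= 1L & QUAL > 0]
  if (nrow(site) == 0L) return(empty)
  data.table::setorder(site, chrom, pos)
  site[, QD := QUAL / var_dp]
  ann <- annotate_sites(dt, site)
  sites <- data.frame(chrom = site$chrom, pos = site$pos, ref = site$ref,
                      alt = site$alt, QUAL = site$QUAL, AC = site$AC,
                      AN = site$AN, DP = ann$DP, QD = site$QD, MQ = ann$MQ,
                      FS = ann$FS, SOR = ann$SOR,
                      MQRankSum = ann$MQRankSum,
                      ReadPosRankSum = ann$ReadPosRankSum,
                      FILTER = ".")
  # genotype matrices
  key <- paste(site$chrom, site$pos)
  gt <- matrix(".", nrow(site), length(samples),
               dimnames = list(key, samples))
  sdp <- matrix(0L, nrow(site), length(samples),
                dimnames = list(key, samples))
  sgq <- matrix(NA_integer_, nrow(site), length(samples),
                dimnames = list(key, samples))
  ge <- g[paste(chrom, pos) %in% key]
  gkey <- paste(ge$chrom, ge$pos)
  gt_str <- ifelse(ge$ploidy == 1L, c("0", "1")[ge$gt_idx],
                   c("0/0", "0/1", "1/1")[ge$gt_idx])
  gt[cbind(match(gkey, key), match(ge$sample, samples))] <- gt_str
  sdp[cbind(match(gkey, key), match(ge$sample, samples))] <- ge$dp
  sgq[cbind(match(gkey, key), match(ge$sample, samples))] <- ge$gq
  structure(list(sites = sites, gt = gt, sample_dp = sdp, sample_gq = sgq,
                 samples = samples, mode = mode),
            class = "site_calls")
}

.empty_calls <- function(samples) {
  sites <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      QUAL = numeric(0), AC = integer(0), AN = integer(0),
                      DP = integer(0), QD = numeric(0), MQ = numeric(0),
                      FS = numeric(0), SOR = numeric(0),
                      MQRankSum = numeric(0), ReadPosRankSum = numeric(0),
                      FILTER = character(0))
  structure(list(sites = sites,
                 gt = matrix(character(0), 0, length(samples),
                             dimnames = list(NULL, samples)),
                 sample_dp = matrix(integer(0), 0, length(samples)),
                 sample_gq = matrix(integer(0), 0, length(samples)),
                 samples = samples, mode = "matched"),
            class = "site_calls")
}

#' GATK-style site annotations from cohort pileup columns
#'
#' Computes, per emitted site: `DP` (depth across genotyped samples), `MQ`
#' (root-mean-square MAPQ of covering reads), `FS` (phred-scaled two-sided
#' Fisher exact p of the ref/alt x forward/reverse strand table), `SOR`
#' (symmetric strand odds ratio with +1 pseudocounts), and `MQRankSum` /
#' `ReadPosRankSum` (normal-approximation Wilcoxon rank-sum z-scores of
#' alt-read versus ref-read MAPQs and distances from the closer read end;
#' `NA` when either allele class has no reads).
#'
#' @param dt Internal per-read table (pileup rows joined with ref/alt).
#' @param site data.table of emitted sites (`chrom`, `pos`).
#' @return data.frame of annotation columns aligned with `site`.
#' @keywords internal
annotate_sites <- function(dt, site) {
  dd <- dt[paste(chrom, pos) %in% paste(site$chrom, site$pos)]
  dd[, is_ref := base == refb]
  dd[, is_alt := base == alt]
  ann <- dd[, {
    rf <- sum(is_ref & strand == "+"); rr <- sum(is_ref & strand == "-")
    af <- sum(is_alt & strand == "+"); ar <- sum(is_alt & strand == "-")
    fs <- if ((rf + rr) > 0L && (af + ar) > 0L) {
      p <- stats::fisher.test(matrix(c(rf, rr, af, ar), 2L))$p.value
      -10 * log10(max(p, 1e-320))
    } else NA_real_
    a <- rf + 1; b <- rr + 1; cc <- af + 1; d <- ar + 1
    sor <- log(a / b * d / cc + b / a * cc / d) +
      log(min(a, b) / max(a, b)) - log(min(cc, d) / max(cc, d))
    .(DP = .N, MQ = sqrt(mean(mapq^2)), FS = fs, SOR = sor,
      MQRankSum = .ranksum_z(mapq[is_alt], mapq[is_ref]),
      ReadPosRankSum = .ranksum_z(enddist[is_alt], enddist[is_ref]))
  }, by = .(chrom, pos)]
  ann[data.table::data.table(chrom = site$chrom, pos = site$pos),
      on = c("chrom", "pos")]
}

# Wilcoxon rank-sum z (alt vs ref) with tie correction; negative when the
# alt reads rank lower
.ranksum_z <- function(x_alt, x_ref) {
  n1 <- length(x_alt); n2 <- length(x_ref)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  r <- rank(c(x_alt, x_ref))
  W <- sum(r[seq_len(n1)])
  N <- n1 + n2
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(0)
  (W - mu) / sqrt(sig2)
}

#' @export
print.site_calls <- function(x, ...) {
  cat(sprintf("site_calls: %d sites x %d samples (%s ploidy)\n",
              nrow(x$sites), length(x$samples), x$mode))
  if (nrow(x$sites)) print(utils::head(x$sites, 5))
  invisible(x)
}

#' Subset a joint call set by site
#'
#' @param calls A `site_calls`.
#' @param idx Logical or integer site index.
#' @return The subset `site_calls` (genotype and per-sample matrices kept in
#'   step with the site table).
#' @export
calls_subset <- function(calls, idx) {
  calls$sites <- calls$sites[idx, , drop = FALSE]
  rownames(calls$sites) <- NULL
  calls$gt <- calls$gt[idx, , drop = FALSE]
  calls$sample_dp <- calls$sample_dp[idx, , drop = FALSE]
  calls$sample_gq <- calls$sample_gq[idx, , drop = FALSE]
  calls
}

#' Write joint calls to VCF 4.2
#'
#' INFO carries DP, AN, AC, QD, MQ, FS, SOR, MQRankSum, ReadPosRankSum;
#' FORMAT is GT:DP:GQ with the mixed-ploidy genotypes as called.
#'
#' @param calls A `site_calls` object.
#' @param path Output path.
#' @param arch A [genome_architecture()] for contig headers.
#' @return Invisibly, `path`.
#' @export
write_calls_vcf <- function(calls, path, arch) {
  s <- calls$sites
  info_num <- function(x) ifelse(is.na(x), ".", formatC(x, digits = 4,
                                                        format = "f"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sexchrombench_caller",
           sprintf("##contig=<ID=%s,length=%d>", names(arch$chrom_lengths),
                   arch$chrom_lengths),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Called allele number\">",
           "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt allele count\">",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Qual by depth\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
           "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Symmetric odds ratio\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Alt vs ref MAPQ rank sum z\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Alt vs ref read position rank sum z\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Sample depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", calls$samples), collapse = "\t"))
  if (nrow(s)) {
    info <- sprintf(
      "DP=%d;AN=%d;AC=%d;QD=%s;MQ=%s;FS=%s;SOR=%s;MQRankSum=%s;ReadPosRankSum=%s",
      s$DP, s$AN, s$AC, info_num(s$QD), info_num(s$MQ), info_num(s$FS),
      info_num(s$SOR), info_num(s$MQRankSum), info_num(s$ReadPosRankSum))
    fmt <- vapply(seq_len(nrow(s)), function(i) {
      paste(sprintf("%s:%d:%s", calls$gt[i, ], calls$sample_dp[i, ],
                    ifelse(is.na(calls$sample_gq[i, ]), ".",
                           calls$sample_gq[i, ])), collapse = "\t")
    }, character(1))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\t%s\t%s\tGT:DP:GQ\t%s",
                    s$chrom, s$pos, s$ref, s$alt, s$QUAL,
                    ifelse(s$FILTER == ".", ".", s$FILTER), info, fmt)
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
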
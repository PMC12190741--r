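#' Simulate, trim, and return reads for every sample of a cohort
#'
#' @param cohort List of `sample_truth` objects from [simulate_cohort()].
#' @param refpair,arch Matching reference pair and architecture.
#' @param policy,params,trim_cfg Simulation and trimming settings.
#' @param seed Integer seed; per-sample seeds are derived from it.
#' @return Named list (by sample id) of trimmed `read_set`s.
#' @export
simulate_cohort_reads <- function(cohort, refpair, arch,
                                  policy = coverage_policy(),
                                  params = read_params(),
                                  trim_cfg = trim_config(), seed = 1L) {
  out <- list()
  for (i in seq_along(cohort)) {
    r <- simulate_reads(cohort[[i]], refpair, arch, policy, params,
                        seed = seed * 1000L + i)
    out[[cohort[[i]]$sample_id]] <- trim_reads(r, trim_cfg)$reads
  }
  out
}

#' Map a cohort and jointly genotype it against one reference
#'
#' Runs the mapper per sample, pools MAPQ-filtered base counts to find
#' candidate variant positions (at least `min_alt` non-reference bases across
#' the cohort), extracts full pileup columns at the candidates, and joint
#' genotypes the cohort with [joint_genotype()].
#'
#' @param reads_list Named list of trimmed `read_set`s (see
#'   [simulate_cohort_reads()]).
#' @param karyotypes Named `"XX"`/`"XY"` vector, same names as `reads_list`.
#' @param reference Named character vector (a [build_reference()] output).
#' @param arch The [genome_architecture()].
#' @param mode Ploidy mode, `"matched"` or `"force_diploid"`.
#' @param seed Seed for mapper tie-breaking.
#' @param min_mapq MAPQ floor for calling (multi-mappers at MAPQ 0 are always
#'   excluded).
#' @param min_alt Minimum pooled non-reference base count for a position to
#'   become a candidate.
#' @param het_prior,eps_floor Passed to [joint_genotype()].
#' @return A `site_calls` object.
#' @export
call_cohort <- function(reads_list, karyotypes, reference, arch,
                        mode = "matched", seed = 1L, min_mapq = 20L,
                        min_alt = 2L, het_prior = 1e-3, eps_floor = 1e-4) {
  samples <- names(reads_list)
  alns <- list()
  counts <- NULL
  for (i in seq_along(samples)) {
    aln <- map_reads(reads_list[[i]], reference, seed = seed + i)
    alns[[samples[i]]] <- aln
    cc <- pileup_base_counts(aln, reads_list[[i]], reference,
                             min_mapq = min_mapq, drop_mapq0 = TRUE)
    counts <- if (is.null(counts)) cc else
      mapply(`+`, counts, cc, SIMPLIFY = FALSE)
  }
  # candidate positions: pooled non-reference depth >= min_alt
  positions <- lapply(names(reference), function(ch) {
    m <- counts[[ch]]
    if (!ncol(m)) return(integer(0))
    refc <- strsplit(reference[[ch]], "")[[1]]
    ridx <- match(refc, BASES)
    tot <- colSums(m)
    refd <- ifelse(is.na(ridx), 0L, m[cbind(ridx, seq_along(ridx))])
    which(tot - refd >= min_alt & !is.na(ridx)) - 1L
  })
  names(positions) <- names(reference)
  cols <- list()
  for (i in seq_along(samples)) {
    p <- build_pileups(alns[[i]], reads_list[[i]], reference,
                       positions = positions, min_mapq = min_mapq,
                       drop_mapq0 = TRUE)
    if (nrow(p)) {
      p$sample <- samples[i]
      cols[[length(cols) + 1L]] <- p
    }
  }
  cols <- if (length(cols)) do.call(rbind, cols) else
    cbind(data.frame(chrom = character(0), pos = integer(0),
                     base = character(0), qual = integer(0),
                     mapq = integer(0), strand = character(0),
                     enddist = integer(0), read_row = integer(0)),
          sample = character(0))
  joint_genotype(cols, karyotypes[samples], reference, arch, mode = mode,
                 het_prior = het_prior, eps_floor = eps_floor)
}

#' Score a joint call set against a cohort's golden truth
#'
#' @param calls A `site_calls`.
#' @param cohort The list of `sample_truth` objects the calls refer to.
#' @param arch The [genome_architecture()].
#' @param pass_only Score only PASS/unfiltered sites.
#' @param window Window size for the per-window tracks.
#' @return List with `labels` (per-sample `bench_labels`), `region`
#'   (summed-over-samples region table plus `TP_mean` etc. columns), and
#'   `windows` (cross-sample mean TP/FP/FN per window).
#' @export
bench_cohort <- function(calls, cohort, arch, pass_only = TRUE,
                         window = 50000L) {
  labels <- list()
  region <- NULL
  wins <- NULL
  n <- length(cohort)
  for (s in cohort) {
    g <- golden_sites(s, arch)
    called <- sample_called_sites(calls, s$sample_id, pass_only = pass_only)
    lab <- classify_calls(g[, c("chrom", "pos", "ref", "alt")], called)
    labels[[s$sample_id]] <- lab
    rg <- stratify_by_region(lab, arch)
    wc <- window_counts(lab, arch, window)
    if (is.null(region)) {
      region <- rg
      wins <- wc
    } else {
      region[, c("TP", "FP", "FN", "simulated")] <-
        region[, c("TP", "FP", "FN", "simulated")] +
        rg[, c("TP", "FP", "FN", "simulated")]
      wins[, c("TP", "FP", "FN")] <- wins[, c("TP", "FP", "FN")] +
        wc[, c("TP", "FP", "FN")]
    }
  }
  region$fp_prop <- ifelse(region$simulated > 0,
                           region$FP / region$simulated, NA_real_)
  region$fn_prop <- ifelse(region$simulated > 0,
                           region$FN / region$simulated, NA_real_)
  for (col in c("TP", "FP", "FN")) region[[paste0(col, "_mean")]] <-
    region[[col]] / n
  wins[, c("TP", "FP", "FN")] <- wins[, c("TP", "FP", "FN")] / n
  list(labels = labels, region = region, windows = wins)
}

#' Run the full alignment x ploidy x filtering experiment
#'
#' Executes the factorial contrast at the heart of the benchmark: an XX and
#' an XY cohort are simulated once; their reads are mapped against the
#' reference variants (default, sex-chromosome-complement, and for XY
#' additionally the Y-XTR-masked SCC reference) and called under the
#' requested ploidy modes; hard filters are applied; and every cell is
#' scored against the golden truth per sample, region class, and window.
#'
#' @param arch A [genome_architecture()] (default: the package's toy X/Y
#'   pair, 200 kb each, plus a 100-kb autosome).
#' @param n_xx,n_xy Cohort sizes (default 10 + 10, the subset size used for
#'   the headline region contrasts).
#' @param theta Per-base per-haplotype SNP density.
#' @param seed Master seed; everything downstream derives from it and the
#'   bundle is reproducible byte-for-byte.
#' @param cells data.frame with columns `cohort` (`"XX"`/`"XY"`), `kind`
#'   (reference kind), `mode` (ploidy mode); defaults to the full benchmark
#'   factorial.
#' @param policy,params,trim_cfg,filter_cfg Component settings.
#' @param window Track window size (default 50 kb).
#' @return A `bench_report`: list with `cells` (per cell: `calls` with
#'   FILTER set, `bench` from [bench_cohort()] on PASS sites, `bench_raw` on
#'   unfiltered sites), the cohorts, and a `summary` numeric vector with the
#'   headline quantities (PAR TP means under default vs SCC, the XTR
#'   masking over-call ratio, Y non-PAR TP difference).
#' @export
run_experiment <- function(arch = genome_architecture(), n_xx = 10L,
                           n_xy = 10L, theta = 0.001, seed = 1L,
                           cells = NULL, policy = coverage_policy(),
                           params = read_params(),
                           trim_cfg = trim_config(),
                           filter_cfg = filter_config(),
                           window = 50000L) {
  validate_architecture(arch)
  if (is.null(cells))
    cells <- data.frame(
      cohort = c("XX", "XX", "XY", "XY", "XY", "XY"),
      kind = c("default", "xx_scc", "default", "xy_scc", "xy_scc",
               "xy_scc_yxtr_masked"),
      mode = c("matched", "matched", "matched", "matched", "force_diploid",
               "matched"))
  refpair <- simulate_reference_pair(arch, seed = seed)
  cohort <- simulate_cohort(arch, refpair, n_xx = n_xx, n_xy = n_xy,
                            theta = theta, seed = seed + 1L)
  kar <- vapply(cohort, `[[`, character(1), "karyotype")
  names(kar) <- vapply(cohort, `[[`, character(1), "sample_id")
  groups <- list(XX = cohort[kar == "XX"], XY = cohort[kar == "XY"])
  reads <- list()
  for (gk in names(groups))
    if (length(groups[[gk]]))
      reads[[gk]] <- simulate_cohort_reads(groups[[gk]], refpair, arch,
                                           policy, params, trim_cfg,
                                           seed = seed + 2L)
  out_cells <- list()
  for (i in seq_len(nrow(cells))) {
    ck <- cells$cohort[i]
    if (!length(groups[[ck]])) next
    refseqs <- build_reference(cells$kind[i], refpair, arch)
    calls <- call_cohort(reads[[ck]], kar[names(reads[[ck]])], refseqs,
                         arch, mode = cells$mode[i], seed = seed + 3L)
    calls <- apply_hard_filters(calls, filter_cfg)
    nm <- sprintf("%s_%s_%s", ck, cells$kind[i], cells$mode[i])
    out_cells[[nm]] <- list(
      cohort = ck, kind = cells$kind[i], mode = cells$mode[i],
      calls = calls,
      bench = bench_cohort(calls, groups[[ck]], arch, pass_only = TRUE,
                           window = window),
      bench_raw = bench_cohort(calls, groups[[ck]], arch, pass_only = FALSE,
                               window = window))
  }
  report <- structure(list(arch = arch, seed = seed, cells = out_cells,
                           cohort = cohort,
                           config = list(n_xx = n_xx, n_xy = n_xy,
                                         theta = theta)),
                      class = "bench_report")
  report$summary <- .report_summary(report)
  report
}

.region_value <- function(bench, chrom, region, col) {
  r <- bench$region
  v <- r[[col]][r$chrom == chrom & r$region == region]
  if (length(v)) v else NA_real_
}

#' Ratio of called to per-sample simulated XTR sites
#'
#' The over-calling statistic for the Y-XTR-masked contrast: the number of
#' sites joint-called in the X-chromosome XTR across the cohort divided by
#' the mean number of simulated X-XTR variant sites per sample.
#'
#' @param calls A `site_calls` (unfiltered joint calls).
#' @param cohort The matching cohort.
#' @param arch The [genome_architecture()].
#' @return The fold ratio.
#' @export
xtr_overcall_ratio <- function(calls, cohort, arch) {
  s <- calls$sites
  cls <- region_class_at(arch, s$chrom, s$pos)
  called <- sum(s$chrom == "X" & cls == "XTR")
  sim <- vapply(cohort, function(smp) {
    g <- golden_sites(smp, arch)
    if (!nrow(g)) return(0)
    sum(g$chrom == "X" &
          region_class_at(arch, g$chrom, g$pos) == "XTR")
  }, numeric(1))
  called / mean(sim)
}

.report_summary <- function(report) {
  cells <- report$cells
  s <- c()
  gx <- report$cohort[vapply(report$cohort, `[[`, character(1),
                             "karyotype") == "XX"]
  gy <- report$cohort[vapply(report$cohort, `[[`, character(1),
                             "karyotype") == "XY"]
  if (!is.null(cells$XX_default_matched))
    s["xx_default_par_tp_mean"] <-
      .region_value(cells$XX_default_matched$bench, "X", "PAR", "TP_mean")
  if (!is.null(cells$XX_xx_scc_matched))
    s["xx_scc_par_tp_mean"] <-
      .region_value(cells$XX_xx_scc_matched$bench, "X", "PAR", "TP_mean")
  if (!is.null(cells$XY_default_matched) && !is.null(cells$XY_xy_scc_matched)) {
    s["xy_y_nonpar_tp_diff"] <-
      .region_value(cells$XY_default_matched$bench, "Y", "NONPAR", "TP") -
      .region_value(cells$XY_xy_scc_matched$bench, "Y", "NONPAR", "TP")
  }
  if (!is.null(cells$XY_xy_scc_yxtr_masked_matched))
    s["xtr_overcall_ratio"] <- xtr_overcall_ratio(
      cells$XY_xy_scc_yxtr_masked_matched$calls, gy, report$arch)
  s
}

#' @export
print.bench_report <- function(x, ...) {
  cat("bench_report (seed ", x$seed, "), cells:\n", sep = "")
  for (nm in names(x$cells)) cat("  ", nm, "\n")
  if (length(x$summary)) {
    cat("summary:\n")
    print(round(x$summary, 4))
  }
  invisible(x)
}
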
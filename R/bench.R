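#' Per-sample called sites from a joint call set
#'
#' Explodes the joint genotype matrix: a sample carries a site iff its
#' genotype contains at least one alternate allele.
#'
#' @param calls A `site_calls`.
#' @param sample Sample id.
#' @param pass_only Keep only `PASS`/unfiltered sites.
#' @return data.frame `chrom`, `pos`, `ref`, `alt`, `gt`.
#' @export
sample_called_sites <- function(calls, sample, pass_only = FALSE) {
  if (pass_only) calls <- pass_sites(calls)
  gt <- calls$gt[, sample]
  keep <- grepl("1", gt, fixed = TRUE)
  out <- calls$sites[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  out$gt <- gt[keep]
  rownames(out) <- NULL
  out
}

#' Classify called sites against a golden truth set
#'
#' Site/allele-level scoring: a true positive is a SNP both called and
#' simulated with matching reference and alternate allele; a false positive
#' is called but not simulated; a false negative is simulated but not
#' called. A position present in both but with a mismatching alternate
#' allele yields one FP and one FN (flagged in `alt_mismatch` so the
#' convention can be audited). Genotypes are not compared.
#'
#' @param golden data.frame `chrom`, `pos`, `ref`, `alt` (one sample's
#'   golden sites, e.g. [golden_sites()] or [read_golden_vcf()]).
#' @param called data.frame `chrom`, `pos`, `ref`, `alt` (e.g.
#'   [sample_called_sites()]).
#' @return A `bench_labels` data.frame: `chrom`, `pos`, `label` (TP/FP/FN),
#'   `ref`, `alt`, `alt_mismatch`.
#' @export
classify_calls <- function(golden, called) {
  gkey <- paste(golden$chrom, golden$pos)
  ckey <- paste(called$chrom, called$pos)
  m <- match(ckey, gkey)
  matched <- !is.na(m)
  allele_ok <- matched & golden$ref[m] == called$ref &
    golden$alt[m] == called$alt
  tp <- data.frame(chrom = called$chrom[allele_ok],
                   pos = called$pos[allele_ok],
                   label = rep("TP", sum(allele_ok)),
                   ref = called$ref[allele_ok], alt = called$alt[allele_ok],
                   alt_mismatch = rep(FALSE, sum(allele_ok)))
  fp_sel <- !allele_ok
  fp <- data.frame(chrom = called$chrom[fp_sel], pos = called$pos[fp_sel],
                   label = rep("FP", sum(fp_sel)), ref = called$ref[fp_sel],
                   alt = called$alt[fp_sel],
                   alt_mismatch = matched[fp_sel])
  fn_sel <- !(gkey %in% ckey[allele_ok])
  fn <- data.frame(chrom = golden$chrom[fn_sel], pos = golden$pos[fn_sel],
                   label = rep("FN", sum(fn_sel)), ref = golden$ref[fn_sel],
                   alt = golden$alt[fn_sel],
                   alt_mismatch = gkey[fn_sel] %in% ckey)
  out <- rbind(tp, fp, fn)
  out <- out[order(out$chrom, out$pos, out$label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bench_labels", "data.frame")
  out
}

#' Stratify benchmark labels by region class
#'
#' Tallies TP/FP/FN per chromosome and region class, with FP and FN
#' proportions relative to the number of simulated sites (TP + FN) in that
#' class. Region classes follow the architecture (`PAR1` and `PAR2` are
#' reported together as `PAR`).
#'
#' @param labels A `bench_labels` data.frame from [classify_calls()].
#' @param arch The [genome_architecture()].
#' @return data.frame `chrom`, `region`, `TP`, `FP`, `FN`, `simulated`,
#'   `fp_prop`, `fn_prop` (proportions `NA` when nothing was simulated).
#'   Includes one `ALL` row per chromosome.
#' @export
stratify_by_region <- function(labels, arch) {
  cls <- region_class_at(arch, labels$chrom, labels$pos)
  if (anyNA(cls) && nrow(labels))
    stop("label outside any region: ",
         paste(labels$chrom[is.na(cls)][1], labels$pos[is.na(cls)][1]))
  cls[cls %in% c("PAR1", "PAR2")] <- "PAR"
  grid <- unique(rbind(
    data.frame(chrom = arch$regions$chrom,
               region = ifelse(arch$regions$class %in% c("PAR1", "PAR2"),
                               "PAR", arch$regions$class)),
    data.frame(chrom = names(arch$chrom_lengths), region = "ALL")))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- labels$chrom == grid$chrom[i] &
      (grid$region[i] == "ALL" | cls == grid$region[i])
    n <- table(factor(labels$label[sel], levels = c("TP", "FP", "FN")))
    sim <- n[["TP"]] + n[["FN"]]
    data.frame(chrom = grid$chrom[i], region = grid$region[i],
               TP = n[["TP"]], FP = n[["FP"]], FN = n[["FN"]],
               simulated = sim,
               fp_prop = if (sim > 0) n[["FP"]] / sim else NA_real_,
               fn_prop = if (sim > 0) n[["FN"]] / sim else NA_real_)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally benchmark labels in fixed windows
#'
#' Windows are anchored at coordinate 0, `[i * w, (i + 1) * w)`, with the
#' final window truncated at the chromosome end.
#'
#' @param labels A `bench_labels` data.frame.
#' @param arch The [genome_architecture()].
#' @param window Window size in bp (default 50 kb).
#' @return data.frame `chrom`, `start`, `end`, `TP`, `FP`, `FN` covering
#'   every window of every chromosome.
#' @export
window_counts <- function(labels, arch, window = 50000L) {
  out <- list()
  for (ch in names(arch$chrom_lengths)) {
    len <- arch$chrom_lengths[[ch]]
    starts <- seq.int(0L, len - 1L, by = window)
    ends <- pmin(starts + window, len)
    sel <- labels$chrom == ch
    widx <- (labels$pos[sel] - 1L) %/% window + 1L
    tab <- table(factor(widx, levels = seq_along(starts)),
                 factor(labels$label[sel], levels = c("TP", "FP", "FN")))
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            TP = as.integer(tab[, "TP"]),
                            FP = as.integer(tab[, "FP"]),
                            FN = as.integer(tab[, "FN"]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
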
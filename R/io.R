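#' Write alignments as a SAM-like TSV
#'
#' Columns: read id, chromosome, 0-based position, strand, mismatch count
#' (NM), MAPQ, aligned length. Unaligned reads are omitted.
#'
#' @param aln An `alignment_set` from [map_reads()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignments <- function(aln, path) {
  a <- aln[aln$aligned, c("read_id", "chrom", "start0", "strand", "nm",
                          "mapq", "length"), drop = FALSE]
  utils::write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a joint call VCF back into a `site_calls` object
#'
#' Inverse of [write_calls_vcf()] (INFO numbers round-trip at the precision
#' they were formatted with).
#'
#' @param path VCF path.
#' @return A `site_calls` object.
#' @export
read_calls_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  samples <- colnames(v@gt)[-1]
  if (nrow(fix) == 0L) return(.empty_calls(samples))
  num <- function(field) suppressWarnings(as.numeric(
    vcfR::extract.info(v, field)))
  sites <- data.frame(
    chrom = as.character(fix[, "CHROM"]), pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]), alt = as.character(fix[, "ALT"]),
    QUAL = as.numeric(fix[, "QUAL"]),
    AC = as.integer(num("AC")), AN = as.integer(num("AN")),
    DP = as.integer(num("DP")), QD = num("QD"), MQ = num("MQ"),
    FS = num("FS"), SOR = num("SOR"), MQRankSum = num("MQRankSum"),
    ReadPosRankSum = num("ReadPosRankSum"),
    FILTER = ifelse(is.na(fix[, "FILTER"]), ".",
                    as.character(fix[, "FILTER"])))
  gt <- vcfR::extract.gt(v, "GT")
  gt[is.na(gt)] <- "."
  as_int_mat <- function(m) matrix(suppressWarnings(as.integer(m)),
                                   nrow = nrow(sites))
  dp <- as_int_mat(vcfR::extract.gt(v, "DP"))
  gq <- as_int_mat(vcfR::extract.gt(v, "GQ"))
  dp[is.na(dp)] <- 0L
  dimnames(gt) <- dimnames(dp) <- dimnames(gq) <-
    list(paste(sites$chrom, sites$pos), samples)
  structure(list(sites = sites, gt = gt, sample_dp = dp, sample_gq = gq,
                 samples = samples, mode = "matched"),
            class = "site_calls")
}

#' Write a benchmark report bundle to disk
#'
#' Emits, per experiment cell, the region-stratified table and the
#' per-window tracks as TSV, plus a JSON file with the summary quantities.
#'
#' @param report A `bench_report` from [run_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(report$cells)) {
    cell <- report$cells[[nm]]
    utils::write.table(cell$bench$region,
                       file.path(dir, paste0(nm, "_regions.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cell$bench$windows,
                       file.path(dir, paste0(nm, "_windows.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(as.list(report$summary),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
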
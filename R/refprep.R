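#' Hard-mask intervals of reference sequences
#'
#' Replaces every base inside the given 0-based half-open intervals with `N`
#' (uppercase hard masking); all other bases and all sequence lengths are
#' unchanged. Masking is idempotent and order-independent over interval sets.
#'
#' @param sequences Named character vector of sequences, or a
#'   `reference_pair`.
#' @param bed data.frame with columns `chrom`, `start`, `end` (additional
#'   columns ignored), or a path to a BED file.
#' @return Named character vector with masked sequences.
#' @export
mask_intervals <- function(sequences, bed) {
  if (inherits(sequences, "reference_pair")) sequences <- sequences$sequences
  if (is.character(bed) && length(bed) == 1L) {
    bed <- utils::read.table(bed, sep = "\t", stringsAsFactors = FALSE)
    names(bed)[1:3] <- c("chrom", "start", "end")
  }
  for (i in seq_len(nrow(bed))) {
    ch <- as.character(bed$chrom[i])
    s <- as.integer(bed$start[i]); e <- as.integer(bed$end[i])
    if (!ch %in% names(sequences))
      stop("interval on unknown chromosome: ", ch)
    L <- nchar(sequences[[ch]])
    if (s < 0L || e > L || e <= s)
      stop(sprintf("interval %s:[%d,%d) outside sequence bounds [0,%d)",
                   ch, s, e, L))
    substr(sequences[[ch]], s + 1L, e) <- strrep("N", e - s)
  }
  sequences
}

REFERENCE_KINDS <- c("default", "xx_scc", "xy_scc", "xy_scc_yxtr_masked")

#' Build a reference variant by sex-chromosome-complement masking
#'
#' The four reference versions contrasted by the benchmark:
#' \describe{
#'   \item{`default`}{no masking; both X and Y carry their PAR copies (the
#'     PAR duplication is what collapses PAR mapping qualities).}
#'   \item{`xx_scc`}{sex-chromosome-complement reference for XX samples: the
#'     entire Y chromosome hard-masked.}
#'   \item{`xy_scc`}{SCC reference for XY samples: PAR1 and PAR2 on Y
#'     hard-masked.}
#'   \item{`xy_scc_yxtr_masked`}{as `xy_scc`, additionally hard-masking the
#'     Y-chromosome XTR.}
#' }
#'
#' @param kind One of `r paste0('\x60', REFERENCE_KINDS, '\x60', collapse = ", ")`.
#' @param refpair A [simulate_reference_pair()] result.
#' @param arch The matching [genome_architecture()].
#' @return Named character vector of (possibly masked) sequences.
#' @export
build_reference <- function(kind, refpair, arch) {
  kind <- match.arg(kind, REFERENCE_KINDS)
  seqs <- refpair$sequences
  bed <- switch(kind,
    default = NULL,
    xx_scc = data.frame(chrom = "Y", start = 0L,
                        end = arch$chrom_lengths[["Y"]]),
    xy_scc = arch_regions(arch, chrom = "Y", class = "PAR"),
    xy_scc_yxtr_masked = arch_regions(arch, chrom = "Y",
                                      class = c("PAR1", "PAR2", "XTR")))
  if (is.null(bed) || nrow(bed) == 0L) return(seqs)
  mask_intervals(seqs, bed)
}
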
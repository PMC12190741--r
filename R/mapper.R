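#' Map a read set to a reference
#'
#' An ungapped, mismatch-count mapper for toy genomes: candidate placements
#' on both strands come from a k-mer positional index, each candidate is
#' scored by its Hamming distance to the reference over the full read length
#' (reference `N` counts as a mismatch, which is how hard masking repels
#' reads), and the best placement wins. If two or more placements are
#' co-optimal the read is a multi-mapper: one placement is chosen uniformly
#' by a per-read seeded hash and MAPQ is set to 0. Otherwise MAPQ is the
#' surrogate `min(60, 6 * (second_best_mm - best_mm) + 20)`; a read with no
#' scoreable second placement gets MAPQ 60. Reads whose best placement
#' exceeds `max_mm` mismatches (or that contain `N`) are unaligned.
#'
#' Base qualities are ignored during placement; only the MAPQ = 0 (tie) and
#' MAPQ >= 40 (unique) regimes matter downstream, because multi-mappers are
#' excluded from calling and the hard-filter set removes MQ < 40 sites.
#'
#' @param reads A `read_set` (or any data.frame with `seq`; `read_id`/`qual`
#'   carried through when present).
#' @param reference Named character vector of sequences, or a
#'   `reference_pair`.
#' @param k Seed k-mer length.
#' @param stride Offset step between successive seed k-mers along the read.
#' @param max_mm Maximum mismatches for a placement to be reported.
#' @param seed Integer seed for multi-mapper tie-breaking. Tie-breaks hash
#'   the seed with the read index, so each read's placement is independent of
#'   every other read.
#' @return An `alignment_set`: data.frame with `read_id`, `chrom`, `start0`
#'   (0-based), `strand`, `nm`, `mapq`, `n_best`, `length`, `aligned`, plus a
#'   `read_row` index into `reads`. Unaligned reads keep a row with `aligned
#'   = FALSE`.
#' @export
map_reads <- function(reads, reference, k = 21L, stride = 7L, max_mm = 25L,
                      seed = 1L) {
  if (inherits(reference, "reference_pair")) reference <- reference$sequences
  res <- .map_reads_cpp(unname(reference), reads$seq, as.integer(k),
                        as.integer(stride), as.integer(max_mm),
                        as.double(seed))
  out <- data.frame(
    read_id = if ("read_id" %in% names(reads)) reads$read_id else
      as.character(seq_len(nrow(reads))),
    read_row = seq_len(nrow(reads)),
    chrom = names(reference)[res$chrom_idx],
    chrom_idx = res$chrom_idx,
    start0 = res$start0,
    strand = res$strand,
    nm = res$nm,
    mapq = res$mapq,
    n_best = res$n_best,
    length = nchar(reads$seq))
  out$aligned <- !is.na(out$chrom_idx)
  class(out) <- c("alignment_set", "data.frame")
  out
}

#' Align a single read
#'
#' Convenience wrapper around [map_reads()] for one sequence.
#'
#' @param read A character scalar (A/C/G/T).
#' @param reference Named character vector or `reference_pair`.
#' @inheritParams map_reads
#' @return One-row `alignment_set` (with `aligned = FALSE` if no placement
#'   within `max_mm`).
#' @export
align_read <- function(read, reference, k = 21L, stride = 7L, max_mm = 25L,
                       seed = 1L) {
  map_reads(data.frame(read_id = "read", seq = read), reference, k = k,
            stride = stride, max_mm = max_mm, seed = seed)
}

#' Build pileup columns from alignments
#'
#' Stacks the aligned reads over reference positions into per-site columns
#' carrying each covering read's base (in reference orientation), base
#' quality, MAPQ, strand, and distance from the closer read end.
#'
#' @param aln An `alignment_set` from [map_reads()].
#' @param reads The `read_set` that was mapped (supplies `seq` and `qual`).
#' @param reference Named character vector or `reference_pair` (for
#'   chromosome names and lengths).
#' @param positions Optional named list (per chromosome) of 0-based positions
#'   to restrict to; default all covered positions.
#' @param min_mapq Exclude reads with MAPQ below this floor.
#' @param drop_mapq0 Exclude MAPQ-0 multi-mappers regardless of `min_mapq`.
#' @return A `pileup`: data.frame with `chrom`, `pos` (1-based), `base`,
#'   `qual`, `mapq`, `strand`, `enddist`, `read_row`.
#' @export
build_pileups <- function(aln, reads, reference, positions = NULL,
                          min_mapq = 0L, drop_mapq0 = FALSE) {
  if (inherits(reference, "reference_pair")) reference <- reference$sequences
  ref_lens <- nchar(reference)
  if (is.null(positions)) {
    positions <- lapply(names(reference), function(ch) {
      a <- aln[aln$aligned & aln$chrom == ch, , drop = FALSE]
      if (!nrow(a)) return(integer(0))
      sort(unique(unlist(mapply(function(s, l) s:(s + l - 1L), a$start0,
                                a$length, SIMPLIFY = FALSE))))
    })
    names(positions) <- names(reference)
  }
  positions <- lapply(positions, as.integer)
  res <- .extract_columns_cpp(aln$chrom_idx, aln$start0,
                              as.integer(aln$strand == "-"), aln$read_row,
                              aln$mapq, reads$seq, reads$qual,
                              positions[names(reference)],
                              unname(ref_lens), as.integer(min_mapq),
                              isTRUE(drop_mapq0))
  out <- data.frame(chrom = names(reference)[res$chrom_idx],
                    pos = res$pos, base = res$base, qual = res$qual,
                    mapq = res$mapq, strand = res$strand,
                    enddist = res$enddist, read_row = res$read_row)
  class(out) <- c("pileup", "data.frame")
  out
}

#' Per-position base counts from alignments
#'
#' Fast path used for variant-candidate detection: counts of A/C/G/T per
#' reference position after the MAPQ floor.
#'
#' @inheritParams build_pileups
#' @return Named list (per chromosome) of 4 x L integer matrices with rows
#'   A, C, G, T.
#' @export
pileup_base_counts <- function(aln, reads, reference, min_mapq = 0L,
                               drop_mapq0 = FALSE) {
  if (inherits(reference, "reference_pair")) reference <- reference$sequences
  res <- .pileup_counts_cpp(aln$chrom_idx, aln$start0,
                            as.integer(aln$strand == "-"), aln$read_row,
                            aln$mapq, reads$seq, unname(nchar(reference)),
                            as.integer(min_mapq), isTRUE(drop_mapq0))
  names(res) <- names(reference)
  for (ch in names(res)) rownames(res[[ch]]) <- BASES
  res
}
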
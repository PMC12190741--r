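#' Read-simulation parameters
#'
#' @param read_length Read length in bp (default 150).
#' @param frag_mean,frag_sd Normal fragment-length mean and sd in bp.
#' @param qual_high Baseline Phred quality of simulated bases (default Q25).
#' @param qual_low Quality assigned to demoted 3'-end runs (default Q12).
#' @param low_frac Expected fraction of bases demoted to `qual_low`; demotion
#'   happens as an end-biased run on the 3' end of half the reads, so default
#'   0.10 means half the reads carry a run of mean length `0.2 * read_length`.
#'   This gives the quality trimmer realistic work to do.
#' @param error_rate If `NULL` (default) each base is flipped to a uniformly
#'   chosen different base with probability `10^(-Q/10)` derived from its own
#'   quality. A numeric value overrides this with a constant per-base error
#'   rate (qualities are still written), e.g. `0` for error-free reads.
#' @return A list of class `read_params`.
#' @export
read_params <- function(read_length = 150L, frag_mean = 350, frag_sd = 50,
                        qual_high = 25L, qual_low = 12L, low_frac = 0.10,
                        error_rate = NULL) {
  stopifnot(read_length <= frag_mean, is.null(error_rate) ||
              (error_rate >= 0 && error_rate < 0.75))
  structure(list(read_length = as.integer(read_length),
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 qual_high = as.integer(qual_high),
                 qual_low = as.integer(qual_low),
                 low_frac = low_frac, error_rate = error_rate),
            class = "read_params")
}

#' Coverage policy
#'
#' Sequencing depth is expressed per haplotype copy: every chromosome copy a
#' sample carries is sequenced to `depth_per_copy`. Diploid regions (two
#' copies) therefore reach `2 * depth_per_copy` (20x at the default) while
#' haploid X and Y in XY samples reach `depth_per_copy` (10x) each, matching
#' the half-coverage expectation for haploid chromosomes.
#'
#' @param depth_per_copy Expected depth contributed by one haplotype copy.
#' @return A list of class `coverage_policy`.
#' @export
coverage_policy <- function(depth_per_copy = 10) {
  stopifnot(depth_per_copy > 0)
  structure(list(depth_per_copy = depth_per_copy), class = "coverage_policy")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# segment table for read generation: haplotype intervals split at region
# boundaries so fragments never span a region-class junction
.haplotype_segments <- function(arch, karyotype) {
  haps <- .haplotype_intervals(arch, karyotype)
  lapply(haps, function(iv) {
    out <- lapply(seq_len(nrow(iv)), function(i) {
      r <- arch$regions[arch$regions$chrom == iv$chrom[i] &
                          arch$regions$start < iv$end[i] &
                          arch$regions$end > iv$start[i], , drop = FALSE]
      data.frame(chrom = iv$chrom[i],
                 start = pmax(r$start, iv$start[i]),
                 end = pmin(r$end, iv$end[i]),
                 src = iv$src[i], class = r$class)
    })
    do.call(rbind, out)
  })
}

# apply one haplotype's SNPs to a reference substring
.apply_snps <- function(seq_chars, chrom, start0, snps, hap) {
  s <- snps[snps$hap == hap & snps$chrom == chrom &
              snps$pos > start0 & snps$pos <= start0 + length(seq_chars), ,
            drop = FALSE]
  if (nrow(s)) seq_chars[s$pos - start0] <- s$alt
  seq_chars
}

.phred_string <- function(qmat) {
  qc <- matrix(strsplit(intToUtf8(33:126), "")[[1]][qmat + 1L], nrow(qmat))
  do.call(paste0, as.data.frame(qc, stringsAsFactors = FALSE))
}

# vectorised error injection + string assembly for a base matrix (rows=reads)
.finish_reads <- function(bmat, params) {
  n <- nrow(bmat); rl <- ncol(bmat)
  qmat <- matrix(params$qual_high, n, rl)
  demote <- stats::runif(n) < 0.5
  k <- integer(n)
  k[demote] <- stats::rbinom(sum(demote), rl, min(1, 2 * params$low_frac))
  tail_mask <- col(qmat) > (rl - k[row(qmat)])
  qmat[tail_mask] <- params$qual_low
  e <- if (is.null(params$error_rate)) 10^(-qmat / 10) else params$error_rate
  if (any(e > 0)) {
    err <- matrix(stats::runif(n * rl), n, rl) < e
    if (any(err)) {
      shift <- sample.int(3L, sum(err), replace = TRUE)
      code <- match(bmat[err], BASES) - 1L
      bmat[err] <- BASES[((code + shift) %% 4L) + 1L]
    }
  }
  list(seq = do.call(paste0, as.data.frame(bmat, stringsAsFactors = FALSE)),
       qual = .phred_string(qmat))
}

#' Simulate paired-end reads for one sample
#'
#' Fragments are drawn uniformly and independently within each (haplotype
#' copy x region segment) at a Poisson rate giving the expected per-copy
#' depth, so fragments never straddle a region-class boundary (the regions
#' are simulated as separate templates, each with its own ploidy-determined
#' coverage). Read bases are copied from the haplotype (golden SNPs applied)
#' and then flipped to a uniformly chosen different base with a probability
#' derived from the base quality; the second mate is the reverse complement
#' of the fragment end. True origins are retained as hidden truth metadata.
#'
#' @param sample A `sample_truth` from [simulate_cohort()].
#' @param refpair The matching [simulate_reference_pair()] result.
#' @param arch The matching [genome_architecture()].
#' @param policy A [coverage_policy()].
#' @param params A [read_params()].
#' @param seed Integer seed.
#' @return A `read_set`: data.frame with columns `read_id`, `mate`, `seq`,
#'   `qual`, and the truth fields `chrom`, `hap`, `start0` (0-based leftmost
#'   aligned reference position), `strand`.
#' @export
simulate_reads <- function(sample, refpair, arch,
                           policy = coverage_policy(),
                           params = read_params(), seed = 1L) {
  set.seed(as.integer(seed))
  rl <- params$read_length
  segs <- .haplotype_segments(arch, sample$karyotype)
  out <- list()
  for (h in seq_along(segs)) {
    sg <- segs[[h]]
    for (i in seq_len(nrow(sg))) {
      L <- sg$end[i] - sg$start[i]
      if (L < rl) {
        warning(sprintf("segment %s:[%d,%d) shorter than a read; skipped",
                        sg$chrom[i], sg$start[i], sg$end[i]))
        next
      }
      chars <- strsplit(substr(refpair$sequences[[sg$src[i]]],
                               sg$start[i] + 1L, sg$end[i]), "")[[1]]
      chars <- .apply_snps(chars, sg$chrom[i], sg$start[i], sample$snps, h)
      n_pairs <- stats::rpois(1L, policy$depth_per_copy * L / (2 * rl))
      if (n_pairs == 0L) next
      flen <- pmin(pmax(round(stats::rnorm(n_pairs, params$frag_mean,
                                           params$frag_sd)), rl), L)
      fstart <- floor(stats::runif(n_pairs, 0, L - flen + 1))
      idx1 <- outer(fstart, seq_len(rl), `+`)        # 1-based into chars
      b1 <- matrix(chars[idx1], n_pairs, rl)
      idx2 <- outer(fstart + flen, seq_len(rl), `-`) + 1L
      b2 <- matrix(COMPLEMENT[chars[idx2]], n_pairs, rl)
      r1 <- .finish_reads(b1, params)
      r2 <- .finish_reads(b2, params)
      ids <- sprintf("%s_h%d_%s%d_%d", sample$sample_id, h,
                     tolower(sg$class[i]), i, seq_len(n_pairs))
      out[[length(out) + 1L]] <- data.frame(
        read_id = rep(ids, 2L),
        mate = rep(c(1L, 2L), each = n_pairs),
        seq = c(r1$seq, r2$seq),
        qual = c(r1$qual, r2$qual),
        chrom = sg$chrom[i],
        hap = h,
        start0 = c(sg$start[i] + fstart,
                   sg$start[i] + fstart + flen - rl),
        strand = rep(c("+", "-"), each = n_pairs))
    }
  }
  reads <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(0), mate = integer(0), seq = character(0),
               qual = character(0), chrom = character(0), hap = integer(0),
               start0 = integer(0), strand = character(0))
  rownames(reads) <- NULL
  class(reads) <- c("read_set", "data.frame")
  reads
}

#' Read-trimming configuration
#'
#' Defaults follow common quality-trimming practice for 150-bp reads:
#' end-trim below Q20 on both sides, discard reads shorter than 75 bp after
#' trimming, and discard reads whose mean Phred quality is below 20.
#'
#' @param trimq End-trim quality threshold.
#' @param minlen Minimum post-trim read length.
#' @param maq Minimum post-trim arithmetic mean Phred quality.
#' @return A list of class `trim_config`.
#' @export
trim_config <- function(trimq = 20L, minlen = 75L, maq = 20L) {
  stopifnot(trimq >= 0, minlen >= 0, maq >= 0)
  structure(list(trimq = as.integer(trimq), minlen = as.integer(minlen),
                 maq = maq), class = "trim_config")
}

#' Quality-trim a read set
#'
#' Removes maximal runs of bases with quality below `trimq` from both read
#' ends, then drops reads shorter than `minlen` or with mean quality below
#' `maq`. Mates are dropped jointly: if either mate of a pair fails, both are
#' removed, keeping downstream pairing simple. Trimming is idempotent. Truth
#' `start0` coordinates are adjusted for the trimmed prefix so depth oracles
#' keep working.
#'
#' @param reads A `read_set`.
#' @param cfg A [trim_config()].
#' @return List with `reads` (the surviving, trimmed `read_set`) and `log`
#'   (data.frame `read_id`, `mate`, `action` in `kept`, `trimmed`,
#'   `dropped_short`, `dropped_maq`, `dropped_mate`).
#' @export
trim_reads <- function(reads, cfg = trim_config()) {
  n <- nrow(reads)
  if (n == 0L) return(list(reads = reads, log = data.frame(
    read_id = character(0), mate = integer(0), action = character(0))))
  qint <- lapply(reads$qual, function(q) utf8ToInt(q) - 33L)
  left <- integer(n); right <- integer(n); newlen <- integer(n)
  meanq <- numeric(n)
  for (i in seq_len(n)) {
    q <- qint[[i]]
    keep <- which(q >= cfg$trimq)
    if (length(keep) == 0L) {
      left[i] <- length(q); newlen[i] <- 0L; meanq[i] <- 0
    } else {
      left[i] <- keep[1L] - 1L
      right[i] <- length(q) - keep[length(keep)]
      newlen[i] <- keep[length(keep)] - keep[1L] + 1L
      meanq[i] <- mean(q[keep[1L]:keep[length(keep)]])
    }
  }
  action <- rep("kept", n)
  action[left > 0L | right > 0L] <- "trimmed"
  action[newlen < cfg$minlen] <- "dropped_short"
  action[newlen >= cfg$minlen & meanq < cfg$maq] <- "dropped_maq"
  dropped <- action %in% c("dropped_short", "dropped_maq")
  # joint pair drop
  bad_ids <- unique(reads$read_id[dropped])
  mate_drop <- reads$read_id %in% bad_ids & !dropped
  action[mate_drop] <- "dropped_mate"
  log <- data.frame(read_id = reads$read_id, mate = reads$mate,
                    action = action)
  keep <- !(dropped | mate_drop)
  out <- reads[keep, , drop = FALSE]
  l <- left[keep]; r <- right[keep]; nl <- newlen[keep]
  out$seq <- substr(out$seq, l + 1L, l + nl)
  out$qual <- substr(out$qual, l + 1L, l + nl)
  out$start0 <- out$start0 + ifelse(out$strand == "+", l, r)
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  list(reads = out, log = log)
}

#' Write a read set as paired FASTQ
#'
#' @param reads A `read_set`.
#' @param path1,path2 Output FASTQ paths for mate 1 and mate 2.
#' @return Invisibly, `c(path1, path2)`.
#' @export
write_fastq <- function(reads, path1, path2) {
  for (m in 1:2) {
    sel <- reads$mate == m
    dss <- Biostrings::DNAStringSet(reads$seq[sel])
    names(dss) <- paste0(reads$read_id[sel], "/", m)
    Biostrings::writeXStringSet(dss, filepath = if (m == 1L) path1 else path2,
                                format = "fastq",
                                qualities = Biostrings::BStringSet(
                                  reads$qual[sel]))
  }
  invisible(c(path1, path2))
}

#' Realized depth over an interval from truth placements
#'
#' Computes mean coverage of `[start0, end0)` on `chrom` from the hidden
#' truth placements of a read set (no alignment involved).
#'
#' @param reads A `read_set`.
#' @param chrom Chromosome name.
#' @param start0,end0 0-based half-open interval.
#' @return Mean per-base depth over the interval.
#' @export
truth_depth <- function(reads, chrom, start0, end0) {
  r <- reads[reads$chrom == chrom, , drop = FALSE]
  if (!nrow(r)) return(0)
  len <- nchar(r$seq)
  s <- pmax(r$start0, start0)
  e <- pmin(r$start0 + len, end0)
  sum(pmax(e - s, 0)) / (end0 - start0)
}
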
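# shared fixtures and independent oracles

# small architecture used across tests: 60-kb sex chromosomes + 20-kb autosome
tiny_arch <- function(autosome = 20000L) {
  genome_architecture(x_length = 60000L, par1 = 4000L, xtr = 10000L,
                      amp = 3000L, par2 = 3000L, autosome_length = autosome)
}

# even smaller pair for mapper oracle tests (<= 50 kb total)
micro_arch <- function() {
  genome_architecture(x_length = 16000L, par1 = 2000L, xtr = 4000L,
                      amp = 1000L, par2 = 1000L, autosome_length = 0L)
}

# exhaustive-scan mapping oracle via Biostrings: every placement of the read
# (both strands) on every chromosome is scored by mismatch count (reference N
# mismatches everything); returns best set, second-best distance and the
# surrogate MAPQ under the same conventions as the mapper
oracle_map <- function(read, reference, max_mm = 25L) {
  if (grepl("N", read, fixed = TRUE))
    return(list(aligned = FALSE))
  hits <- list()
  L <- nchar(read)
  pats <- c(`+` = read,
            `-` = as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(read))))
  for (ch in names(reference)) {
    subj <- Biostrings::DNAString(reference[[ch]])
    if (length(subj) < L) next
    starts <- seq_len(length(subj) - L + 1L)
    for (st in names(pats)) {
      mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pats[[st]]),
                                        subj, starting.at = starts,
                                        with.indels = FALSE)
      keep <- which(mm <= max_mm)
      if (length(keep))
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = ch, start0 = keep - 1L, strand = st, nm = mm[keep])
    }
  }
  if (!length(hits)) return(list(aligned = FALSE))
  hits <- do.call(rbind, hits)
  best <- min(hits$nm)
  best_set <- hits[hits$nm == best, , drop = FALSE]
  n_best <- nrow(best_set)
  others <- hits$nm[hits$nm > best]
  mapq <- if (n_best >= 2L) 0L else if (length(others))
    min(60L, 6L * (min(others) - best) + 20L) else 60L
  list(aligned = TRUE, nm = best, n_best = n_best, mapq = mapq,
       best_set = best_set)
}

# independent genotype-posterior oracle: direct enumeration with per-read
# probability products (no log space), flat prior with `het_prior` on each
# variant genotype
oracle_genotype_posterior <- function(bases, quals, ref, alt, ploidy,
                                      het_prior = 1e-3, eps_floor = 1e-4) {
  e <- pmax(10^(-quals / 10), eps_floor)
  p_of <- function(allele) ifelse(bases == allele, 1 - e, e / 3)
  if (ploidy == 1L) {
    lik <- c(ref = prod(p_of(ref)), alt = prod(p_of(alt)))
    prior <- c(1 - het_prior, het_prior)
  } else {
    lik <- c(ref_ref = prod(p_of(ref)),
             ref_alt = prod((p_of(ref) + p_of(alt)) / 2),
             alt_alt = prod(p_of(alt)))
    prior <- c(1 - 2 * het_prior, het_prior, het_prior)
  }
  post <- lik * prior
  post / sum(post)
}

# synthetic single-position pileup rows for caller tests
make_column <- function(chrom, pos, bases, quals, sample,
                        mapq = 60L, strand = NULL, enddist = 40L) {
  n <- length(bases)
  if (is.null(strand)) strand <- rep(c("+", "-"), length.out = n)
  data.frame(chrom = chrom, pos = pos, base = bases,
             qual = rep_len(quals, n), mapq = rep_len(mapq, n),
             strand = rep_len(strand, n), enddist = rep_len(enddist, n),
             read_row = seq_len(n), sample = sample)
}

# minimal site_calls construction for filter tests
make_calls <- function(sites, gt = NULL, samples = "S1") {
  defaults <- list(QUAL = 100, AC = 1L, AN = 2L, DP = 20L, QD = 10,
                   MQ = 60, FS = 0, SOR = 0.7, MQRankSum = 0,
                   ReadPosRankSum = 0, FILTER = ".")
  for (nm in names(defaults))
    if (is.null(sites[[nm]])) sites[[nm]] <- defaults[[nm]]
  if (is.null(gt))
    gt <- matrix("0/1", nrow(sites), length(samples),
                 dimnames = list(NULL, samples))
  structure(list(sites = sites, gt = gt,
                 sample_dp = matrix(10L, nrow(sites), length(samples),
                                    dimnames = list(NULL, samples)),
                 sample_gq = matrix(99L, nrow(sites), length(samples),
                                    dimnames = list(NULL, samples)),
                 samples = samples, mode = "matched"),
            class = "site_calls")
}
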
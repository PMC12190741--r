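#' Ploidy at genomic positions for a karyotype
#'
#' Encodes the region-ploidy model: autosomes are diploid in everyone; the
#' PARs are diploid in everyone and anchored to X coordinates (Y PAR ploidy is
#' 0); X outside the PARs is diploid in XX and haploid in XY; Y outside the
#' PARs is haploid in XY and absent (0) in XX. The `"force_diploid"` override
#' maps every non-zero ploidy to 2, i.e. calling the sex chromosomes like
#' autosomes.
#'
#' @param arch A [genome_architecture()].
#' @param karyotype `"XX"` or `"XY"`.
#' @param chrom,pos Chromosome names and 1-based positions (vectorised).
#' @param mode `"matched"` (karyotype-aware) or `"force_diploid"`.
#' @return Integer vector of ploidies in `{0, 1, 2}`.
#' @export
ploidy_at <- function(arch, karyotype, chrom, pos,
                      mode = c("matched", "force_diploid")) {
  mode <- match.arg(mode)
  karyotype <- match.arg(karyotype, c("XX", "XY"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  cls <- region_class_at(arch, chrom, pos)
  par <- cls %in% c("PAR1", "PAR2")
  p <- integer(n)
  p[chrom == "A"] <- 2L
  p[chrom == "X" & par] <- 2L
  p[chrom == "X" & !par] <- if (karyotype == "XX") 2L else 1L
  p[chrom == "Y" & par] <- 0L
  p[chrom == "Y" & !par] <- if (karyotype == "XY") 1L else 0L
  if (mode == "force_diploid") p[p > 0L] <- 2L
  p
}

# eligible SNP intervals (0-based half-open) per haplotype copy of a sample.
# Each row: chrom used for truth coordinates, start, end, and the chromosome
# whose reference sequence the haplotype carries there (src).
.haplotype_intervals <- function(arch, karyotype) {
  xfull <- data.frame(chrom = "X", start = 0L,
                      end = arch$chrom_lengths[["X"]], src = "X")
  haps <- list()
  if (karyotype == "XX") {
    haps[[1]] <- xfull
    haps[[2]] <- xfull
  } else {
    haps[[1]] <- xfull
    xpar <- arch_regions(arch, chrom = "X", class = "PAR")
    ybody <- arch_regions(arch, chrom = "Y",
                          class = c("XTR", "AMP", "NONPAR"))
    h2 <- rbind(
      if (nrow(xpar)) data.frame(chrom = "X", start = xpar$start,
                                 end = xpar$end, src = "X"),
      if (nrow(ybody)) data.frame(chrom = "Y", start = ybody$start,
                                  end = ybody$end, src = "Y"))
    haps[[2]] <- h2
  }
  if ("A" %in% names(arch$chrom_lengths)) {
    afull <- data.frame(chrom = "A", start = 0L,
                        end = arch$chrom_lengths[["A"]], src = "A")
    haps[[1]] <- rbind(haps[[1]], afull)
    haps[[2]] <- rbind(haps[[2]], afull)
  }
  haps
}

.draw_hap_snps <- function(refpair, intervals, theta) {
  out <- vector("list", nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    L <- intervals$end[i] - intervals$start[i]
    n <- stats::rbinom(1L, L, theta)
    if (n == 0L) next
    off <- sort(sample.int(L, n))          # unique positions, no collisions
    pos <- intervals$start[i] + off        # 1-based within chromosome
    ref <- strsplit(substr(refpair$sequences[[intervals$src[i]]],
                           intervals$start[i] + 1L, intervals$end[i]),
                    "")[[1]][off]
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1))
    out[[i]] <- data.frame(chrom = intervals$chrom[i], pos = pos,
                           ref = ref, alt = alt)
  }
  do.call(rbind, out)
}

#' Simulate a cohort of XX/XY samples with golden SNP truth sets
#'
#' Per sample and haplotype copy, SNP positions are drawn as a Bernoulli
#' process at density `theta` over the bases that haplotype carries, with the
#' alternate allele uniform over the three non-reference bases. XX samples
#' carry two full X haplotypes; XY samples carry one X haplotype and one
#' "Y-complement" haplotype consisting of the X-anchored PARs plus the
#' non-PAR Y. PAR variants are therefore always recorded on X coordinates and
#' XX samples never carry Y-linked SNPs. If both haplotypes of a diploid
#' region hit the same position, the second draw adopts the first allele
#' (yielding a homozygous variant), keeping every site biallelic.
#'
#' @param arch A [genome_architecture()].
#' @param refpair A [simulate_reference_pair()] result.
#' @param n_xx,n_xy Number of XX and XY samples.
#' @param theta Per-base per-haplotype SNP density (default 0.001/bp,
#'   human-like heterozygosity scale).
#' @param seed Integer seed.
#' @return List of `sample_truth` objects: each a list with `sample_id`,
#'   `karyotype`, and `snps` (data.frame `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `hap`).
#' @export
simulate_cohort <- function(arch, refpair, n_xx = 0L, n_xy = 0L,
                            theta = 0.001, seed = 1L) {
  stopifnot(theta >= 0, n_xx >= 0L, n_xy >= 0L)
  set.seed(as.integer(seed))
  karyos <- c(rep("XX", n_xx), rep("XY", n_xy))
  ids <- c(sprintf("XX_%02d", seq_len(n_xx)), sprintf("XY_%02d", seq_len(n_xy)))
  out <- vector("list", length(karyos))
  for (i in seq_along(karyos)) {
    haps <- .haplotype_intervals(arch, karyos[i])
    snps <- vector("list", length(haps))
    for (h in seq_along(haps)) {
      s <- .draw_hap_snps(refpair, haps[[h]], theta)
      if (!is.null(s) && nrow(s)) {
        s$hap <- h
        snps[[h]] <- s
      }
    }
    snps <- do.call(rbind, snps)
    if (is.null(snps))
      snps <- data.frame(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         hap = integer(0))
    # same-position hits on the two haplotypes adopt the hap-1 allele
    if (nrow(snps)) {
      key <- paste(snps$chrom, snps$pos)
      dup <- duplicated(key)
      if (any(dup)) {
        first_alt <- snps$alt[match(key[dup], key)]
        snps$alt[dup] <- first_alt
      }
      snps <- snps[order(snps$chrom, snps$pos, snps$hap), , drop = FALSE]
      rownames(snps) <- NULL
    }
    out[[i]] <- structure(list(sample_id = ids[i], karyotype = karyos[i],
                               snps = snps),
                          class = "sample_truth")
  }
  out
}

#' @export
print.sample_truth <- function(x, ...) {
  cat(sprintf("Sample %s (%s): %d golden haplotype SNPs\n", x$sample_id,
              x$karyotype, nrow(x$snps)))
  invisible(x)
}

#' Collapse haplotype SNPs to golden variant sites
#'
#' Collapses the per-haplotype SNP list of a sample to per-site records with
#' a golden genotype, using the sample's region ploidy: diploid sites are
#' `0/1` (one haplotype) or `1/1` (both), haploid sites are `1`.
#'
#' @param sample A `sample_truth`.
#' @param arch The matching [genome_architecture()].
#' @return data.frame `chrom`, `pos`, `ref`, `alt`, `gt`, `ploidy`.
#' @export
golden_sites <- function(sample, arch) {
  s <- sample$snps
  if (!nrow(s))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gt = character(0), ploidy = integer(0)))
  key <- paste(s$chrom, s$pos)
  nhap <- as.integer(table(key)[key])
  first <- !duplicated(key)
  out <- s[first, c("chrom", "pos", "ref", "alt")]
  out$ploidy <- ploidy_at(arch, sample$karyotype, out$chrom, out$pos)
  nh <- nhap[first]
  out$gt <- ifelse(out$ploidy == 1L, "1", ifelse(nh >= 2L, "1/1", "0/1"))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("chrom", "pos", "ref", "alt", "gt", "ploidy")]
}

#' Write a golden truth VCF for one sample
#'
#' VCF 4.2, 1-based, sorted, biallelic SNPs only; the GT ploidy of each record
#' follows the sample's region-ploidy map (`"1"` on the haploid non-PAR X/Y of
#' an XY sample, `"0/1"`/`"1/1"` on diploid regions).
#'
#' @param sample A `sample_truth`.
#' @param path Output path.
#' @param arch The matching [genome_architecture()].
#' @return Invisibly, `path`.
#' @export
write_golden_vcf <- function(sample, path, arch) {
  g <- golden_sites(sample, arch)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sexchrombench_golden",
           sprintf("##contig=<ID=%s,length=%d>", names(arch$chrom_lengths),
                   arch$chrom_lengths),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample$sample_id))
  body <- if (nrow(g))
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
            g$chrom, g$pos, g$ref, g$alt, g$gt)
  else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a golden truth VCF
#'
#' @param path VCF path (as written by [write_golden_vcf()]).
#' @return data.frame `chrom`, `pos`, `ref`, `alt`, `gt`.
#' @export
read_golden_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gt = character(0)))
  gt <- if (ncol(v@gt) >= 2L) as.character(v@gt[, 2L]) else NA_character_
  data.frame(chrom = as.character(fix[, "CHROM"]),
             pos = as.integer(fix[, "POS"]),
             ref = as.character(fix[, "REF"]),
             alt = as.character(fix[, "ALT"]),
             gt = gt)
}
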
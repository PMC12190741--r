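BASES <- c("A", "C", "G", "T")

.random_seq <- function(n) {
  if (n <= 0L) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# substitute exactly floor((1 - s) * L) uniformly chosen positions of `seq`
# with a uniformly chosen different base
.diverge_seq <- function(seq, s) {
  L <- nchar(seq)
  n_sub <- floor((1 - s) * L)
  if (n_sub == 0L) return(seq)
  pos <- sample.int(L, n_sub)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  old <- chars[pos]
  new <- vapply(old, function(b) sample(setdiff(BASES, b), 1L), character(1))
  chars[pos] <- new
  paste(chars, collapse = "")
}

#' Simulate a homologous X/Y reference pair
#'
#' Draws random sequence for the X chromosome (and the optional autosome) and
#' derives the Y chromosome from it region by region: PAR copies are taken
#' from X and substituted at exactly `floor((1 - s_par) * L)` positions
#' (identical when `s_par = 1`, the default for recombining PARs); the Y XTR
#' is a copy of the X XTR with exactly `floor((1 - s_xtr) * L)` uniformly
#' placed single-base substitutions; ampliconic and non-PAR sequence on Y is
#' drawn independently of X.
#'
#' @param arch A [genome_architecture()].
#' @param seed Integer seed; the pair is byte-identical for equal
#'   architecture and seed.
#' @return An object of class `reference_pair`: list with `sequences` (named
#'   character vector of A/C/G/T strings), `arch`, and `seed`.
#' @examples
#' arch <- genome_architecture(x_length = 5000, par1 = 500, xtr = 1000,
#'                             amp = 500, par2 = 300, autosome_length = 2000)
#' ref <- simulate_reference_pair(arch, seed = 1)
#' nchar(ref$sequences)
#' @export
simulate_reference_pair <- function(arch, seed = 1L) {
  validate_architecture(arch)
  set.seed(as.integer(seed))
  s <- arch$similarity
  seqs <- list()
  seqs$X <- .random_seq(arch$chrom_lengths[["X"]])
  # Y assembled region by region, homolog-aware
  yreg <- arch_regions(arch, chrom = "Y")
  yreg <- yreg[order(yreg$start), , drop = FALSE]
  parts <- character(nrow(yreg))
  for (i in seq_len(nrow(yreg))) {
    cls <- yreg$class[i]
    L <- yreg$end[i] - yreg$start[i]
    if (cls %in% c("PAR1", "PAR2", "XTR")) {
      xr <- arch_regions(arch, chrom = "X", class = cls)
      xcopy <- substr(seqs$X, xr$start[1] + 1L, xr$end[1])
      sim <- if (cls == "XTR") s[["s_xtr"]] else s[["s_par"]]
      parts[i] <- .diverge_seq(xcopy, sim)
    } else {
      parts[i] <- .random_seq(L)
    }
  }
  seqs$Y <- paste(parts, collapse = "")
  if ("A" %in% names(arch$chrom_lengths))
    seqs$A <- .random_seq(arch$chrom_lengths[["A"]])
  structure(list(sequences = unlist(seqs), arch = arch,
                 seed = as.integer(seed)),
            class = "reference_pair")
}

#' @export
print.reference_pair <- function(x, ...) {
  cat("Reference pair (seed ", x$seed, "):\n", sep = "")
  for (ch in names(x$sequences))
    cat(sprintf("  %s: %d bp\n", ch, nchar(x$sequences[[ch]])))
  invisible(x)
}

#' Write reference sequences to FASTA
#'
#' @param sequences A named character vector of sequences, or a
#'   `reference_pair` (its `sequences` element is used).
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_reference_fasta <- function(sequences, path) {
  if (inherits(sequences, "reference_pair")) sequences <- sequences$sequences
  dss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}

#' Read reference sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  out <- as.character(dss)
  names(out) <- sub("\\s.*$", "", names(dss))
  out
}

#' Hamming distance between two equal-length sequences
#'
#' @param a,b Character scalars of equal length.
#' @return Integer count of differing positions.
#' @export
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
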
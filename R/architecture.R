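#' Define a toy X/Y genome architecture
#'
#' Lays out a pair of sex chromosomes (plus an optional autosome) as a tiling
#' of named region classes: the two pseudoautosomal regions (`PAR1`, `PAR2`) at
#' the chromosome ends, the X-transposed region (`XTR`), an ampliconic region
#' (`AMP`), and the remaining unique sequence (`NONPAR`). Homologous classes
#' have equal length on X and Y, mirroring the human arrangement at toy scale.
#'
#' Coordinates are 0-based half-open (BED convention) throughout the package;
#' only VCF output is 1-based.
#'
#' @param x_length Total X chromosome length in bp.
#' @param par1,xtr,amp,par2 Lengths (bp) of the PAR1, XTR, ampliconic and PAR2
#'   classes on each sex chromosome. Any of them may be 0 (the class is then
#'   absent). The remainder of the chromosome is `NONPAR`.
#' @param y_length Total Y length; defaults to `x_length` so that homologous
#'   classes tile both chromosomes identically.
#' @param autosome_length Length of the optional diploid autosome `"A"` used as
#'   the autosomal baseline; 0 omits it.
#' @param s_par Fraction of identical bases between the X and Y PAR copies
#'   (1 = recombining, identical PARs; the default).
#' @param s_xtr Fraction of identical bases between the X and Y XTR copies.
#'   Default 0.9878, the X-Y sequence identity reported for the human XTR.
#' @param regions Optionally, a full region table (data.frame with columns
#'   `chrom`, `start`, `end`, `class`) overriding the length-based layout.
#' @param chrom_lengths Named lengths, required when `regions` is supplied.
#'
#' @return An object of class `genome_architecture`: a list with
#'   `chrom_lengths` (named integer), `regions` (data.frame of 0-based
#'   half-open intervals) and `similarity` (named numeric `s_par`, `s_xtr`).
#'
#' @details The X layout is `PAR1 | XTR | AMP | NONPAR | PAR2`; Y mirrors it.
#'   `NONPAR` on the autosome simply means unique diploid sequence. Validation
#'   enforces: non-overlapping regions tiling `[0, length)` on every
#'   chromosome, PAR1 at the start and PAR2 at the end of both sex
#'   chromosomes, equal class lengths on X and Y, and similarities in `[0, 1]`.
#'
#' @examples
#' arch <- genome_architecture(x_length = 200000, par1 = 10000, xtr = 30000,
#'                             amp = 10000, par2 = 5000)
#' arch$regions
#' @export
genome_architecture <- function(x_length = 200000L, par1 = 10000L,
                                xtr = 30000L, amp = 10000L, par2 = 5000L,
                                y_length = x_length, autosome_length = 100000L,
                                s_par = 1.0, s_xtr = 0.9878,
                                regions = NULL, chrom_lengths = NULL) {
  if (is.null(regions)) {
    x_length <- as.integer(x_length); y_length <- as.integer(y_length)
    lens <- c(PAR1 = as.integer(par1), XTR = as.integer(xtr),
              AMP = as.integer(amp), PAR2 = as.integer(par2))
    if (any(lens < 0L)) stop("region lengths must be non-negative")
    if (sum(lens) > min(x_length, y_length))
      stop("PAR1 + XTR + AMP + PAR2 exceed chromosome length")
    chrom_lengths <- c(X = x_length, Y = y_length)
    if (autosome_length > 0L)
      chrom_lengths <- c(chrom_lengths, A = as.integer(autosome_length))
    regions <- rbind(.layout_chrom("X", x_length, lens),
                     .layout_chrom("Y", y_length, lens))
    if (autosome_length > 0L)
      regions <- rbind(regions, data.frame(chrom = "A", start = 0L,
                                           end = as.integer(autosome_length),
                                           class = "NONPAR"))
  } else {
    if (is.null(chrom_lengths))
      stop("chrom_lengths is required when regions are supplied directly")
    chrom_lengths <- vapply(chrom_lengths, as.integer, integer(1))
  }
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  regions$chrom <- as.character(regions$chrom)
  regions$class <- as.character(regions$class)
  rownames(regions) <- NULL
  arch <- structure(list(chrom_lengths = chrom_lengths,
                         regions = regions,
                         similarity = c(s_par = s_par, s_xtr = s_xtr)),
                    class = "genome_architecture")
  validate_architecture(arch)
  arch
}

# canonical per-chromosome layout: PAR1 | XTR | AMP | NONPAR | PAR2
.layout_chrom <- function(chrom, len, lens) {
  cuts <- c(PAR1 = lens[["PAR1"]], XTR = lens[["XTR"]], AMP = lens[["AMP"]])
  nonpar <- len - sum(cuts) - lens[["PAR2"]]
  widths <- c(cuts, NONPAR = nonpar, PAR2 = lens[["PAR2"]])
  widths <- widths[widths > 0L]
  ends <- cumsum(widths)
  data.frame(chrom = chrom, start = as.integer(c(0L, ends[-length(ends)])),
             end = as.integer(ends), class = names(widths))
}

REGION_CLASSES <- c("PAR1", "PAR2", "XTR", "AMP", "NONPAR")

#' Validate a genome architecture
#'
#' Checks every structural invariant of a [genome_architecture()] object and
#' stops with a message naming the offending interval on violation.
#'
#' @param arch A `genome_architecture`.
#' @return `arch`, invisibly, if valid.
#' @export
validate_architecture <- function(arch) {
  stopifnot(inherits(arch, "genome_architecture"))
  reg <- arch$regions
  if (!all(reg$class %in% REGION_CLASSES))
    stop("unknown region class: ",
         paste(setdiff(reg$class, REGION_CLASSES), collapse = ", "))
  s <- arch$similarity
  if (any(s < 0 | s > 1)) stop("similarities must lie in [0, 1]")
  for (chrom in names(arch$chrom_lengths)) {
    len <- arch$chrom_lengths[[chrom]]
    r <- reg[reg$chrom == chrom, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) == 0L) stop("chromosome ", chrom, " has no regions")
    bad <- which(r$end <= r$start | r$start < 0L | r$end > len)
    if (length(bad))
      stop(sprintf("invalid interval %s:[%d,%d) (%s)", chrom,
                   r$start[bad[1]], r$end[bad[1]], r$class[bad[1]]))
    if (r$start[1] != 0L || r$end[nrow(r)] != len ||
        (nrow(r) > 1L && any(r$start[-1] != r$end[-nrow(r)])))
      stop("regions on ", chrom, " do not tile [0, ", len, ") without gaps ",
           "or overlaps")
    if (chrom %in% c("X", "Y")) {
      if ("PAR1" %in% r$class && r$class[1] != "PAR1")
        stop("PAR1 must sit at the start of ", chrom)
      if ("PAR2" %in% r$class && r$class[nrow(r)] != "PAR2")
        stop("PAR2 must sit at the end of ", chrom)
    }
  }
  # homologous classes equal length on X and Y
  for (cls in c("PAR1", "PAR2", "XTR", "AMP")) {
    lx <- .class_length(arch, "X", cls)
    ly <- .class_length(arch, "Y", cls)
    if (lx != ly)
      stop("class ", cls, " has unequal length on X (", lx, ") and Y (",
           ly, ")")
  }
  invisible(arch)
}

.class_length <- function(arch, chrom, cls) {
  r <- arch$regions
  sum(with(r, end - start)[r$chrom == chrom & r$class == cls])
}

#' Regions of one chromosome or class
#'
#' @param arch A `genome_architecture`.
#' @param chrom Optional chromosome name filter.
#' @param class Optional region class filter (e.g. `"XTR"`, or `"PAR"` for
#'   PAR1 and PAR2 together).
#' @return A data.frame of 0-based half-open intervals.
#' @export
arch_regions <- function(arch, chrom = NULL, class = NULL) {
  r <- arch$regions
  if (!is.null(chrom)) r <- r[r$chrom %in% chrom, , drop = FALSE]
  if (!is.null(class)) {
    if (identical(class, "PAR")) class <- c("PAR1", "PAR2")
    r <- r[r$class %in% class, , drop = FALSE]
  }
  rownames(r) <- NULL
  r
}

#' Region class at given positions
#'
#' @param arch A `genome_architecture`.
#' @param chrom Chromosome name (scalar or vector recycled against `pos`).
#' @param pos 1-based positions.
#' @return Character vector of region classes.
#' @export
region_class_at <- function(arch, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos0 <- rep_len(as.integer(pos), n) - 1L
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    r <- arch$regions[arch$regions$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    idx <- findInterval(pos0[sel], r$start[order(r$start)])
    ro <- r[order(r$start), , drop = FALSE]
    ok <- idx >= 1L & pos0[sel] < ro$end[pmax(idx, 1L)]
    out[sel][ok] <- ro$class[idx[ok]]
  }
  out
}

#' Write region BED files
#'
#' Emits one 3-column BED per region class plus a combined 4-column BED
#' (`chrom start end class`), 0-based half-open.
#'
#' @param arch A `genome_architecture`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (named by class, plus `"combined"`).
#' @export
write_region_beds <- function(arch, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (cls in unique(arch$regions$class)) {
    r <- arch_regions(arch, class = cls)
    p <- file.path(dir, paste0(tolower(cls), ".bed"))
    utils::write.table(r[, c("chrom", "start", "end")], p, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths[cls] <- p
  }
  p <- file.path(dir, "regions.bed")
  utils::write.table(arch$regions[, c("chrom", "start", "end", "class")], p,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  paths["combined"] <- p
  invisible(paths)
}

#' @export
print.genome_architecture <- function(x, ...) {
  cat("Genome architecture:",
      paste(sprintf("%s (%d bp)", names(x$chrom_lengths), x$chrom_lengths),
            collapse = ", "), "\n")
  cat(sprintf("  X-Y identity: PAR %.4f, XTR %.4f\n",
              x$similarity[["s_par"]], x$similarity[["s_xtr"]]))
  print(x$regions)
  invisible(x)
}
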
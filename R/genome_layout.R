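#' Genome layout: chromosomes and fixed-width bins
#'
#' A genome layout fixes the chromosome names, their lengths, and the bin size
#' used for all binned-signal arithmetic. Coverage analysis of mitotic
#' nascent-DNA sequencing operates on fixed-width bins (10 kb by default);
#' every track in the package carries one of these layouts. Bins are anchored
#' at coordinate 0 of each chromosome; the final bin may be partial and is
#' kept.
#'
#' @param chrom_names character vector of unique chromosome identifiers.
#' @param chrom_lengths integer-ish vector of chromosome lengths in base
#'   pairs, parallel to `chrom_names`.
#' @param bin_size bin width in base pairs (default 10,000).
#' @return An object of class `genome_layout`: a list with elements
#'   `chrom_names`, `chrom_lengths` (named), `bin_size` and `n_bins` (named;
#'   `ceiling(length / bin_size)` per chromosome).
#' @examples
#' layout <- genome_layout(c("chr1", "chr2"), c(3e7, 2e7))
#' layout$n_bins
#' @export
genome_layout <- function(chrom_names, chrom_lengths, bin_size = 10000) {
  chrom_names <- as.character(chrom_names)
  if (length(chrom_names) == 0L) {
    stop("layout needs at least one chromosome")
  }
  if (anyDuplicated(chrom_names)) {
    stop("chromosome names must be unique")
  }
  if (length(chrom_lengths) != length(chrom_names)) {
    stop("chrom_names and chrom_lengths must have the same length")
  }
  chrom_lengths <- as.numeric(chrom_lengths)
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("chromosome lengths must be positive")
  }
  bin_size <- as.numeric(bin_size)
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size <= 0) {
    stop("bin_size must be a single positive number")
  }
  names(chrom_lengths) <- chrom_names
  n_bins <- ceiling(chrom_lengths / bin_size)
  structure(
    list(
      chrom_names = chrom_names,
      chrom_lengths = chrom_lengths,
      bin_size = bin_size,
      n_bins = n_bins
    ),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf(
    "genome_layout: %d chromosome(s), %.0f bp total, bin size %.0f bp (%d bins)\n",
    length(x$chrom_names), sum(x$chrom_lengths), x$bin_size, sum(x$n_bins)
  ))
  invisible(x)
}

#' Read / write a genome layout table
#'
#' The layout is stored as a tab-separated table with a header line and
#' columns `chrom`, `length`, `bin_size`.
#'
#' @param path file path.
#' @return `read_genome_layout()` returns a [genome_layout()];
#'   `write_genome_layout()` returns `path` invisibly.
#' @export
read_genome_layout <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "length", "bin_size")
  if (!all(need %in% names(tab))) {
    stop("genome layout table must have columns: ", paste(need, collapse = ", "))
  }
  genome_layout(tab$chrom, tab$length, bin_size = tab$bin_size[1])
}

#' @param layout a [genome_layout()].
#' @rdname read_genome_layout
#' @export
write_genome_layout <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  tab <- data.frame(
    chrom = layout$chrom_names,
    length = format_bp(layout$chrom_lengths),
    bin_size = format_bp(layout$bin_size)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 0-based bin index of a base-pair position
bin_index <- function(pos, bin_size) floor(pos / bin_size)

# midpoint (bp) of a 0-based bin, clipping the trailing partial bin
bin_midpoint <- function(bin, layout, chrom) {
  bs <- layout$bin_size
  end <- pmin((bin + 1) * bs, layout$chrom_lengths[[chrom]])
  floor((bin * bs + end) / 2)
}

# integers printed without scientific notation
format_bp <- function(x) {
  format(x, scientific = FALSE, trim = TRUE)
}
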
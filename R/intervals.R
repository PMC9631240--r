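#' Read genomic intervals from a BED3/BED6 file
#'
#' Intervals are the generic carrier for genes, replication origins, R-loop
#' peaks, G-quadruplex positions, replication-timing domains and control
#' regions. Coordinates are 0-based half-open throughout (BED convention).
#' Blank lines and lines starting with `#`, `track` or `browser` are skipped.
#'
#' @param path path to a tab-separated BED file with at least 3 columns
#'   (chrom, start, end) and optionally name, score, strand.
#' @param kind free-text tag recording what the intervals are (e.g. `"gene"`,
#'   `"origin"`, `"rloop"`, `"g4"`, `"rt_domain"`); stored as an attribute.
#' @param layout optional [genome_layout()]; when supplied, chromosome names
#'   are validated (with `chr`-prefix aliasing, so `1` matches `chr1`) and
#'   coordinates are bounds-checked.
#' @return A data frame with columns `chrom`, `start`, `end`, `name`, `score`
#'   (numeric, `NA` where absent) and `strand` (`+`, `-` or `.`), sorted by
#'   chromosome then start, with attribute `kind`.
#' @export
read_intervals <- function(path, kind = "generic", layout = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) &
    !grepl("^#", lines) &
    !grepl("^(track|browser)\\b", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(empty_intervals(kind))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- lineno[which(nf < 3L)[1]]
    stop(sprintf("parse error at line %d: fewer than 3 tab-separated fields", bad))
  }
  get_col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  chrom <- get_col(1)
  start <- suppressWarnings(as.numeric(get_col(2)))
  end <- suppressWarnings(as.numeric(get_col(3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- lineno[which(is.na(start) | is.na(end))[1]]
    stop(sprintf("parse error at line %d: non-numeric coordinates", bad))
  }
  if (any(start < 0)) {
    bad <- lineno[which(start < 0)[1]]
    stop(sprintf("validation error at line %d: start < 0", bad))
  }
  if (any(end <= start)) {
    bad <- lineno[which(end <= start)[1]]
    stop(sprintf("validation error at line %d: end <= start", bad))
  }
  name <- get_col(4)
  name[is.na(name) | name == ""] <- "."
  score_chr <- get_col(5)
  score <- suppressWarnings(as.numeric(score_chr))
  strand <- get_col(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  df <- data.frame(
    chrom = chrom, start = start, end = end,
    name = name, score = score, strand = strand,
    stringsAsFactors = FALSE
  )
  if (!is.null(layout)) {
    df$chrom <- normalize_chroms(df$chrom, layout)
    len <- layout$chrom_lengths[df$chrom]
    if (any(df$end > len)) {
      bad <- lineno[which(df$end > len)[1]]
      stop(sprintf("validation error at line %d: interval exceeds chromosome length", bad))
    }
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "kind") <- kind
  df
}

empty_intervals <- function(kind = "generic") {
  df <- data.frame(
    chrom = character(0), start = numeric(0), end = numeric(0),
    name = character(0), score = numeric(0), strand = character(0),
    stringsAsFactors = FALSE
  )
  attr(df, "kind") <- kind
  df
}

# Map bare chromosome names onto the layout's dialect ("1" -> "chr1" and
# vice versa). Mixed public tracks use both conventions.
normalize_chroms <- function(chrom, layout) {
  known <- chrom %in% layout$chrom_names
  if (all(known)) return(chrom)
  fixed <- chrom
  add <- paste0("chr", chrom)
  strip <- sub("^chr", "", chrom)
  fixed[!known & add %in% layout$chrom_names] <- add[!known & add %in% layout$chrom_names]
  known2 <- fixed %in% layout$chrom_names
  fixed[!known2 & strip %in% layout$chrom_names] <- strip[!known2 & strip %in% layout$chrom_names]
  if (any(!fixed %in% layout$chrom_names)) {
    stop("unknown chromosome: ", fixed[which(!fixed %in% layout$chrom_names)[1]])
  }
  fixed
}

#' Write genomic intervals as BED6
#'
#' Inverse of [read_intervals()]: `read_intervals(write_intervals(x, f))`
#' reproduces `x` field for field. Missing scores are written as `.`.
#'
#' @param x an interval data frame as returned by [read_intervals()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  validate_intervals(x)
  if (nrow(x) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  score <- ifelse(is.na(x$score), ".", format(x$score, scientific = FALSE, trim = TRUE))
  lines <- paste(
    x$chrom, format_bp(x$start), format_bp(x$end),
    x$name, score, x$strand,
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

validate_intervals <- function(x) {
  need <- c("chrom", "start", "end")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("intervals must be a data frame with columns chrom, start, end")
  }
  if (nrow(x) > 0L) {
    if (any(x$start < 0)) stop("interval start < 0")
    if (any(x$end <= x$start)) stop("interval end <= start")
  }
  if (is.null(x$name)) x$name <- rep(".", nrow(x))
  if (is.null(x$score)) x$score <- rep(NA_real_, nrow(x))
  if (is.null(x$strand)) x$strand <- rep(".", nrow(x))
  invisible(x)
}

# GRanges view of a 0-based half-open interval data frame (1-based closed
# internally, the IRanges convention)
gr_intervals <- function(x) {
  if (nrow(x) == 0L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

# GRanges of half-open windows [center - w, center + w)
gr_windows <- function(chrom, center, w) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(
      start = pmax(center - w, 0) + 1,
      end = pmax(center + w, 1)
    )
  )
}
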
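#' Binned genomic tracks
#'
#' A bin track holds one numeric value per fixed-width genomic bin, the unit
#' of all signal arithmetic in this package: raw nascent-DNA read counts,
#' sigma-normalized enrichment, replication fork directionality, or generic
#' signal. Values are stored per chromosome; `NA` marks missing bins (these
#' are flagged, never zero-filled).
#'
#' @param layout a [genome_layout()].
#' @param values named list of per-chromosome numeric vectors, one entry per
#'   bin, in layout order.
#' @param kind one of `"raw_count"`, `"sigma"`, `"rfd"`, `"signal"`.
#' @return An object of class `bin_track`.
#' @export
bin_track <- function(layout, values, kind = "signal") {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.list(values) || !identical(sort(names(values)), sort(layout$chrom_names))) {
    stop("values must be a named list with one vector per layout chromosome")
  }
  values <- values[layout$chrom_names]
  for (chrom in layout$chrom_names) {
    if (length(values[[chrom]]) != layout$n_bins[[chrom]]) {
      stop(sprintf(
        "values for %s have length %d, layout expects %d bins",
        chrom, length(values[[chrom]]), layout$n_bins[[chrom]]
      ))
    }
  }
  if (kind == "raw_count") {
    v <- unlist(values, use.names = FALSE)
    if (any(v < 0, na.rm = TRUE)) stop("raw counts must be non-negative")
  }
  if (kind == "rfd") {
    v <- unlist(values, use.names = FALSE)
    if (any(abs(v) > 1 + 1e-9, na.rm = TRUE)) stop("RFD values must lie in [-1, 1]")
  }
  structure(list(layout = layout, values = values, kind = kind), class = "bin_track")
}

#' @export
print.bin_track <- function(x, ...) {
  v <- unlist(x$values, use.names = FALSE)
  cat(sprintf(
    "bin_track [%s]: %d bins across %d chromosome(s), bin size %.0f bp, %d NA\n",
    x$kind, length(v), length(x$values), x$layout$bin_size, sum(is.na(v))
  ))
  invisible(x)
}

#' Bin read positions or a bedGraph file into a raw-count track
#'
#' A read is represented by a single genomic position (its alignment start);
#' position `p` increments bin `floor(p / bin_size)`. A bedGraph record's
#' value is treated as a mass spread uniformly over the record, so each
#' overlapped bin receives `value * overlap_length / record_length`.
#'
#' @param source either a data frame with columns `chrom` and `pos`
#'   (0-based read positions), or the path to a bedGraph file.
#' @param layout a [genome_layout()].
#' @return A `bin_track` of kind `"raw_count"`.
#' @export
load_bin_track <- function(source, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  values <- lapply(layout$chrom_names, function(chrom) {
    numeric(layout$n_bins[[chrom]])
  })
  names(values) <- layout$chrom_names
  bs <- layout$bin_size
  if (is.character(source)) {
    bg <- read_bedgraph_records(source)
    bg$chrom <- normalize_chroms(bg$chrom, layout)
    len <- layout$chrom_lengths[bg$chrom]
    if (any(bg$end > len)) stop("bedGraph record exceeds chromosome length")
    for (i in seq_len(nrow(bg))) {
      chrom <- bg$chrom[i]
      s <- bg$start[i]; e <- bg$end[i]; val <- bg$value[i]
      b0 <- bin_index(s, bs)
      b1 <- bin_index(e - 1, bs)
      for (b in b0:b1) {
        ov <- min(e, (b + 1) * bs) - max(s, b * bs)
        values[[chrom]][b + 1] <- values[[chrom]][b + 1] + val * ov / (e - s)
      }
    }
  } else if (is.data.frame(source)) {
    if (!all(c("chrom", "pos") %in% names(source))) {
      stop("read positions need columns chrom and pos")
    }
    chrom <- normalize_chroms(as.character(source$chrom), layout)
    pos <- as.numeric(source$pos)
    if (any(pos < 0)) stop("position out of bounds: negative position")
    len <- layout$chrom_lengths[chrom]
    if (any(pos >= len)) {
      stop("position out of bounds: position beyond chromosome length")
    }
    b <- bin_index(pos, bs)
    for (cn in unique(chrom)) {
      tb <- tabulate(b[chrom == cn] + 1, nbins = layout$n_bins[[cn]])
      values[[cn]] <- values[[cn]] + tb
    }
  } else {
    stop("source must be a data frame of positions or a bedGraph path")
  }
  bin_track(layout, values, kind = "raw_count")
}

read_bedgraph_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !grepl("^#", lines) &
    !grepl("^(track|browser)\\b", lines)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(
      chrom = character(0), start = numeric(0),
      end = numeric(0), value = numeric(0)
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    stop("bedGraph records need 4 tab-separated fields")
  }
  df <- data.frame(
    chrom = vapply(fields, `[`, character(1), 1),
    start = as.numeric(vapply(fields, `[`, character(1), 2)),
    end = as.numeric(vapply(fields, `[`, character(1), 3)),
    value = as.numeric(vapply(fields, `[`, character(1), 4)),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$value)) {
    stop("bedGraph parse error: non-numeric fields")
  }
  if (any(df$end <= df$start)) stop("bedGraph record with end <= start")
  df
}

#' Write / read a bin track as bedGraph
#'
#' One record per non-missing bin. `read_track()` expects bin-aligned records
#' (as written by `write_track()`); bins without a record are `NA`.
#'
#' @param track a `bin_track`.
#' @param path bedGraph file path.
#' @param layout a [genome_layout()] matching the file.
#' @param kind track kind to stamp on the result.
#' @return `write_track()` returns `path` invisibly; `read_track()` a
#'   `bin_track`.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "bin_track"))
  layout <- track$layout
  bs <- layout$bin_size
  con <- file(path, open = "w")
  on.exit(close(con))
  for (chrom in layout$chrom_names) {
    v <- track$values[[chrom]]
    ok <- which(!is.na(v))
    if (length(ok) == 0L) next
    b <- ok - 1
    lines <- paste(
      chrom,
      format_bp(b * bs),
      format_bp(pmin((b + 1) * bs, layout$chrom_lengths[[chrom]])),
      format(v[ok], scientific = FALSE, trim = TRUE, digits = 10),
      sep = "\t"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path, layout, kind = "signal") {
  bg <- read_bedgraph_records(path)
  bg$chrom <- normalize_chroms(bg$chrom, layout)
  bs <- layout$bin_size
  values <- lapply(layout$chrom_names, function(chrom) {
    rep(NA_real_, layout$n_bins[[chrom]])
  })
  names(values) <- layout$chrom_names
  b <- bin_index(bg$start, bs)
  aligned <- bg$start == b * bs &
    bg$end == pmin((b + 1) * bs, layout$chrom_lengths[bg$chrom])
  if (any(!aligned)) {
    stop("record not aligned to a single bin; use load_bin_track() for arbitrary bedGraph")
  }
  for (i in seq_len(nrow(bg))) {
    values[[bg$chrom[i]]][b[i] + 1] <- bg$value[i]
  }
  bin_track(layout, values, kind = kind)
}

# sum of track values over bins overlapping [center - w, center + w)
window_bin_sum <- function(track, chrom, center, w) {
  bs <- track$layout$bin_size
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  b0 <- max(bin_index(center - w, bs), 0)
  b1 <- min(bin_index(center + w - 1, bs), length(v) - 1)
  if (b1 < b0) return(0)
  sum(v[(b0 + 1):(b1 + 1)], na.rm = TRUE)
}

# mean of non-missing track values over bins overlapping [center - w, center + w)
window_bin_mean <- function(track, chrom, center, w) {
  bs <- track$layout$bin_size
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  b0 <- max(bin_index(center - w, bs), 0)
  b1 <- min(bin_index(center + w - 1, bs), length(v) - 1)
  if (b1 < b0) return(NA_real_)
  x <- v[(b0 + 1):(b1 + 1)]
  if (all(is.na(x))) return(NA_real_)
  mean(x, na.rm = TRUE)
}
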
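#' Call MiDAS sites from a sigma track by local-maxima search
#'
#' Contiguous runs of bins with `sigma >= threshold` and length `>= min_run`
#' become candidate regions; candidate regions separated by at most
#' `merge_gap` sub-threshold bins are merged. Within each region, bins whose
#' sigma exceeds the threshold and strictly exceeds both flanking values are
#' peak bins (a plateau of equal values counts once, at its leftmost bin;
#' chromosome ends count as minus infinity). A site with two or more peak
#' bins is classified `"multiple"`, mirroring large MiDAS regions with
#' nascent-DNA incorporation at both edges; otherwise `"single"`.
#'
#' The site anchor — the reference point for all downstream window analyses —
#' is the base-pair midpoint of the maximal-sigma peak bin (leftmost on ties).
#'
#' @param sigma a `bin_track` of kind `"sigma"` (see [compute_sigma()]).
#' @param threshold calling threshold in sigma units (default 3.0).
#' @param min_run minimum run length in bins (default 2).
#' @param merge_gap maximum number of sub-threshold bins bridged when merging
#'   adjacent candidate regions (default 2).
#' @param condition free-text condition label stamped on every site
#'   (e.g. `"-BRCA2"`, `"+BRCA2+APH"`).
#' @return A data frame with one row per site: `site_id`, `chrom`, `start`,
#'   `end` (bin-aligned, 0-based half-open), `anchor` (bp), `max_sigma`,
#'   `n_peaks`, `peak_bins` (comma-separated 0-based bin indices), `shape`
#'   (`"single"`/`"multiple"`) and `condition`; sorted by chromosome then
#'   start.
#' @export
call_midas_sites <- function(sigma, threshold = 3.0, min_run = 2L,
                             merge_gap = 2L, condition = "") {
  stopifnot(inherits(sigma, "bin_track"))
  if (!is.finite(threshold) || threshold <= 0) stop("threshold must be > 0")
  if (min_run < 1L) stop("min_run must be >= 1")
  if (merge_gap < 0L) stop("merge_gap must be >= 0")
  if (sum(sigma$layout$n_bins) == 0L) stop("empty sigma track")
  layout <- sigma$layout
  bs <- layout$bin_size
  rows <- list()
  for (chrom in layout$chrom_names) {
    v <- sigma$values[[chrom]]
    regions <- find_regions(v, threshold, min_run, merge_gap)
    for (reg in regions) {
      peaks <- find_peak_bins(v, reg[1], reg[2], threshold)
      sig_at <- v[peaks + 1]
      best <- peaks[which.max(sig_at)]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom,
        start = reg[1] * bs,
        end = min((reg[2] + 1) * bs, layout$chrom_lengths[[chrom]]),
        anchor = bin_midpoint(best, layout, chrom),
        max_sigma = max(sig_at),
        n_peaks = length(peaks),
        peak_bins = paste(peaks, collapse = ","),
        shape = if (length(peaks) >= 2L) "multiple" else "single",
        condition = condition,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(
      site_id = character(0), chrom = character(0), start = numeric(0),
      end = numeric(0), anchor = numeric(0), max_sigma = numeric(0),
      n_peaks = integer(0), peak_bins = character(0), shape = character(0),
      condition = character(0), stringsAsFactors = FALSE
    )
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(match(out$chrom, layout$chrom_names), out$start)
  out <- out[ord, , drop = FALSE]
  out <- cbind(
    site_id = sprintf("site_%04d", seq_len(nrow(out))),
    out,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# candidate regions as list of c(first_bin, last_bin), 0-based
find_regions <- function(v, threshold, min_run, merge_gap) {
  above <- !is.na(v) & v >= threshold
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values & r$lengths >= min_run)
  if (length(cand) == 0L) return(list())
  regions <- list()
  cur <- c(starts[cand[1]] - 1, ends[cand[1]] - 1)
  for (i in cand[-1]) {
    s <- starts[i] - 1
    e <- ends[i] - 1
    if (s - cur[2] - 1 <= merge_gap) {
      cur[2] <- e
    } else {
      regions[[length(regions) + 1]] <- cur
      cur <- c(s, e)
    }
  }
  regions[[length(regions) + 1]] <- cur
  regions
}

# plateau-aware strict local maxima (above threshold) within region [s, e]
# (0-based bins); ties broken leftmost: each plateau contributes its first bin
find_peak_bins <- function(v, s, e, threshold) {
  n <- length(v)
  val <- function(i) {
    if (i < 0 || i >= n || is.na(v[i + 1])) -Inf else v[i + 1]
  }
  peaks <- integer(0)
  i <- s
  while (i <= e) {
    j <- i
    while (j < e && !is.na(v[j + 2]) && !is.na(v[i + 1]) && v[j + 2] == v[i + 1]) {
      j <- j + 1
    }
    vi <- val(i)
    if (is.finite(vi) && vi >= threshold && vi > val(i - 1) && vi > val(j + 1)) {
      peaks <- c(peaks, i)
    }
    i <- j + 1
  }
  if (length(peaks) == 0L) {
    # degenerate region (e.g. flat plateau flanked by equal values at the
    # merge boundary): fall back to the maximal above-threshold bin
    idx <- s:e
    ok <- idx[!is.na(v[idx + 1]) & v[idx + 1] >= threshold]
    if (length(ok) > 0L) peaks <- ok[which.max(v[ok + 1])]
  }
  peaks
}

#' Write called sites as an extended BED table
#'
#' Columns: chrom, start, end, site_id, max_sigma, strand (`.`), shape,
#' condition, anchor, peak_bins. Tab-separated, no header.
#'
#' @param sites a site table from [call_midas_sites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  lines <- paste(
    sites$chrom, format_bp(sites$start), format_bp(sites$end),
    sites$site_id, format(sites$max_sigma, scientific = FALSE, trim = TRUE),
    ".", sites$shape, sites$condition,
    format_bp(sites$anchor), sites$peak_bins,
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

# anchor positions for either a called-site table (anchor column) or a plain
# interval table (midpoint)
site_anchors <- function(x) {
  if ("anchor" %in% names(x)) {
    as.numeric(x$anchor)
  } else {
    floor((as.numeric(x$start) + as.numeric(x$end)) / 2)
  }
}
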
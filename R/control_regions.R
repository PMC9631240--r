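#' Sample constrained random control regions
#'
#' Draws sets of control regions matched to the genomic context of MiDAS
#' sites in BRCA2-deficient cells: each control region is a single genomic
#' bin whose center lies in an early-replicating domain, is at least
#' `exclusion_bins` bins away from every MiDAS peak bin, and has at least one
#' R-loop peak within +/- `window` of its center. Sampling is without
#' replacement within a set; each set is drawn with its own derived seed so
#' the whole draw is reproducible from `seed`.
#'
#' @param rt_domains replication-timing domain intervals (`name` = label).
#' @param rloop_peaks R-loop peak intervals.
#' @param midas_sites called site table (its `peak_bins` column, or anchors,
#'   defines the exclusion centers).
#' @param layout a [genome_layout()].
#' @param genes optional gene intervals; when given, each region is annotated
#'   with its +/- `window` gene count.
#' @param n regions per set (default 150).
#' @param n_sets number of sets (default 10).
#' @param exclusion_bins minimum bin distance from any MiDAS peak bin
#'   (default 50, i.e. 500 kb at 10-kb bins).
#' @param window half-width in bp of the R-loop / gene annotation window
#'   (default 50,000).
#' @param seed integer seed; set `s` uses `seed + s`.
#' @return A list of `n_sets` data frames (`chrom`, `start`, `end`, `center`,
#'   `bin`, `rloop_count`, and `gene_count` when `genes` is given), each with
#'   attributes `set_index` and `seed`.
#' @export
sample_control_regions <- function(rt_domains, rloop_peaks, midas_sites, layout,
                                   genes = NULL, n = 150, n_sets = 10,
                                   exclusion_bins = 50, window = 50000,
                                   seed = 1) {
  pool <- eligible_control_bins(
    rt_domains, rloop_peaks, midas_sites, layout,
    exclusion_bins = exclusion_bins, window = window
  )
  if (nrow(pool) < n) {
    stop(sprintf(
      "infeasible sampling: eligible pool has %d bins, need %d", nrow(pool), n
    ))
  }
  win <- gr_windows(pool$chrom, pool$center, window)
  pool$rloop_count <- GenomicRanges::countOverlaps(win, gr_intervals(rloop_peaks))
  if (!is.null(genes)) {
    pool$gene_count <- GenomicRanges::countOverlaps(win, gr_intervals(genes))
  }
  lapply(seq_len(n_sets), function(s) {
    set.seed(seed + s)
    idx <- sample.int(nrow(pool), n)
    out <- pool[sort(idx), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "set_index") <- s
    attr(out, "seed") <- seed + s
    out
  })
}

# bins eligible as control regions: early-replicating center, far from MiDAS
# peak bins, R-loop peak within the window
eligible_control_bins <- function(rt_domains, rloop_peaks, midas_sites, layout,
                                  exclusion_bins = 50, window = 50000) {
  bs <- layout$bin_size
  early <- rt_domains[rt_domains$name == "early", , drop = FALSE]
  peak_bins_by_chrom <- midas_peak_bins(midas_sites, bs)
  rows <- list()
  for (chrom in layout$chrom_names) {
    nb <- layout$n_bins[[chrom]]
    b <- 0:(nb - 1)
    center <- floor((b * bs + pmin((b + 1) * bs, layout$chrom_lengths[[chrom]])) / 2)
    # early-replicating: bin center inside an early domain
    ec <- early[early$chrom == chrom, , drop = FALSE]
    in_early <- rep(FALSE, nb)
    if (nrow(ec) > 0L) {
      pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(center + 1, width = 1))
      in_early <- GenomicRanges::countOverlaps(pts, gr_intervals(ec)) > 0
    }
    # distance (in bins) from every MiDAS peak bin
    far <- rep(TRUE, nb)
    pb <- peak_bins_by_chrom[[chrom]]
    if (length(pb) > 0L) {
      for (p in pb) far <- far & abs(b - p) >= exclusion_bins
    }
    # R-loop peak within the window of the bin center
    rl <- rloop_peaks[rloop_peaks$chrom == chrom, , drop = FALSE]
    has_rloop <- rep(FALSE, nb)
    if (nrow(rl) > 0L) {
      win <- gr_windows(rep(chrom, nb), center, window)
      has_rloop <- GenomicRanges::countOverlaps(win, gr_intervals(rl)) > 0
    }
    ok <- in_early & far & has_rloop
    if (any(ok)) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom,
        start = b[ok] * bs,
        end = pmin((b[ok] + 1) * bs, layout$chrom_lengths[[chrom]]),
        center = center[ok],
        bin = b[ok],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      chrom = character(0), start = numeric(0), end = numeric(0),
      center = numeric(0), bin = numeric(0)
    ))
  }
  do.call(rbind, rows)
}

# per-chromosome 0-based peak bins of a site table (falls back to anchor bins)
midas_peak_bins <- function(sites, bin_size) {
  out <- list()
  if (nrow(sites) == 0L) return(out)
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    pb_field <- if ("peak_bins" %in% names(sites)) {
      # tables reloaded from disk may carry this column as integer
      as.character(sites$peak_bins[i])
    } else {
      NA_character_
    }
    if (!is.na(pb_field) && nzchar(pb_field)) {
      pb <- as.numeric(strsplit(pb_field, ",", fixed = TRUE)[[1]])
    } else {
      pb <- bin_index(site_anchors(sites[i, , drop = FALSE]), bin_size)
    }
    out[[chrom]] <- c(out[[chrom]], pb)
  }
  out
}

#' Write control-region sets as BED6
#'
#' One file per set is avoided: all sets go to a single BED6 file with the
#' set index recorded in the name field (`set<k>_bin<b>`).
#'
#' @param sets list returned by [sample_control_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_control_regions <- function(sets, path) {
  dfs <- lapply(sets, function(s) {
    data.frame(
      chrom = s$chrom, start = s$start, end = s$end,
      name = sprintf("set%d_bin%d", attr(s, "set_index"), s$bin),
      score = NA_real_, strand = ".",
      stringsAsFactors = FALSE
    )
  })
  write_intervals(do.call(rbind, dfs), path)
}
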
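#' Fraction of sites coinciding with R-loop peaks
#'
#' A site is coincident with R-loops if at least one R-loop peak intersects
#' the half-open window `[anchor - window, anchor + window)`.
#'
#' @param sites a site table.
#' @param rloop_peaks R-loop peak intervals (DRIP-seq / qDRIP-seq peaks).
#' @param window half-width in bp (default 50,000).
#' @return A list: `n_coincident`, `n_total`, `fraction`, and `coincident`
#'   (logical vector per site).
#' @export
rloop_overlap_fraction <- function(sites, rloop_peaks, window = 50000) {
  if (nrow(sites) == 0L) stop("empty site list")
  win <- gr_windows(sites$chrom, site_anchors(sites), window)
  hit <- GenomicRanges::countOverlaps(win, gr_intervals(rloop_peaks)) > 0
  list(
    n_coincident = sum(hit),
    n_total = nrow(sites),
    fraction = mean(hit),
    coincident = hit
  )
}

#' Average signal profile centered on site anchors
#'
#' For each offset `o` in `[-span/2, span/2)` stepped by the signal's bin
#' size, the profile is the mean over sites of the signal in the bin
#' containing `anchor + o`. Sites whose window would extend past a chromosome
#' end are dropped (with a warning reporting the count).
#'
#' @param sites a site table.
#' @param signal a `bin_track` (any bin size; 50 bp for qDRIP/EU-style
#'   signal, 10 kb for MiDAS sigma).
#' @param span total window width in bp; must be a multiple of the signal bin
#'   size.
#' @return A data frame (`offset_bp`, `mean_signal`) with attributes
#'   `n_sites_used` and `n_dropped`.
#' @export
aggregate_signal_profile <- function(sites, signal, span) {
  if (nrow(sites) == 0L) stop("empty site list")
  stopifnot(inherits(signal, "bin_track"))
  bs <- signal$layout$bin_size
  if (span <= 0 || span %% bs != 0) {
    stop("span must be a positive multiple of the signal bin size")
  }
  k <- span / bs
  anchors <- site_anchors(sites)
  mat <- matrix(NA_real_, nrow = nrow(sites), ncol = k)
  used <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    v <- signal$values[[sites$chrom[i]]]
    if (is.null(v)) next
    b0 <- bin_index(anchors[i] - span / 2, bs)
    idx <- b0 + 0:(k - 1)
    if (b0 < 0 || idx[k] >= length(v)) next
    mat[i, ] <- v[idx + 1]
    used[i] <- TRUE
  }
  n_dropped <- sum(!used)
  if (n_dropped > 0L) {
    warning(sprintf("%d site(s) truncated by chromosome ends were dropped", n_dropped))
  }
  if (!any(used)) stop("no usable sites for the requested span")
  out <- data.frame(
    offset_bp = -span / 2 + (0:(k - 1)) * bs,
    mean_signal = colMeans(mat[used, , drop = FALSE], na.rm = TRUE)
  )
  attr(out, "n_sites_used") <- sum(used)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' G-quadruplex density around site anchors
#'
#' Number of G4 intervals intersecting the half-open window
#' `[anchor - span/2, anchor + span/2)`, expressed per kilobase of window.
#'
#' @param sites a site table.
#' @param g4_positions G4 interval data frame.
#' @param span window width in bp (default 110,000).
#' @return Numeric vector: G4s per kb, one per site.
#' @export
g4_density <- function(sites, g4_positions, span = 110000) {
  if (span <= 0) stop("span must be > 0")
  if (nrow(sites) == 0L) return(numeric(0))
  win <- gr_windows(sites$chrom, site_anchors(sites), span / 2)
  counts <- GenomicRanges::countOverlaps(win, gr_intervals(g4_positions))
  counts / (span / 1000)
}

#' Transcripts-per-million quantification
#'
#' `rate_g = count_g / (length_g / 1000)`; `tpm_g = rate_g / sum(rate) * 1e6`.
#' TPM sums to one million over genes by construction. `log10_tpm1` is
#' `log10(TPM + 1)`.
#'
#' @param counts reads per gene (non-negative).
#' @param lengths gene lengths in bp (positive).
#' @param gene_id optional gene identifiers.
#' @return A data frame: `gene_id`, `count`, `length_bp`, `tpm`,
#'   `log10_tpm1`.
#' @export
quantify_tpm <- function(counts, lengths, gene_id = NULL) {
  if (length(counts) != length(lengths)) {
    stop("counts and lengths must have the same length")
  }
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (is.null(gene_id)) gene_id <- sprintf("gene_%05d", seq_along(counts))
  rate <- counts / (lengths / 1000)
  tot <- sum(rate)
  if (tot == 0) {
    warning("zero total rate: returning all-zero TPM")
    tpm <- rep(0, length(counts))
  } else {
    tpm <- rate / tot * 1e6
  }
  data.frame(
    gene_id = gene_id, count = counts, length_bp = lengths,
    tpm = tpm, log10_tpm1 = log10(tpm + 1),
    stringsAsFactors = FALSE
  )
}

#' Compare expression of site genes versus control genes
#'
#' Summaries of `log10(TPM + 1)` per set and an unpaired two-tailed t-test.
#'
#' @param site_log_tpm,control_log_tpm numeric vectors of `log10(TPM + 1)`.
#' @return A list: `site_median`, `site_mean`, `control_median`,
#'   `control_mean`, `p_value`.
#' @export
compare_site_expression <- function(site_log_tpm, control_log_tpm) {
  if (length(site_log_tpm) == 0L || length(control_log_tpm) == 0L) {
    stop("both expression sets must be non-empty")
  }
  p <- tryCatch(
    stats::t.test(site_log_tpm, control_log_tpm,
      alternative = "two.sided", paired = FALSE
    )$p.value,
    error = function(e) {
      # essentially-constant data: equal means are indistinguishable
      if (isTRUE(all.equal(mean(site_log_tpm), mean(control_log_tpm)))) 1 else 0
    }
  )
  list(
    site_median = stats::median(site_log_tpm),
    site_mean = mean(site_log_tpm),
    control_median = stats::median(control_log_tpm),
    control_mean = mean(control_log_tpm),
    p_value = p
  )
}

#' Classify sites as transcribed in early S-phase
#'
#' Two interchangeable rules, since published analyses report the transcribed
#' fraction without fixing the criterion:
#' * `rule = "signal"` (default): the site is transcribed if the summed
#'   nascent-RNA (EU) signal within +/- `window` of the anchor, on the
#'   stronger of the two strands and after subtracting `background` per
#'   window, exceeds `min_signal`.
#' * `rule = "peaks"`: transcribed if at least one interval of `peaks`
#'   (called EU peaks) intersects the window.
#'
#' @param sites a site table.
#' @param eu_plus,eu_minus stranded EU signal as `bin_track`s (`eu_minus` may
#'   be `NULL` for unstranded signal).
#' @param window half-width in bp (default 50,000).
#' @param min_signal threshold on the background-subtracted window sum
#'   (default 0, i.e. any supra-background signal).
#' @param background background signal level subtracted per window (default 0).
#' @param rule `"signal"` or `"peaks"`.
#' @param peaks EU peak intervals, required for `rule = "peaks"`.
#' @return A list: `n_transcribed`, `n_total`, `fraction`, `transcribed`
#'   (logical per site).
#' @export
classify_transcribed_sites <- function(sites, eu_plus = NULL, eu_minus = NULL,
                                       window = 50000, min_signal = 0,
                                       background = 0,
                                       rule = c("signal", "peaks"),
                                       peaks = NULL) {
  rule <- match.arg(rule)
  if (nrow(sites) == 0L) {
    return(list(
      n_transcribed = 0L, n_total = 0L,
      fraction = NA_real_, transcribed = logical(0)
    ))
  }
  anchors <- site_anchors(sites)
  if (rule == "peaks") {
    if (is.null(peaks)) stop("rule = 'peaks' requires EU peak intervals")
    win <- gr_windows(sites$chrom, anchors, window)
    transcribed <- GenomicRanges::countOverlaps(win, gr_intervals(peaks)) > 0
  } else {
    if (is.null(eu_plus)) stop("rule = 'signal' requires an EU signal track")
    transcribed <- vapply(seq_len(nrow(sites)), function(i) {
      sp <- window_bin_sum(eu_plus, sites$chrom[i], anchors[i], window)
      sm <- if (!is.null(eu_minus)) {
        window_bin_sum(eu_minus, sites$chrom[i], anchors[i], window)
      } else {
        -Inf
      }
      max(sp, sm) - background > min_signal
    }, logical(1))
  }
  list(
    n_transcribed = sum(transcribed),
    n_total = nrow(sites),
    fraction = mean(transcribed),
    transcribed = transcribed
  )
}
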
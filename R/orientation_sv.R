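#' Mean replication fork directionality over sites
#'
#' Unweighted mean of the non-missing RFD bin values over either a fixed
#' window centered on the site anchor (default 150 kb) or the site's gene
#' body. Positive RFD means predominantly rightward-moving forks.
#'
#' @param sites a site table.
#' @param rfd a `bin_track` of kind `"rfd"` (values in `[-1, 1]`, `NA` for
#'   missing bins).
#' @param span fixed-window width in bp (default 150,000).
#' @param extent `"fixed_window"` (default) or `"gene_body"`.
#' @param genes gene intervals, one row per site, required for
#'   `extent = "gene_body"`.
#' @return Numeric vector of mean RFD values; `NA` where every bin in the
#'   extent is missing (a warning reports how many).
#' @export
mean_rfd_over_site <- function(sites, rfd, span = 150000,
                               extent = c("fixed_window", "gene_body"),
                               genes = NULL) {
  extent <- match.arg(extent)
  stopifnot(inherits(rfd, "bin_track"))
  if (nrow(sites) == 0L) return(numeric(0))
  anchors <- site_anchors(sites)
  out <- vapply(seq_len(nrow(sites)), function(i) {
    if (extent == "fixed_window") {
      window_bin_mean(rfd, sites$chrom[i], anchors[i], span / 2)
    } else {
      g <- genes[i, , drop = FALSE]
      center <- floor((g$start + g$end) / 2)
      window_bin_mean(rfd, g$chrom, center, (g$end - g$start) / 2)
    }
  }, numeric(1))
  if (all(is.na(out))) stop("no RFD data over any site")
  if (anyNA(out)) {
    warning(sprintf("%d site(s) have no RFD data in their extent", sum(is.na(out))))
  }
  out
}

#' Orient replication relative to transcription at single-gene sites
#'
#' Restricted to sites with exactly one gene within the +/- `window` anchor
#' window (multi-gene or gene-free sites are reported as
#' `"not_applicable"` and excluded from the tally). A site is co-directional
#' when the sign of its mean RFD matches the gene strand (`+` with positive
#' RFD, `-` with negative) and `|mean RFD| >= tau`; head-on when the signs
#' oppose at `|mean RFD| >= tau`; ambiguous otherwise.
#'
#' @param sites a site table.
#' @param genes gene intervals (`name` = symbol, `strand` in `+`/`-`).
#' @param rfd a `bin_track` of kind `"rfd"`.
#' @param tau ambiguity threshold on `|mean RFD|` (default 0.1).
#' @param window gene-assignment half-width in bp (default 50,000).
#' @param span RFD averaging window in bp (default 150,000).
#' @return A data frame: `site_id`, `gene`, `gene_strand`, `mean_rfd`,
#'   `call` (`co-directional`, `head-on`, `ambiguous`, `not_applicable`).
#' @export
classify_orientation <- function(sites, genes, rfd, tau = 0.1,
                                 window = 50000, span = 150000) {
  if (nrow(sites) == 0L) {
    return(data.frame(
      site_id = character(0), gene = character(0), gene_strand = character(0),
      mean_rfd = numeric(0), call = character(0)
    ))
  }
  cg <- classify_genic(sites, genes, window = window)
  mean_rfd <- suppressWarnings(mean_rfd_over_site(sites, rfd, span = span))
  call <- rep("not_applicable", nrow(sites))
  gene <- rep(NA_character_, nrow(sites))
  gene_strand <- rep(NA_character_, nrow(sites))
  single <- which(cg$gene_count == 1L)
  for (i in single) {
    gene[i] <- cg$genes[i]
    gs <- genes$strand[match(cg$genes[i], genes$name)]
    gene_strand[i] <- gs
    r <- mean_rfd[i]
    if (is.na(r) || !gs %in% c("+", "-")) {
      call[i] <- "not_applicable"
    } else if (abs(r) < tau) {
      call[i] <- "ambiguous"
    } else if ((gs == "+") == (r > 0)) {
      call[i] <- "co-directional"
    } else {
      call[i] <- "head-on"
    }
  }
  data.frame(
    site_id = cg$site_id, gene = gene, gene_strand = gene_strand,
    mean_rfd = mean_rfd, call = call, stringsAsFactors = FALSE
  )
}

#' Summarize orientation calls
#'
#' Fractions of co-directional, head-on and ambiguous calls over all
#' classified (applicable) sites; the three fractions sum to 1.
#'
#' @param calls output of [classify_orientation()].
#' @return A list: `n`, `fraction_codirectional`, `fraction_head_on`,
#'   `fraction_ambiguous`.
#' @export
orientation_summary <- function(calls) {
  appl <- calls$call[calls$call != "not_applicable"]
  if (length(appl) == 0L) stop("no classified sites")
  list(
    n = length(appl),
    fraction_codirectional = mean(appl == "co-directional"),
    fraction_head_on = mean(appl == "head-on"),
    fraction_ambiguous = mean(appl == "ambiguous")
  )
}

#' Per-site structural-variant frequency in tumor cohorts
#'
#' For each site and cohort, the percentage of tumors with at least one
#' rearrangement breakpoint (either end of any record) inside the half-open
#' window `[anchor - window, anchor + window)` on the matching chromosome.
#' A tumor counts at most once per site however many of its breakpoints fall
#' in the window. Translocation records contribute both ends independently.
#'
#' @param sites a site table.
#' @param sv_records data frame of rearrangements with columns `sample_id`,
#'   `cohort`, `chrom1`, `pos1`, `chrom2`, `pos2` (and optionally `type`).
#' @param cohort_sizes named integer vector: number of tumors per cohort
#'   (denominators; tumors without rearrangements never appear in
#'   `sv_records`).
#' @param window half-width in bp (default 200,000).
#' @return A data frame: `site_id`, `cohort`, `n_tumors`, `percentage`.
#' @export
site_sv_frequency <- function(sites, sv_records, cohort_sizes, window = 200000) {
  if (is.null(names(cohort_sizes)) || any(cohort_sizes <= 0)) {
    stop("cohort_sizes must be a named vector of positive counts")
  }
  if (nrow(sv_records) > 0L) {
    unknown <- setdiff(unique(sv_records$cohort), names(cohort_sizes))
    if (length(unknown) > 0L) {
      stop("cohort not in cohort_sizes: ", paste(unknown, collapse = ", "))
    }
  }
  grid <- expand.grid(
    site_id = site_ids(sites), cohort = names(cohort_sizes),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$n_tumors <- 0L
  if (nrow(sites) > 0L && nrow(sv_records) > 0L) {
    bp <- data.frame(
      sample_id = rep(sv_records$sample_id, 2),
      cohort = rep(sv_records$cohort, 2),
      chrom = c(sv_records$chrom1, sv_records$chrom2),
      pos = c(sv_records$pos1, sv_records$pos2),
      stringsAsFactors = FALSE
    )
    bp <- bp[!is.na(bp$chrom) & !is.na(bp$pos), , drop = FALSE]
    win <- gr_windows(sites$chrom, site_anchors(sites), window)
    pts <- GenomicRanges::GRanges(bp$chrom, IRanges::IRanges(bp$pos + 1, width = 1))
    hits <- GenomicRanges::findOverlaps(win, pts)
    if (length(hits) > 0L) {
      hit_df <- unique(data.frame(
        site_id = site_ids(sites)[S4Vectors::queryHits(hits)],
        cohort = bp$cohort[S4Vectors::subjectHits(hits)],
        sample_id = bp$sample_id[S4Vectors::subjectHits(hits)],
        stringsAsFactors = FALSE
      ))
      agg <- stats::aggregate(
        sample_id ~ site_id + cohort,
        data = hit_df, FUN = function(x) length(unique(x))
      )
      m <- match(
        paste(grid$site_id, grid$cohort),
        paste(agg$site_id, agg$cohort)
      )
      grid$n_tumors[!is.na(m)] <- agg$sample_id[m[!is.na(m)]]
    }
  }
  grid$percentage <- grid$n_tumors / as.numeric(cohort_sizes[grid$cohort]) * 100
  grid
}

#' Compare per-site SV frequencies across groups
#'
#' Group summaries plus one-way ANOVA with Tukey honest-significant-difference
#' adjusted pairwise p-values, the standard comparison for per-site tumor
#' rearrangement percentages across site sets and cohorts.
#'
#' @param percentages numeric vector of per-site percentages.
#' @param group factor/character vector of group labels (e.g. site set x
#'   cohort), parallel to `percentages`.
#' @return A list: `summary` (data frame of group `n`, `mean`, `median`) and
#'   `tukey` (data frame of pairwise `comparison`, `diff`, `p_adj`).
#' @export
cohort_sv_comparison <- function(percentages, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  tabs <- table(group)
  if (any(tabs < 2L)) stop("every group needs at least 2 sites")
  df <- data.frame(y = percentages, g = group)
  fit <- stats::aov(y ~ g, data = df)
  tk <- stats::TukeyHSD(fit)$g
  list(
    summary = data.frame(
      group = levels(group),
      n = as.integer(tabs),
      mean = as.numeric(tapply(percentages, group, mean)),
      median = as.numeric(tapply(percentages, group, stats::median)),
      stringsAsFactors = FALSE
    ),
    tukey = data.frame(
      comparison = rownames(tk),
      diff = tk[, "diff"],
      p_adj = tk[, "p adj"],
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  )
}
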
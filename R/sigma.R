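#' Sigma-value normalization of binned nascent-DNA counts
#'
#' Converts raw per-bin read counts into sigma values, the enrichment
#' statistic used to call mitotic DNA synthesis (MiDAS) sites. Counts are
#' first library-size normalized (`n_i = c_i / mean(c)` over included bins,
#' so the normalized track has mean 1 and is invariant under uniform scaling
#' of sequencing depth) and then expressed in standard-deviation units:
#' `sigma_i = (n_i - center) / scale`. With the default robust estimator the
#' center is the median and the scale is `1.4826 * MAD` of the normalized
#' counts over nonzero bins, so that the enriched bins themselves do not
#' inflate the denominator; the plain estimator uses the mean and the sample
#' standard deviation. `center = FALSE` divides the uncentered normalized
#' count by the scale instead.
#'
#' @param counts a `bin_track` of kind `"raw_count"`.
#' @param estimator `"robust"` (default) or `"plain"`.
#' @param center logical; subtract the center estimate before scaling
#'   (default `TRUE`, giving a standard score whose background sits near 0).
#' @param include which bins enter the normalization and spread estimates:
#'   `"nonzero"` (default) or `"all"`.
#' @return A `bin_track` of kind `"sigma"` with an extra element `meta`
#'   (list: `mean_count`, `sd_estimate`, `estimator`, `centered`).
#' @examples
#' layout <- genome_layout("chr1", 1e5, bin_size = 1e4)
#' counts <- bin_track(layout, list(chr1 = c(2, 2, 2, 2, 12, 2, 2, 2, 2, 2)),
#'   kind = "raw_count")
#' sig <- compute_sigma(counts, estimator = "plain")
#' which.max(sig$values$chr1)
#' @export
compute_sigma <- function(counts,
                          estimator = c("robust", "plain"),
                          center = TRUE,
                          include = c("nonzero", "all")) {
  stopifnot(inherits(counts, "bin_track"))
  if (counts$kind != "raw_count") stop("compute_sigma expects a raw_count track")
  estimator <- match.arg(estimator)
  include <- match.arg(include)
  pool <- unlist(counts$values, use.names = FALSE)
  if (anyNA(pool)) stop("raw counts must not contain NA")
  if (all(pool == 0)) stop("all-zero track: nothing to normalize")
  incl <- if (include == "nonzero") pool > 0 else rep(TRUE, length(pool))
  if (sum(incl) < 2L) stop("need at least 2 bins with nonzero counts")
  m <- mean(pool[incl])
  n <- pool / m
  if (estimator == "plain") {
    mu <- mean(n[incl])
    s <- stats::sd(n[incl])
  } else {
    mu <- stats::median(n[incl])
    s <- stats::mad(n[incl])
  }
  if (!is.finite(s) || s <= 0) {
    stop("degenerate variance: spread of normalized counts is zero")
  }
  if (!center) mu <- 0
  sigma <- (n - mu) / s
  values <- split_like(sigma, counts$values)
  out <- bin_track(counts$layout, values, kind = "sigma")
  out$meta <- list(
    mean_count = m, sd_estimate = s,
    estimator = estimator, centered = center
  )
  out
}

# split a flat vector back into the shape of a per-chromosome value list
split_like <- function(x, template) {
  out <- vector("list", length(template))
  names(out) <- names(template)
  at <- 0L
  for (chrom in names(template)) {
    k <- length(template[[chrom]])
    out[[chrom]] <- x[(at + 1):(at + k)]
    at <- at + k
  }
  out
}
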
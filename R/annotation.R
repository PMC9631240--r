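#' Match two site sets by anchor distance
#'
#' A site in `a` is matched if some site in `b` on the same chromosome has an
#' anchor within `window` bp of its own anchor (inclusive). Used to compare
#' MiDAS site catalogs between conditions, e.g. BRCA2-depleted versus
#' aphidicolin-treated cells at the conventional +/- 600 kb.
#'
#' @param a,b site tables ([call_midas_sites()] output, or any interval data
#'   frame — anchors default to interval midpoints).
#' @param window maximum anchor distance in bp (default 600,000).
#' @return A list: `n_a_matched`, `n_b_matched`, and `pairs`, a data frame of
#'   matched index pairs (`a_idx`, `b_idx`, `distance`).
#' @export
overlap_site_sets <- function(a, b, window = 600000) {
  if (window < 0) stop("window must be >= 0")
  pa <- gr_points(a)
  pb <- gr_points(b)
  # disjoint chromosome sets are a legitimate no-match case, not a warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(pa, pb, maxgap = max(window - 1, -1))
  )
  ai <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  dist <- abs(site_anchors(a)[ai] - site_anchors(b)[bi])
  keep <- dist <= window
  pairs <- data.frame(a_idx = ai[keep], b_idx = bi[keep], distance = dist[keep])
  list(
    n_a_matched = length(unique(pairs$a_idx)),
    n_b_matched = length(unique(pairs$b_idx)),
    pairs = pairs
  )
}

gr_points <- function(x) {
  anchors <- site_anchors(x)
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(anchors + 1, width = 1))
}

#' Assign replication timing to sites
#'
#' Each site takes the timing label of the replication-timing domain
#' containing its anchor; `"undefined"` where no domain covers the anchor.
#'
#' @param sites a site table.
#' @param domains an interval data frame whose `name` column holds the timing
#'   label (`early`, `mid`, `late`); domains must not overlap within a
#'   chromosome.
#' @return Character vector of timing labels, one per site.
#' @export
assign_replication_timing <- function(sites, domains) {
  check_nonoverlapping(domains)
  if (nrow(sites) == 0L) return(character(0))
  hits <- GenomicRanges::findOverlaps(gr_points(sites), gr_intervals(domains))
  timing <- rep("undefined", nrow(sites))
  timing[S4Vectors::queryHits(hits)] <- domains$name[S4Vectors::subjectHits(hits)]
  timing
}

check_nonoverlapping <- function(domains) {
  for (chrom in unique(domains$chrom)) {
    d <- domains[domains$chrom == chrom, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("overlapping replication-timing domains on ", chrom)
    }
  }
  invisible(TRUE)
}

#' Classify sites as genic or intergenic
#'
#' A site is genic if at least one gene intersects the half-open window
#' `[anchor - window, anchor + window)` (default +/- 50 kb, the convention
#' for gene assignment around a MiDAS peak).
#'
#' @param sites a site table.
#' @param genes a gene interval data frame (`name` = gene symbol).
#' @param window half-width in bp (default 50,000).
#' @return A data frame with one row per site: `site_id`, `genic`
#'   (`"genic"`/`"intergenic"`), `gene_count`, and `genes` (comma-separated
#'   symbols, `""` when none).
#' @export
classify_genic <- function(sites, genes, window = 50000) {
  if (nrow(sites) == 0L) {
    return(data.frame(
      site_id = character(0), genic = character(0),
      gene_count = integer(0), genes = character(0)
    ))
  }
  win <- gr_windows(sites$chrom, site_anchors(sites), window)
  gg <- gr_intervals(genes)
  hits <- GenomicRanges::findOverlaps(win, gg)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  count <- tabulate(q, nbins = nrow(sites))
  labels <- vapply(seq_len(nrow(sites)), function(i) {
    paste(genes$name[s[q == i]], collapse = ",")
  }, character(1))
  data.frame(
    site_id = site_ids(sites),
    genic = ifelse(count >= 1L, "genic", "intergenic"),
    gene_count = count,
    genes = labels,
    stringsAsFactors = FALSE
  )
}

site_ids <- function(sites) {
  if ("site_id" %in% names(sites)) {
    as.character(sites$site_id)
  } else if ("name" %in% names(sites)) {
    as.character(sites$name)
  } else {
    sprintf("site_%04d", seq_len(nrow(sites)))
  }
}

#' Per-site gene counts around anchors
#'
#' Gene frequency in the vicinity of each site (the count of genes
#' intersecting the +/- `window` anchor window), plus its histogram.
#'
#' @inheritParams classify_genic
#' @return A list: `counts` (integer vector, one per site) and `histogram`
#'   (a table of count frequencies).
#' @export
gene_density <- function(sites, genes, window = 50000) {
  cg <- classify_genic(sites, genes, window = window)
  list(counts = cg$gene_count, histogram = table(cg$gene_count))
}

#' Distance from each site to its nearest replication origin
#'
#' Edge-to-edge distance between the anchor bin (the bin containing the site
#' anchor) and the nearest origin interval on the same chromosome; 0 when
#' they intersect; `NA` ("unassigned") when the chromosome carries no origin
#' or the nearest origin is farther than `max_distance`.
#'
#' @param sites a site table.
#' @param origins an origin interval data frame.
#' @param bin_size bin width used to form the anchor bin (default 10,000).
#' @param max_distance optional cap beyond which the distance is `NA`.
#' @return Numeric vector of distances in bp (`NA` = unassigned).
#' @export
nearest_origin_distance <- function(sites, origins, bin_size = 10000,
                                    max_distance = Inf) {
  if (nrow(sites) == 0L) return(numeric(0))
  b <- bin_index(site_anchors(sites), bin_size)
  bins <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(b * bin_size + 1, (b + 1) * bin_size)
  )
  og <- gr_intervals(origins)
  out <- rep(NA_real_, nrow(sites))
  if (length(og) == 0L) return(out)
  # origins may live on chromosomes without sites; those pairs simply stay NA
  hits <- suppressWarnings(GenomicRanges::distanceToNearest(bins, og))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out[!is.na(out) & out > max_distance] <- NA_real_
  out
}

#' Overlap between site-associated genes and a fragile-site gene list
#'
#' Counts the genes found within MiDAS site windows that appear in a list of
#' genes mapping to cytogenetically defined common fragile sites (CFSs).
#' Matching is case-insensitive exact match after whitespace stripping.
#'
#' @param site_genes character vector of gene symbols found at sites.
#' @param cfs_genes character vector of CFS gene symbols.
#' @return A list: `n_hit`, `n_total` (unique site genes) and `fraction`.
#' @export
cfs_gene_overlap <- function(site_genes, cfs_genes) {
  if (length(site_genes) == 0L) stop("empty site gene list")
  norm <- function(x) toupper(trimws(x))
  sg <- unique(norm(site_genes))
  cg <- unique(norm(cfs_genes))
  n_hit <- sum(sg %in% cg)
  list(n_hit = n_hit, n_total = length(sg), fraction = n_hit / length(sg))
}

#' Compare gene-length distributions between two gene sets
#'
#' Gene length is `end - start`; distributions are compared with a two-tailed
#' Mann-Whitney (Wilcoxon rank-sum) test, the standard test for the skewed
#' gene-size distributions of fragile-site versus average genes.
#'
#' @param site_genes,reference_genes gene interval data frames.
#' @return A list: `median_site`, `median_ref` (bp) and `p_value`.
#' @export
summarize_gene_sizes <- function(site_genes, reference_genes) {
  if (nrow(site_genes) == 0L || nrow(reference_genes) == 0L) {
    stop("gene sets must be non-empty")
  }
  ls <- site_genes$end - site_genes$start
  lr <- reference_genes$end - reference_genes$start
  p <- suppressWarnings(
    stats::wilcox.test(ls, lr, alternative = "two.sided")$p.value
  )
  list(median_site = stats::median(ls), median_ref = stats::median(lr), p_value = p)
}
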
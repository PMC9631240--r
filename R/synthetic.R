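#' Configuration for the synthetic genome generator
#'
#' The generator builds a toy genome carrying every structure the MiDAS
#' analysis assumes: Poisson background bin counts with planted enrichment
#' sites (single- and double-peak), strand-annotated genes with a realistic
#' log-normal size spread, alternating early/mid/late replication-timing
#' domains, origins confined to early domains, R-loop peaks over highly
#' transcribed genes, an origin-derived sawtooth fork-directionality track,
#' and two tumor cohorts with breakpoints enriched near planted sites in one
#' cohort. Defaults define the study conditions used throughout the test
#' suite: a 2 x 50-Mb genome at 10-kb bins, background 50 reads/bin, 20
#' planted sites at 8-fold enrichment.
#'
#' @param n_chroms number of chromosomes (default 2).
#' @param chrom_length chromosome length in bp (default 5e7).
#' @param bin_size bin width in bp (default 10,000).
#' @param background_lambda Poisson background mean, reads/bin (default 50).
#' @param n_planted_sites planted enrichment sites (default 20).
#' @param enrichment_fold peak bin mean as a multiple of the background
#'   (default 8).
#' @param double_peak_fraction fraction of planted sites carrying two
#'   enrichment bumps 20-60 bins apart (default 0.2), mimicking replication
#'   forks at both edges of a large under-replicated region.
#' @param peak_width_bins Gaussian bump standard deviation in bins
#'   (default 1.5, i.e. a visible width of about 3 bins).
#' @param aph_fraction fraction of planted sites drawn in the
#'   aphidicolin-like regime (late-replicating, long genes, origin-distant);
#'   the rest are BRCA2-like (early, gene-rich, origin-proximal,
#'   R-loop-prone). Default 0.
#' @param gene_size_meanlog,gene_size_sdlog log-normal gene size parameters
#'   (defaults give a median of ~40 kb, the genome-wide median gene size).
#' @param gene_gap_min,gene_gap_max intergenic gap range in bp.
#' @param expression_meanlog,expression_sdlog log-normal per-gene expression
#'   level parameters.
#' @param rt_domain_length replication-timing domain length in bp
#'   (default 5e6, cycling early/mid/late).
#' @param rloop_top_fraction fraction of most highly expressed genes hosting
#'   an R-loop peak (default 0.25, the top quartile).
#' @param origin_spacing origin spacing within early domains in bp
#'   (default 3e5).
#' @param sv_rate_near_sites per-tumor probability of a breakpoint within
#'   +/- 200 kb of each BRCA2-like site in the mutated cohort (default 0.30).
#' @param sv_rate_background same probability for the wild-type cohort
#'   (default 0.05).
#' @param n_tumors_per_cohort tumors per cohort (default 100).
#' @param n_background_svs uniform background rearrangements per tumor
#'   (default 1).
#' @param dispersion negative-binomial size parameter for bin counts;
#'   `Inf` (default) gives Poisson counts.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_chroms = 2,
                             chrom_length = 5e7,
                             bin_size = 10000,
                             background_lambda = 50,
                             n_planted_sites = 20,
                             enrichment_fold = 8,
                             double_peak_fraction = 0.2,
                             peak_width_bins = 1.5,
                             aph_fraction = 0,
                             gene_size_meanlog = log(4e4),
                             gene_size_sdlog = 0.8,
                             gene_gap_min = 2e4,
                             gene_gap_max = 8e4,
                             expression_meanlog = 3,
                             expression_sdlog = 1.2,
                             rt_domain_length = 5e6,
                             rloop_top_fraction = 0.25,
                             origin_spacing = 3e5,
                             sv_rate_near_sites = 0.30,
                             sv_rate_background = 0.05,
                             n_tumors_per_cohort = 100,
                             n_background_svs = 1,
                             dispersion = Inf) {
  cfg <- list(
    n_chroms = n_chroms, chrom_length = chrom_length, bin_size = bin_size,
    background_lambda = background_lambda, n_planted_sites = n_planted_sites,
    enrichment_fold = enrichment_fold,
    double_peak_fraction = double_peak_fraction,
    peak_width_bins = peak_width_bins, aph_fraction = aph_fraction,
    gene_size_meanlog = gene_size_meanlog, gene_size_sdlog = gene_size_sdlog,
    gene_gap_min = gene_gap_min, gene_gap_max = gene_gap_max,
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog,
    rt_domain_length = rt_domain_length,
    rloop_top_fraction = rloop_top_fraction,
    origin_spacing = origin_spacing,
    sv_rate_near_sites = sv_rate_near_sites,
    sv_rate_background = sv_rate_background,
    n_tumors_per_cohort = n_tumors_per_cohort,
    n_background_svs = n_background_svs,
    dispersion = dispersion
  )
  pos <- c(
    "n_chroms", "chrom_length", "bin_size", "background_lambda",
    "enrichment_fold", "peak_width_bins", "gene_gap_min", "gene_gap_max",
    "rt_domain_length", "origin_spacing", "n_tumors_per_cohort"
  )
  for (k in pos) {
    if (!is.finite(cfg[[k]]) || cfg[[k]] <= 0) stop(k, " must be positive")
  }
  frac <- c(
    "double_peak_fraction", "aph_fraction", "rloop_top_fraction",
    "sv_rate_near_sites", "sv_rate_background"
  )
  for (k in frac) {
    if (cfg[[k]] < 0 || cfg[[k]] > 1) stop(k, " must lie in [0, 1]")
  }
  if (cfg$n_planted_sites < 0) stop("n_planted_sites must be >= 0")
  if (cfg$n_background_svs < 0) stop("n_background_svs must be >= 0")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic world with known ground truth
#'
#' Deterministic given `(config, seed)`. BRCA2-like planted sites lie in
#' early-replicating domains inside highly transcribed, R-loop-hosting genes
#' with a replication origin within 100 kb; aphidicolin-like sites lie in
#' late domains inside long genes, away from origins. The fork-directionality
#' track is the analytic sawtooth implied by the origin placement: +1 just
#' right of each origin, decreasing linearly to -1 just left of the next.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return An object of class `synthetic_truth`: a list with elements
#'   `config`, `seed`, `layout`, `rt_domains`, `genes`, `origins`, `rloops`,
#'   `g4s`, `sites` (planted ground truth), `rfd` (a `bin_track`) and
#'   `expression`.
#' @export
generate_world <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  bs <- config$bin_size
  layout <- genome_layout(
    paste0("chr", seq_len(config$n_chroms)),
    rep(config$chrom_length, config$n_chroms),
    bin_size = bs
  )

  rt_domains <- synth_rt_domains(layout, config$rt_domain_length)
  genes <- synth_genes(layout, config)
  genes <- rbind(genes, synth_long_late_genes(layout, rt_domains, config))
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  genes$name <- sprintf("gene_%05d", seq_len(nrow(genes)))
  rownames(genes) <- NULL
  genes$level <- stats::rlnorm(
    nrow(genes), config$expression_meanlog, config$expression_sdlog
  )
  origins <- synth_origins(rt_domains, config$origin_spacing, layout)

  n_aph <- round(config$aph_fraction * config$n_planted_sites)
  n_brca <- config$n_planted_sites - n_aph
  placed <- plant_sites(genes, rt_domains, origins, layout, config, n_brca, n_aph)
  sites <- placed$sites
  genes <- placed$genes
  origins <- placed$origins

  rloops <- synth_rloops(genes, sites, config)
  g4s <- synth_g4s(layout, sites)
  rfd <- synth_rfd(origins, layout)
  expression <- data.frame(
    gene_id = genes$name,
    count = stats::rpois(nrow(genes), genes$level * (genes$end - genes$start) / 2000),
    length_bp = genes$end - genes$start,
    stringsAsFactors = FALSE
  )

  structure(
    list(
      config = config, seed = seed, layout = layout,
      rt_domains = rt_domains, genes = genes, origins = origins,
      rloops = rloops, g4s = g4s, sites = sites, rfd = rfd,
      expression = expression
    ),
    class = "synthetic_truth"
  )
}

synth_rt_domains <- function(layout, domain_length) {
  labels <- c("early", "mid", "late")
  rows <- list()
  for (chrom in layout$chrom_names) {
    len <- layout$chrom_lengths[[chrom]]
    starts <- seq(0, len - 1, by = domain_length)
    rows[[chrom]] <- data.frame(
      chrom = chrom, start = starts, end = pmin(starts + domain_length, len),
      name = labels[(seq_along(starts) - 1) %% 3 + 1],
      score = NA_real_, strand = ".",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "kind") <- "rt_domain"
  out
}

synth_genes <- function(layout, config) {
  rows <- list()
  for (chrom in layout$chrom_names) {
    len <- layout$chrom_lengths[[chrom]]
    pos <- 0
    starts <- numeric(0); ends <- numeric(0)
    repeat {
      gap <- stats::runif(1, config$gene_gap_min, config$gene_gap_max)
      size <- min(max(stats::rlnorm(1, config$gene_size_meanlog, config$gene_size_sdlog), 5e3), 2e6)
      if (pos + gap + size > len) break
      starts <- c(starts, round(pos + gap))
      ends <- c(ends, round(pos + gap + size))
      pos <- pos + gap + size
    }
    rows[[chrom]] <- data.frame(
      chrom = chrom, start = starts, end = ends,
      name = NA_character_, score = NA_real_,
      strand = sample(c("+", "-"), length(starts), replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# one long gene per late domain (the aphidicolin-like substrate: CFS-style
# long, late-replicating genes)
synth_long_late_genes <- function(layout, rt_domains, config) {
  late <- rt_domains[rt_domains$name == "late", , drop = FALSE]
  if (nrow(late) == 0L) return(late[0, c("chrom", "start", "end", "name", "score", "strand")])
  size <- round(stats::runif(nrow(late), 3e5, 6e5))
  center <- floor((late$start + late$end) / 2)
  data.frame(
    chrom = late$chrom,
    start = pmax(center - size %/% 2, 0),
    end = pmin(center + size %/% 2, layout$chrom_lengths[late$chrom]),
    name = NA_character_, score = NA_real_,
    strand = sample(c("+", "-"), nrow(late), replace = TRUE),
    stringsAsFactors = FALSE
  )
}

synth_origins <- function(rt_domains, spacing, layout) {
  early <- rt_domains[rt_domains$name == "early", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(early))) {
    centers <- seq(early$start[i] + spacing / 2, early$end[i], by = spacing)
    centers <- centers + round(stats::runif(length(centers), -5e4, 5e4))
    centers <- pmin(pmax(centers, early$start[i] + 1e3), early$end[i] - 2e3)
    rows[[i]] <- data.frame(
      chrom = early$chrom[i], start = round(centers) - 500,
      end = round(centers) + 500,
      name = NA_character_, score = NA_real_, strand = ".",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- sprintf("origin_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  attr(out, "kind") <- "origin"
  out
}

plant_sites <- function(genes, rt_domains, origins, layout, config,
                        n_brca, n_aph) {
  bs <- config$bin_size
  timing_of <- function(df) assign_replication_timing(
    data.frame(
      chrom = df$chrom,
      anchor = floor((df$start + df$end) / 2),
      start = df$start, end = df$end
    ),
    rt_domains
  )
  gene_timing <- timing_of(genes)
  min_sep_bins <- 150
  greedy_pick <- function(cand, k, taken) {
    chosen <- integer(0)
    for (g in cand) {
      ab <- bin_index(floor((genes$start[g] + genes$end[g]) / 2), bs)
      near_edge <- ab < min_sep_bins ||
        ab > layout$n_bins[[genes$chrom[g]]] - min_sep_bins
      if (near_edge) next
      clash <- FALSE
      for (h in c(chosen, taken)) {
        if (genes$chrom[h] == genes$chrom[g]) {
          hb <- bin_index(floor((genes$start[h] + genes$end[h]) / 2), bs)
          if (abs(hb - ab) < min_sep_bins) { clash <- TRUE; break }
        }
      }
      if (!clash) chosen <- c(chosen, g)
      if (length(chosen) == k) break
    }
    chosen
  }
  pick_hosts <- function(candidates, k, taken) {
    # randomized greedy selection enforcing a minimum anchor separation;
    # a random visiting order can strand itself, so retry a few shuffles
    best <- integer(0)
    for (attempt in 1:20) {
      chosen <- greedy_pick(candidates[sample.int(length(candidates))], k, taken)
      if (length(chosen) > length(best)) best <- chosen
      if (length(best) == k) return(best)
    }
    # first-fit in position order packs the maximum number of hosts on a
    # line, at the cost of left-biased placement
    ord <- candidates[order(genes$chrom[candidates], genes$start[candidates])]
    chosen <- greedy_pick(ord, k, taken)
    if (length(chosen) >= k) return(chosen)
    if (length(chosen) < length(best)) chosen <- best
    stop(sprintf(
      "generation error: cannot place %d sites with %d-bin separation (found %d hosts)",
      k, min_sep_bins, length(chosen)
    ))
  }

  brca_cand <- which(gene_timing == "early" &
    (genes$end - genes$start) >= 2e4 & (genes$end - genes$start) <= 3e5)
  long <- genes$end - genes$start >= 2.5e5
  aph_cand <- which(gene_timing == "late" & long)
  hosts_brca <- if (n_brca > 0) pick_hosts(brca_cand, n_brca, integer(0)) else integer(0)
  hosts_aph <- if (n_aph > 0) pick_hosts(aph_cand, n_aph, hosts_brca) else integer(0)

  # BRCA2-like hosts become highly transcribed (top of the expression range)
  if (length(hosts_brca) > 0L) {
    top <- max(genes$level)
    genes$level[hosts_brca] <- top * stats::runif(length(hosts_brca), 1.5, 3)
  }

  hosts <- c(hosts_brca, hosts_aph)
  scenario <- c(rep("brca2_like", n_brca), rep("aph_like", n_aph))
  n <- length(hosts)
  dbl <- rep(FALSE, n)
  n_dbl <- round(config$double_peak_fraction * n)
  if (n_dbl > 0) dbl[sample.int(n, n_dbl)] <- TRUE

  rows <- list()
  for (i in seq_len(n)) {
    g <- hosts[i]
    chrom <- genes$chrom[g]
    anchor_bin <- bin_index(floor((genes$start[g] + genes$end[g]) / 2), bs)
    bumps <- anchor_bin
    if (dbl[i]) {
      d <- sample(20:60, 1)
      b2 <- anchor_bin + d
      if (b2 >= layout$n_bins[[chrom]] - 3) b2 <- anchor_bin - d
      bumps <- c(bumps, b2)
    }
    rows[[i]] <- data.frame(
      site_id = sprintf("truth_%03d", i),
      scenario = scenario[i],
      chrom = chrom,
      gene_id = g,
      anchor_bin = anchor_bin,
      anchor = bin_midpoint(anchor_bin, layout, chrom),
      bumps = paste(sort(bumps), collapse = ","),
      shape = if (dbl[i]) "multiple" else "single",
      start = (min(bumps) - 3) * bs,
      end = (max(bumps) + 4) * bs,
      stringsAsFactors = FALSE
    )
  }
  sites <- if (n > 0) do.call(rbind, rows) else data.frame(
    site_id = character(0), scenario = character(0), chrom = character(0),
    gene_id = integer(0), anchor_bin = numeric(0), anchor = numeric(0),
    bumps = character(0), shape = character(0), start = numeric(0),
    end = numeric(0), stringsAsFactors = FALSE
  )

  # guarantee an origin within 100 kb of every BRCA2-like anchor
  if (n_brca > 0) {
    for (i in seq_len(n_brca)) {
      a <- sites$anchor[i]
      chrom <- sites$chrom[i]
      oc <- origins[origins$chrom == chrom, , drop = FALSE]
      d <- if (nrow(oc) > 0) {
        min(pmax(pmax(oc$start - a, 0), pmax(a - oc$end + 1, 0)))
      } else {
        Inf
      }
      if (d > 1e5) {
        origins <- rbind(origins, data.frame(
          chrom = chrom, start = a + 6e4 - 500, end = a + 6e4 + 500,
          name = sprintf("origin_x%03d", i), score = NA_real_, strand = ".",
          stringsAsFactors = FALSE
        ))
      }
    }
    origins <- origins[order(origins$chrom, origins$start), , drop = FALSE]
    rownames(origins) <- NULL
  }
  sites$gene <- genes$name[sites$gene_id]
  sites$gene_strand <- genes$strand[sites$gene_id]
  list(sites = sites, genes = genes, origins = origins)
}

synth_rloops <- function(genes, sites, config) {
  # the most highly transcribed genes host R-loop peaks
  k <- max(1L, round(config$rloop_top_fraction * nrow(genes)))
  top <- order(genes$level, decreasing = TRUE)[seq_len(k)]
  hosts <- union(top, sites$gene_id[sites$scenario == "brca2_like"])
  center <- floor((genes$start[hosts] + genes$end[hosts]) / 2)
  out <- data.frame(
    chrom = genes$chrom[hosts],
    start = pmax(center - 5e3, genes$start[hosts]),
    end = pmin(center + 5e3, genes$end[hosts]),
    name = paste0("rloop_", genes$name[hosts]),
    score = NA_real_, strand = ".",
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kind") <- "rloop"
  out
}

synth_g4s <- function(layout, sites, background_per_kb = 0.02,
                      extra_per_site = 25) {
  rows <- list()
  for (chrom in layout$chrom_names) {
    len <- layout$chrom_lengths[[chrom]]
    n_bg <- round(len / 1000 * background_per_kb)
    pos <- round(stats::runif(n_bg, 0, len - 31))
    rows[[chrom]] <- data.frame(
      chrom = chrom, start = pos, end = pos + 30,
      stringsAsFactors = FALSE
    )
  }
  brca <- sites[sites$scenario == "brca2_like", , drop = FALSE]
  for (i in seq_len(nrow(brca))) {
    len <- layout$chrom_lengths[[brca$chrom[i]]]
    pos <- round(stats::runif(extra_per_site, brca$anchor[i] - 5.4e4, brca$anchor[i] + 5.4e4))
    pos <- pmin(pmax(pos, 0), len - 31)
    rows[[length(rows) + 1]] <- data.frame(
      chrom = brca$chrom[i], start = pos, end = pos + 30,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$name <- "."; out$score <- NA_real_; out$strand <- "."
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kind") <- "g4"
  out
}

# analytic sawtooth fork directionality: +1 just right of each origin,
# decreasing linearly to -1 just left of the next; -1 left of the first
# origin and +1 right of the last
synth_rfd <- function(origins, layout) {
  values <- list()
  for (chrom in layout$chrom_names) {
    nb <- layout$n_bins[[chrom]]
    b <- 0:(nb - 1)
    x <- vapply(b, function(bb) bin_midpoint(bb, layout, chrom), numeric(1))
    oc <- origins[origins$chrom == chrom, , drop = FALSE]
    if (nrow(oc) == 0L) {
      values[[chrom]] <- rep(NA_real_, nb)
      next
    }
    o <- sort(floor((oc$start + oc$end) / 2))
    v <- numeric(nb)
    v[x < o[1]] <- -1
    v[x >= o[length(o)]] <- 1
    if (length(o) > 1L) {
      seg <- findInterval(x, o)
      mid <- seg >= 1 & seg < length(o)
      oi <- o[seg[mid]]
      oj <- o[seg[mid] + 1]
      v[mid] <- 1 - 2 * (x[mid] - oi) / (oj - oi)
    }
    values[[chrom]] <- pmin(pmax(v, -1), 1)
  }
  bin_track(layout, values, kind = "rfd")
}

#' Simulate a raw-count track from a synthetic truth
#'
#' Background bins are Poisson with mean `background_lambda` (negative
#' binomial when `dispersion` is finite). Each planted bump adds a
#' Gaussian-shaped elevation so that the bump's center bin has mean
#' `enrichment_fold * background_lambda`; double-peak sites carry two bumps.
#'
#' @param truth a `synthetic_truth` from [generate_world()].
#' @param seed integer seed (independent of the world seed, so count noise
#'   can be redrawn without moving the planted structure).
#' @return A `bin_track` of kind `"raw_count"`.
#' @export
simulate_bin_counts <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  config <- truth$config
  set.seed(seed)
  layout <- truth$layout
  lambda <- config$background_lambda
  w <- config$peak_width_bins
  values <- list()
  for (chrom in layout$chrom_names) {
    nb <- layout$n_bins[[chrom]]
    mu <- rep(lambda, nb)
    s <- truth$sites[truth$sites$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(s))) {
      bumps <- as.numeric(strsplit(s$bumps[i], ",", fixed = TRUE)[[1]])
      for (b in bumps) {
        idx <- max(b - 10, 0):min(b + 10, nb - 1)
        mu[idx + 1] <- mu[idx + 1] +
          (config$enrichment_fold - 1) * lambda * exp(-(idx - b)^2 / (2 * w^2))
      }
    }
    values[[chrom]] <- if (is.finite(config$dispersion)) {
      stats::rnbinom(nb, mu = mu, size = config$dispersion)
    } else {
      stats::rpois(nb, mu)
    }
  }
  bin_track(layout, values, kind = "raw_count")
}

#' Simulate a tumor rearrangement catalog
#'
#' Two cohorts of `n_tumors_per_cohort` tumors each. For every tumor, each
#' planted BRCA2-like site receives a breakpoint uniformly within +/- 200 kb
#' of its anchor with per-tumor probability `sv_rate_near_sites` (mutated
#' cohort) or `sv_rate_background` (wild-type cohort); `n_background_svs`
#' rearrangements per tumor are placed uniformly genome-wide.
#'
#' @param truth a `synthetic_truth`.
#' @param seed integer seed.
#' @return A list: `records` (data frame `sample_id`, `cohort`, `chrom1`,
#'   `pos1`, `chrom2`, `pos2`, `type`) and `cohort_sizes` (named vector).
#' @export
simulate_sv_catalog <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  config <- truth$config
  set.seed(seed)
  layout <- truth$layout
  brca <- truth$sites[truth$sites$scenario == "brca2_like", , drop = FALSE]
  cohorts <- c("BRCA2-mutated" = config$sv_rate_near_sites,
               "BRCA2-wild-type" = config$sv_rate_background)
  nt <- config$n_tumors_per_cohort
  rows <- list()
  for (ci in seq_along(cohorts)) {
    cohort <- names(cohorts)[ci]
    rate <- cohorts[[ci]]
    for (t in seq_len(nt)) {
      sid <- sprintf("%s_%03d", if (ci == 1) "MUT" else "WT", t)
      for (i in seq_len(nrow(brca))) {
        if (stats::runif(1) < rate) {
          len <- layout$chrom_lengths[[brca$chrom[i]]]
          p1 <- round(stats::runif(1, max(brca$anchor[i] - 2e5, 0),
                                   min(brca$anchor[i] + 2e5, len) - 1))
          p2 <- min(p1 + 1e6, len - 1)
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = sid, cohort = cohort,
            chrom1 = brca$chrom[i], pos1 = p1,
            chrom2 = brca$chrom[i], pos2 = p2,
            type = "DEL", stringsAsFactors = FALSE
          )
        }
      }
      for (k in seq_len(config$n_background_svs)) {
        chrom <- sample(layout$chrom_names, 1)
        len <- layout$chrom_lengths[[chrom]]
        p1 <- round(stats::runif(1, 0, len - 2))
        p2 <- round(stats::runif(1, 0, len - 2))
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, cohort = cohort,
          chrom1 = chrom, pos1 = p1, chrom2 = chrom, pos2 = p2,
          type = "BG", stringsAsFactors = FALSE
        )
      }
    }
  }
  records <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    data.frame(
      sample_id = character(0), cohort = character(0),
      chrom1 = character(0), pos1 = numeric(0),
      chrom2 = character(0), pos2 = numeric(0), type = character(0),
      stringsAsFactors = FALSE
    )
  }
  list(
    records = records,
    cohort_sizes = c("BRCA2-mutated" = nt, "BRCA2-wild-type" = nt)
  )
}

#' Synthetic stand-in MiDAS site tables with a planted Venn geometry
#'
#' Builds two synthetic condition-specific site tables (by default 150
#' BRCA2-depleted-like and 346 aphidicolin-like sites, of which exactly
#' `n_common` pairs share anchors within `window`) on an hg19-like layout of
#' 23 chromosomes. The tables are synthetic stand-ins for deposited
#' supplementary site lists: all anchors except the planted common pairs are
#' kept at least `2 * window` apart so the pairwise matching structure is
#' known exactly by construction.
#'
#' @param n_a,n_b site counts per condition (defaults 150 and 346).
#' @param n_common planted matched pairs (default 10).
#' @param window matching window in bp (default 600,000).
#' @param seed integer seed.
#' @return A list: `brca2`, `aph` (interval data frames, anchors at interval
#'   midpoints), `n_common`, and `layout`.
#' @export
simulate_site_tables <- function(n_a = 150, n_b = 346, n_common = 10,
                                 window = 600000, seed = 1) {
  if (n_common > min(n_a, n_b)) stop("n_common cannot exceed either set size")
  set.seed(seed)
  lengths <- round(seq(2.4e8, 6e7, length.out = 23))
  layout <- genome_layout(paste0("chr", 1:23), lengths, bin_size = 10000)
  spacing <- 2 * window + 3e5
  slots <- list()
  for (chrom in layout$chrom_names) {
    pos <- seq(1e6, layout$chrom_lengths[[chrom]] - 1e6, by = spacing)
    slots[[chrom]] <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  }
  slots <- do.call(rbind, slots)
  need <- n_a + n_b - n_common
  if (nrow(slots) < need) stop("layout too small for the requested site counts")
  pick <- slots[sample.int(nrow(slots), need), , drop = FALSE]
  # jitter keeps non-paired anchors > window apart: spacing - 2*jitter - drift
  pick$pos <- pick$pos + round(stats::runif(need, -5e4, 5e4))
  a_anchor <- pick[seq_len(n_a), , drop = FALSE]
  b_only <- pick[(n_a + 1):need, , drop = FALSE]
  common <- a_anchor[seq_len(n_common), , drop = FALSE]
  common$pos <- common$pos + round(stats::runif(n_common, -(window - 1e4), window - 1e4))
  b_anchor <- rbind(common, b_only)
  mk <- function(df, prefix) {
    out <- data.frame(
      chrom = df$chrom, start = df$pos - 5e3, end = df$pos + 5e3,
      name = sprintf("%s_%03d", prefix, seq_len(nrow(df))),
      score = round(stats::runif(nrow(df), 3, 30), 2), strand = ".",
      stringsAsFactors = FALSE
    )
    out <- out[order(match(out$chrom, layout$chrom_names), out$start), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "kind") <- "site"
    out
  }
  list(
    brca2 = mk(a_anchor, "mB"), aph = mk(b_anchor, "mA"),
    n_common = n_common, layout = layout
  )
}

#' Write a synthetic world to a directory of pipeline-ready files
#'
#' Emits the formats the pipeline reads: `genome.tsv`, `counts.bedgraph`,
#' `genes.bed`, `rt_domains.bed`, `origins.bed`, `rloops.bed`, `g4s.bed`,
#' `rfd.bedgraph`, `expression.tsv`, `svs.tsv` and `truth.json`.
#'
#' @param truth a `synthetic_truth`.
#' @param dir output directory (created if missing).
#' @param counts optional `bin_track` from [simulate_bin_counts()].
#' @param svs optional catalog from [simulate_sv_catalog()].
#' @return `dir`, invisibly.
#' @export
write_world <- function(truth, dir, counts = NULL, svs = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_genome_layout(truth$layout, p("genome.tsv"))
  genes_bed <- truth$genes
  genes_bed$score <- round(genes_bed$level, 3)
  write_intervals(genes_bed[, c("chrom", "start", "end", "name", "score", "strand")],
                  p("genes.bed"))
  write_intervals(truth$rt_domains, p("rt_domains.bed"))
  write_intervals(truth$origins, p("origins.bed"))
  write_intervals(truth$rloops, p("rloops.bed"))
  write_intervals(truth$g4s, p("g4s.bed"))
  write_track(truth$rfd, p("rfd.bedgraph"))
  utils::write.table(truth$expression, p("expression.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(counts)) write_track(counts, p("counts.bedgraph"))
  if (!is.null(svs)) {
    utils::write.table(svs$records, p("svs.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    writeLines(jsonlite::toJSON(as.list(svs$cohort_sizes), auto_unbox = TRUE),
               p("cohort_sizes.json"))
  }
  truth_json <- list(
    seed = truth$seed,
    config = unclass(truth$config),
    sites = truth$sites
  )
  writeLines(
    jsonlite::toJSON(truth_json, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     na = "null"),
    p("truth.json")
  )
  invisible(dir)
}
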
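# Independent brute-force oracles. Deliberately naive: plain loops over the
# definitions, sharing no code path with the package implementations.

# sigma by direct evaluation of the normalization formula
oracle_sigma <- function(counts, estimator = "robust", center = TRUE) {
  incl <- counts > 0
  m <- mean(counts[incl])
  n <- counts / m
  if (estimator == "plain") {
    mu <- mean(n[incl]); s <- sd(n[incl])
  } else {
    mu <- median(n[incl]); s <- mad(n[incl])
  }
  if (!center) mu <- 0
  (n - mu) / s
}

# exhaustive scan peak caller: runs, merging, strict plateau-leftmost maxima
oracle_call_sites <- function(v, threshold = 3, min_run = 2, merge_gap = 2) {
  n <- length(v)
  above <- !is.na(v) & v >= threshold
  # candidate runs
  runs <- list()
  i <- 1
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run) runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(runs) == 0) return(list())
  # merge runs separated by <= merge_gap sub-threshold bins
  regions <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- regions[[length(regions)]]
    if (r[1] - last[2] - 1 <= merge_gap) {
      regions[[length(regions)]] <- c(last[1], r[2])
    } else {
      regions[[length(regions) + 1]] <- r
    }
  }
  # peaks: above-threshold bins strictly greater than both plateau flanks
  lapply(regions, function(reg) {
    peaks <- integer(0)
    i <- reg[1]
    while (i <= reg[2]) {
      j <- i
      while (j < reg[2] && !is.na(v[j + 1]) && !is.na(v[i]) && v[j + 1] == v[i]) j <- j + 1
      vi <- if (is.na(v[i])) -Inf else v[i]
      lv <- if (i - 1 >= 1 && !is.na(v[i - 1])) v[i - 1] else -Inf
      rv <- if (j + 1 <= n && !is.na(v[j + 1])) v[j + 1] else -Inf
      if (is.finite(vi) && vi >= threshold && vi > lv && vi > rv) {
        peaks <- c(peaks, i)
      }
      i <- j + 1
    }
    if (length(peaks) == 0) {
      idx <- reg[1]:reg[2]
      ok <- idx[!is.na(v[idx]) & v[idx] >= threshold]
      if (length(ok) > 0) peaks <- ok[which.max(v[ok])]
    }
    list(first = reg[1] - 1, last = reg[2] - 1, peaks = peaks - 1) # 0-based
  })
}

# all-pairs anchor matching
oracle_overlap <- function(anchors_a, chrom_a, anchors_b, chrom_b, window) {
  a_matched <- rep(FALSE, length(anchors_a))
  b_matched <- rep(FALSE, length(anchors_b))
  for (i in seq_along(anchors_a)) {
    for (j in seq_along(anchors_b)) {
      if (chrom_a[i] == chrom_b[j] && abs(anchors_a[i] - anchors_b[j]) <= window) {
        a_matched[i] <- TRUE
        b_matched[j] <- TRUE
      }
    }
  }
  list(n_a = sum(a_matched), n_b = sum(b_matched))
}

# half-open intersection of [s1, e1) and [s2, e2)
intersects <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

# number of intervals intersecting [center - w, center + w)
oracle_count_in_window <- function(center, w, chrom, iv) {
  n <- 0L
  for (j in seq_len(nrow(iv))) {
    if (iv$chrom[j] == chrom && intersects(center - w, center + w, iv$start[j], iv$end[j])) {
      n <- n + 1L
    }
  }
  n
}

# minimum edge-to-edge distance between [s, e) and intervals on the chromosome
oracle_nearest <- function(s, e, chrom, iv) {
  best <- Inf
  for (j in seq_len(nrow(iv))) {
    if (iv$chrom[j] != chrom) next
    d <- if (intersects(s, e, iv$start[j], iv$end[j])) 0 else {
      max(iv$start[j] - e, s - iv$end[j])
    }
    best <- min(best, d)
  }
  if (is.infinite(best)) NA_real_ else best
}

# nested-loop per-site, per-cohort tumor counting
oracle_sv_frequency <- function(sites, records, cohort_sizes, window) {
  anchors <- if ("anchor" %in% names(sites)) sites$anchor else floor((sites$start + sites$end) / 2)
  out <- list()
  for (i in seq_len(nrow(sites))) {
    for (cohort in names(cohort_sizes)) {
      hits <- character(0)
      for (r in seq_len(nrow(records))) {
        if (records$cohort[r] != cohort) next
        ok1 <- records$chrom1[r] == sites$chrom[i] &&
          records$pos1[r] >= anchors[i] - window &&
          records$pos1[r] < anchors[i] + window
        ok2 <- records$chrom2[r] == sites$chrom[i] &&
          records$pos2[r] >= anchors[i] - window &&
          records$pos2[r] < anchors[i] + window
        if (ok1 || ok2) hits <- c(hits, records$sample_id[r])
      }
      out[[length(out) + 1]] <- data.frame(
        site = i, cohort = cohort,
        pct = length(unique(hits)) / cohort_sizes[[cohort]] * 100
      )
    }
  }
  do.call(rbind, out)
}

# random interval fixture on a given layout
random_intervals <- function(n, layout, max_width = 5e4) {
  chrom <- sample(layout$chrom_names, n, replace = TRUE)
  len <- layout$chrom_lengths[chrom]
  start <- floor(runif(n, 0, len - max_width - 1))
  width <- ceiling(runif(n, 1, max_width))
  df <- data.frame(
    chrom = chrom, start = start, end = start + width,
    name = sprintf("iv_%04d", seq_len(n)),
    score = NA_real_, strand = sample(c("+", "-", "."), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  df[order(df$chrom, df$start), ]
}

# random site-like table (anchors at interval midpoints)
random_sites <- function(n, layout, margin = 2e5) {
  chrom <- sample(layout$chrom_names, n, replace = TRUE)
  len <- layout$chrom_lengths[chrom]
  anchor <- floor(runif(n, margin, len - margin))
  data.frame(
    site_id = sprintf("s_%03d", seq_len(n)),
    chrom = chrom, start = anchor - 5e3, end = anchor + 5e3, anchor = anchor,
    stringsAsFactors = FALSE
  )
}

# sigma track wrapper around a plain vector on a one-chromosome layout
sigma_track_from_vector <- function(v, bin_size = 1e4) {
  layout <- genome_layout("chr1", length(v) * bin_size, bin_size = bin_size)
  tr <- bin_track(layout, list(chr1 = v), kind = "sigma")
  tr
}
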
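test_that("world generation is deterministic in (config, seed)", {
  w1 <- generate_world(small_config(), seed = 5)
  w2 <- generate_world(small_config(), seed = 5)
  expect_identical(w1$genes, w2$genes)
  expect_identical(w1$sites, w2$sites)
  expect_identical(w1$rfd$values, w2$rfd$values)
  expect_identical(w1$origins, w2$origins)
  w3 <- generate_world(small_config(), seed = 6)
  expect_false(identical(w1$sites$anchor, w3$sites$anchor))
})

test_that("replication-timing domains tile each chromosome and cycle labels", {
  w <- small_world()
  for (chrom in w$layout$chrom_names) {
    d <- w$rt_domains[w$rt_domains$chrom == chrom, ]
    expect_equal(d$start[1], 0)
    expect_equal(d$end[nrow(d)], unname(w$layout$chrom_lengths[chrom]))
    expect_equal(d$start[-1], d$end[-nrow(d)]) # gapless, non-overlapping
    expect_equal(d$name, rep_len(c("early", "mid", "late"), nrow(d)))
  }
})

test_that("origins lie inside early domains and RFD is an origin sawtooth", {
  w <- small_world()
  early <- w$rt_domains[w$rt_domains$name == "early", ]
  centers <- floor((w$origins$start + w$origins$end) / 2)
  inside <- vapply(seq_along(centers), function(i) {
    any(early$chrom == w$origins$chrom[i] &
          early$start <= centers[i] & centers[i] < early$end)
  }, logical(1))
  expect_true(all(inside))
  v <- w$rfd$values$chr1
  expect_true(all(abs(v) <= 1, na.rm = TRUE))
  oc <- sort(centers[w$origins$chrom == "chr1"])
  bs <- w$layout$bin_size
  # forks diverge around origins that are well separated from their
  # neighbors (tightly spaced origin pairs trade fork polarity in between):
  # positive just right, negative just left, -1 before the first origin and
  # +1 after the last
  gaps <- diff(oc)
  isolated <- which(c(Inf, gaps) >= 1e5 & c(gaps, Inf) >= 1e5)
  expect_gt(length(isolated), 0)
  for (o in oc[isolated]) {
    b <- midasmap:::bin_index(o, bs)
    if (b + 3 <= length(v)) expect_gt(v[b + 3], 0)
    if (b - 1 >= 1) expect_lt(v[b - 1], 0)
  }
  expect_equal(v[1], -1)
  expect_equal(v[length(v)], 1)
})

test_that("planted sites sit in transcribed, R-loop-marked, origin-proximal genes", {
  w <- small_world()
  sites <- w$sites
  expect_equal(nrow(sites), 5)
  expect_true(all(sites$scenario == "brca2_like"))
  # anchors fall in early domains
  expect_true(all(assign_replication_timing(sites, w$rt_domains) == "early"))
  # each host gene carries an R-loop peak within the +/- 50 kb anchor window
  rf <- rloop_overlap_fraction(sites, w$rloops, window = 5e4)
  expect_equal(rf$fraction, 1)
  # an origin lies within 100 kb of every anchor
  d <- nearest_origin_distance(sites, w$origins, bin_size = w$layout$bin_size)
  expect_true(all(d <= 1e5))
  # host genes are among the most highly expressed
  host_levels <- w$genes$level[sites$gene_id]
  expect_true(all(host_levels >= quantile(w$genes$level, 0.75)))
  # anchors are pairwise separated by at least 150 bins
  bs <- w$layout$bin_size
  ab <- sort(midasmap:::bin_index(sites$anchor, bs))
  expect_true(all(diff(ab) >= 150))
})

test_that("aphidicolin-like sites land in long late-replicating genes", {
  cfg <- synthetic_config(n_chroms = 2, chrom_length = 4e7,
                          n_planted_sites = 6, aph_fraction = 0.5)
  w <- generate_world(cfg, seed = 21)
  aph <- w$sites[w$sites$scenario == "aph_like", ]
  expect_equal(nrow(aph), 3)
  expect_true(all(assign_replication_timing(aph, w$rt_domains) == "late"))
  host_len <- w$genes$end[aph$gene_id] - w$genes$start[aph$gene_id]
  expect_true(all(host_len >= 2.5e5))
})

test_that("count noise is independent of the world and redrawable by seed", {
  w <- small_world()
  c1 <- simulate_bin_counts(w, seed = 31)
  c2 <- simulate_bin_counts(w, seed = 31)
  expect_identical(c1$values, c2$values)
  c3 <- simulate_bin_counts(w, seed = 32)
  expect_false(identical(c1$values, c3$values))
  # interleaving other draws must not perturb a seeded simulation
  runif(1000)
  c4 <- simulate_bin_counts(w, seed = 31)
  expect_identical(c1$values, c4$values)
})

test_that("planted bumps raise the local count mean to the configured fold", {
  w <- small_world()
  counts <- simulate_bin_counts(w, seed = 33)
  v <- counts$values$chr1
  lambda <- w$config$background_lambda
  bumps <- as.numeric(unlist(strsplit(w$sites$bumps, ",")))
  far <- setdiff(seq_along(v), unlist(lapply(bumps, function(b) (b - 10):(b + 12))))
  expect_lt(abs(mean(v[far]) - lambda), 1)
  at_bumps <- v[bumps + 1]
  # Poisson with mean fold * lambda = 400: all bump bins well above background
  expect_true(all(at_bumps > lambda * 4))
  expect_lt(abs(mean(at_bumps) - w$config$enrichment_fold * lambda),
            4 * sqrt(w$config$enrichment_fold * lambda / length(at_bumps)) + 10)
})

test_that("negative-binomial dispersion widens counts without moving the mean", {
  w <- small_world()
  cfg2 <- small_config(dispersion = 2)
  w2 <- w
  w2$config <- cfg2
  over <- simulate_bin_counts(w2, seed = 34)
  pois <- simulate_bin_counts(w, seed = 34)
  lambda <- w$config$background_lambda
  expect_lt(abs(mean(over$values$chr1) - lambda), 3)
  expect_gt(var(over$values$chr1), var(pois$values$chr1))
})

test_that("SV catalogs concentrate mutated-cohort breakpoints near planted sites", {
  w <- small_world()
  svs <- simulate_sv_catalog(w, seed = 41)
  expect_equal(unname(svs$cohort_sizes), c(100, 100))
  expect_setequal(names(svs$cohort_sizes), c("BRCA2-mutated", "BRCA2-wild-type"))
  r <- svs$records
  expect_true(all(r$cohort %in% names(svs$cohort_sizes)))
  planted <- r[r$type == "DEL", ]
  # every planted breakpoint is within 200 kb of some site anchor
  ok <- vapply(seq_len(nrow(planted)), function(i) {
    any(w$sites$chrom == planted$chrom1[i] &
          abs(w$sites$anchor - planted$pos1[i]) <= 2e5)
  }, logical(1))
  expect_true(all(ok))
  n_mut <- sum(planted$cohort == "BRCA2-mutated")
  n_wt <- sum(planted$cohort == "BRCA2-wild-type")
  expect_gt(n_mut, 3 * n_wt)
  # each tumor also carries its background rearrangements
  bg <- r[r$type == "BG", ]
  expect_equal(nrow(bg), 200 * w$config$n_background_svs)
})

test_that("stand-in site tables plant an exact matching geometry", {
  tabs <- simulate_site_tables(n_a = 40, n_b = 70, n_common = 7, seed = 13)
  expect_equal(nrow(tabs$brca2), 40)
  expect_equal(nrow(tabs$aph), 70)
  anchors <- function(x) floor((x$start + x$end) / 2)
  want <- oracle_overlap(anchors(tabs$brca2), tabs$brca2$chrom,
                         anchors(tabs$aph), tabs$aph$chrom, 6e5)
  expect_equal(want$n_a, 7)
  expect_equal(want$n_b, 7)
  expect_error(simulate_site_tables(n_a = 5, n_b = 5, n_common = 6), "cannot exceed")
})

test_that("a written world reloads into equivalent pipeline inputs", {
  w <- small_world()
  counts <- simulate_bin_counts(w, seed = 51)
  svs <- simulate_sv_catalog(w, seed = 52)
  dir <- tempfile("world")
  write_world(w, dir, counts = counts, svs = svs)
  layout <- read_genome_layout(file.path(dir, "genome.tsv"))
  expect_equal(layout$chrom_lengths, w$layout$chrom_lengths)
  genes <- read_intervals(file.path(dir, "genes.bed"), layout = layout)
  expect_equal(genes$start, w$genes$start)
  expect_equal(genes$strand, w$genes$strand)
  rfd <- read_track(file.path(dir, "rfd.bedgraph"), layout, kind = "rfd")
  expect_equal(rfd$values$chr1, w$rfd$values$chr1, tolerance = 1e-8)
  back_counts <- load_bin_track(file.path(dir, "counts.bedgraph"), layout)
  expect_equal(back_counts$values, counts$values)
  svs_back <- utils::read.delim(file.path(dir, "svs.tsv"))
  expect_equal(nrow(svs_back), nrow(svs$records))
  sizes <- unlist(jsonlite::read_json(file.path(dir, "cohort_sizes.json")))
  expect_equal(sizes[["BRCA2-mutated"]], 100)
})

test_that("generator configuration is validated", {
  expect_error(synthetic_config(background_lambda = 0), "positive")
  expect_error(synthetic_config(double_peak_fraction = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(n_planted_sites = -1), ">= 0")
  expect_error(
    generate_world(synthetic_config(n_chroms = 1, chrom_length = 2e6,
                                    n_planted_sites = 50), seed = 1),
    "generation error"
  )
})
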
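# builds a one-chromosome fixture with one gene per site and a constant RFD
# plateau around each anchor
orientation_fixture <- function(rfd_values, strands, spacing_bins = 60,
                                bin_size = 1e4) {
  n <- length(rfd_values)
  nb <- (n + 1) * spacing_bins
  layout <- genome_layout("chr1", nb * bin_size, bin_size = bin_size)
  anchors <- (seq_len(n) * spacing_bins) * bin_size + bin_size / 2
  v <- rep(0, nb)
  for (i in seq_len(n)) {
    b <- i * spacing_bins
    v[(b - 20):(b + 20) + 1] <- rfd_values[i]
  }
  genes <- data.frame(
    chrom = "chr1",
    start = anchors - 2e4, end = anchors + 2e4,
    name = sprintf("G%02d", seq_len(n)),
    score = NA_real_, strand = strands
  )
  sites <- data.frame(
    chrom = "chr1", start = anchors - 5e3, end = anchors + 5e3,
    anchor = anchors, site_id = sprintf("s%02d", seq_len(n))
  )
  list(
    layout = layout, genes = genes, sites = sites,
    rfd = bin_track(layout, list(chr1 = v), kind = "rfd")
  )
}

test_that("mean RFD over a fixed window recovers planted plateau values", {
  fx <- orientation_fixture(c(0.6, -0.4, 0.05), c("+", "+", "+"))
  got <- mean_rfd_over_site(fx$sites, fx$rfd, span = 15e4)
  expect_equal(got, c(0.6, -0.4, 0.05))
})

test_that("gene-body RFD averaging uses the gene extent, not the anchor window", {
  layout <- genome_layout("chr1", 1e6, bin_size = 1e4)
  v <- c(rep(0.8, 50), rep(-0.8, 50))
  rfd <- bin_track(layout, list(chr1 = v), kind = "rfd")
  sites <- data.frame(chrom = "chr1", start = 1e5, end = 1.1e5,
                      anchor = 1.05e5, site_id = "s1")
  gene <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  over_gene <- mean_rfd_over_site(sites, rfd, extent = "gene_body", genes = gene)
  expect_equal(over_gene, 0)
  over_window <- mean_rfd_over_site(sites, rfd, span = 15e4)
  expect_equal(over_window, 0.8)
})

test_that("missing RFD propagates as NA with a warning, all-missing is an error", {
  layout <- genome_layout("chr1", 1e6, bin_size = 1e4)
  v <- rep(NA_real_, 100)
  v[1:20] <- 0.5
  rfd <- bin_track(layout, list(chr1 = v), kind = "rfd")
  sites <- data.frame(
    chrom = "chr1", start = c(5e4, 8e5), end = c(6e4, 8.1e5),
    anchor = c(5.5e4, 8.05e5), site_id = c("s1", "s2")
  )
  expect_warning(got <- mean_rfd_over_site(sites, rfd), "no RFD data")
  expect_equal(got[1], 0.5)
  expect_true(is.na(got[2]))
  expect_error(
    mean_rfd_over_site(sites[2, ], rfd),
    "no RFD data over any site"
  )
})

test_that("orientation calls combine gene strand with fork direction", {
  fx <- orientation_fixture(
    rfd_values = c(0.5, 0.5, -0.5, -0.5, 0.02, 0.5),
    strands = c("+", "-", "+", "-", "+", "+")
  )
  # make the last site multi-gene so it is not applicable
  extra <- fx$genes[6, ]
  extra$name <- "G99"
  extra$start <- extra$start - 1e4
  genes <- rbind(fx$genes, extra)
  calls <- classify_orientation(fx$sites, genes, fx$rfd,
                                tau = 0.1, window = 5e4, span = 15e4)
  expect_equal(
    calls$call,
    c("co-directional", "head-on", "head-on", "co-directional",
      "ambiguous", "not_applicable")
  )
  expect_equal(calls$gene[1:5], sprintf("G%02d", 1:5))
  expect_equal(calls$mean_rfd[1:5], c(0.5, 0.5, -0.5, -0.5, 0.02))
  os <- orientation_summary(calls)
  expect_equal(os$n, 5L)
  expect_equal(os$fraction_codirectional, 2 / 5)
  expect_equal(os$fraction_head_on, 2 / 5)
  expect_equal(os$fraction_ambiguous, 1 / 5)
  expect_equal(
    os$fraction_codirectional + os$fraction_head_on + os$fraction_ambiguous, 1
  )
})

test_that("negating the fork-direction track swaps the orientation classes", {
  set.seed(101)
  r <- round(runif(12, -0.9, 0.9), 2)
  strands <- sample(c("+", "-"), 12, replace = TRUE)
  fx <- orientation_fixture(r, strands)
  neg <- bin_track(fx$layout, list(chr1 = -fx$rfd$values$chr1), kind = "rfd")
  a <- classify_orientation(fx$sites, fx$genes, fx$rfd)
  b <- classify_orientation(fx$sites, fx$genes, neg)
  swap <- c("co-directional" = "head-on", "head-on" = "co-directional",
            "ambiguous" = "ambiguous", "not_applicable" = "not_applicable")
  expect_equal(b$call, unname(swap[a$call]))
  expect_equal(b$mean_rfd, -a$mean_rfd)
})

test_that("SV frequency counts each tumor once per site using both breakpoint ends", {
  sites <- data.frame(
    chrom = "chr1", start = c(1e6, 9e6) - 5e3, end = c(1e6, 9e6) + 5e3,
    anchor = c(1e6, 9e6), site_id = c("s1", "s2")
  )
  records <- data.frame(
    sample_id = c("t1", "t1", "t2", "t3", "t4"),
    cohort = c("mut", "mut", "mut", "wt", "wt"),
    chrom1 = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    pos1 = c(1.1e6, 0.9e6, 5e6, 8.85e6, 1e6),
    chrom2 = c("chr1", "chr2", "chr1", "chr1", "chr2"),
    pos2 = c(2e6, 5e6, 1.19e6, 30e6, 2e6) # t2 reaches s1 via its second end
  )
  freq <- site_sv_frequency(sites, records, c(mut = 10, wt = 20), window = 2e5)
  get <- function(id, co) freq$n_tumors[freq$site_id == id & freq$cohort == co]
  expect_equal(get("s1", "mut"), 2L) # t1 counted once despite two hits
  expect_equal(get("s1", "wt"), 0L)
  expect_equal(get("s2", "wt"), 1L)
  expect_equal(get("s2", "mut"), 0L)
  pct <- function(id, co) freq$percentage[freq$site_id == id & freq$cohort == co]
  expect_equal(pct("s1", "mut"), 20)
  expect_equal(pct("s2", "wt"), 5)
  expect_error(
    site_sv_frequency(sites, records, c(mut = 10), window = 2e5),
    "cohort not in cohort_sizes"
  )
  expect_error(
    site_sv_frequency(sites, records, c(10, 20), window = 2e5),
    "named vector"
  )
})

test_that("SV frequency matches a nested-loop oracle on random catalogs", {
  layout <- genome_layout(c("chr1", "chr2"), rep(3e7, 2))
  set.seed(102)
  for (rep in 1:10) {
    sites <- random_sites(sample(3:12, 1), layout, margin = 5e5)
    nr <- sample(20:100, 1)
    records <- data.frame(
      sample_id = sprintf("t%02d", sample.int(30, nr, replace = TRUE)),
      cohort = sample(c("A", "B"), nr, replace = TRUE),
      chrom1 = sample(layout$chrom_names, nr, replace = TRUE),
      pos1 = round(runif(nr, 0, 3e7 - 1)),
      chrom2 = sample(layout$chrom_names, nr, replace = TRUE),
      pos2 = round(runif(nr, 0, 3e7 - 1))
    )
    sizes <- c(A = 30, B = 30)
    got <- site_sv_frequency(sites, records, sizes, window = 2e5)
    want <- oracle_sv_frequency(sites, records, sizes, window = 2e5)
    for (k in seq_len(nrow(want))) {
      g <- got$percentage[got$site_id == sites$site_id[want$site[k]] &
                            got$cohort == want$cohort[k]]
      expect_equal(g, want$pct[k])
    }
  }
})

test_that("cohort comparison returns group summaries and Tukey-adjusted contrasts", {
  set.seed(103)
  y <- c(rnorm(40, 30, 3), rnorm(40, 5, 3), rnorm(40, 5.5, 3))
  g <- rep(c("mutated", "wildtype", "control"), each = 40)
  res <- cohort_sv_comparison(y, g)
  expect_equal(sort(res$summary$group), sort(unique(g)))
  expect_equal(res$summary$n, rep(40L, 3))
  expect_equal(
    res$summary$mean[res$summary$group == "mutated"],
    mean(y[g == "mutated"])
  )
  expect_equal(nrow(res$tukey), 3)
  big <- res$tukey$p_adj[grepl("mutated", res$tukey$comparison)]
  expect_true(all(big < 1e-8))
  null <- res$tukey$p_adj[res$tukey$comparison == "wildtype-control"]
  expect_gt(null, 0.05)
  expect_error(cohort_sv_comparison(y, rep("one", 120)), "at least 2 groups")
  expect_error(cohort_sv_comparison(c(1, 2, 3), c("a", "a", "b")),
               "at least 2 sites")
})
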
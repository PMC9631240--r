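test_that("site-set matching is inclusive at the window edge and chromosome-aware", {
  a <- data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1e6, 5e6, 1e6) - 5e3,
    end = c(1e6, 5e6, 1e6) + 5e3,
    anchor = c(1e6, 5e6, 1e6)
  )
  b <- data.frame(
    chrom = c("chr1", "chr2", "chr2"),
    start = c(1e6 + 6e5, 1e6 + 6e5 + 1, 9e6) - 5e3,
    end = c(1e6 + 6e5, 1e6 + 6e5 + 1, 9e6) + 5e3,
    anchor = c(1e6 + 6e5, 1e6 + 6e5 + 1, 9e6)
  )
  ov <- overlap_site_sets(a, b, window = 6e5)
  # a1-b1 at exactly 600 kb matches; a3-b2 at 600,001 bp does not
  expect_equal(ov$n_a_matched, 1L)
  expect_equal(ov$n_b_matched, 1L)
  expect_equal(ov$pairs$a_idx, 1L)
  expect_equal(ov$pairs$distance, 6e5)
  # same positions, different chromosome: no match at any window
  ov0 <- overlap_site_sets(a[3, ], b[1, , drop = FALSE], window = 6e5)
  expect_equal(ov0$n_a_matched, 0L)
})

test_that("site-set matching agrees with all-pairs comparison on random catalogs", {
  layout <- genome_layout(c("chr1", "chr2", "chr3"), rep(3e7, 3))
  set.seed(81)
  for (rep in 1:20) {
    a <- random_sites(sample(5:30, 1), layout)
    b <- random_sites(sample(5:30, 1), layout)
    w <- sample(c(0, 1e4, 2e5, 6e5), 1)
    ov <- overlap_site_sets(a, b, window = w)
    want <- oracle_overlap(a$anchor, a$chrom, b$anchor, b$chrom, w)
    expect_equal(ov$n_a_matched, want$n_a)
    expect_equal(ov$n_b_matched, want$n_b)
  }
})

test_that("replication timing is taken from the domain containing the anchor", {
  domains <- data.frame(
    chrom = "chr1",
    start = c(0, 5e6, 1e7),
    end = c(5e6, 1e7, 1.5e7),
    name = c("early", "mid", "late")
  )
  sites <- data.frame(
    chrom = "chr1",
    start = c(1e6, 7e6, 1.2e7, 2e7) - 5e3,
    end = c(1e6, 7e6, 1.2e7, 2e7) + 5e3,
    anchor = c(1e6, 7e6, 1.2e7, 2e7)
  )
  expect_equal(
    assign_replication_timing(sites, domains),
    c("early", "mid", "late", "undefined")
  )
  bad <- rbind(domains, data.frame(chrom = "chr1", start = 4e6, end = 6e6, name = "early"))
  expect_error(assign_replication_timing(sites, bad), "overlapping")
})

test_that("genic classification uses a half-open +/- window around the anchor", {
  genes <- data.frame(
    chrom = "chr1",
    start = c(2e5, 1e6),
    end = c(3e5, 1.2e6),
    name = c("GENEA", "GENEB"),
    strand = c("+", "-")
  )
  sites <- data.frame(
    chrom = "chr1",
    start = c(3.4e5, 3.6e5, 5e6) - 5e3,
    end = c(3.4e5, 3.6e5, 5e6) + 5e3,
    anchor = c(3.4e5, 3.6e5, 5e6),
    site_id = c("s1", "s2", "s3")
  )
  cg <- classify_genic(sites, genes, window = 5e4)
  # [290000, 390000) touches GENEA's last base; [310000, 410000) does not
  expect_equal(cg$genic, c("genic", "intergenic", "intergenic"))
  expect_equal(cg$gene_count, c(1L, 0L, 0L))
  expect_equal(cg$genes, c("GENEA", "", ""))
  gd <- gene_density(sites, genes, window = 5e4)
  expect_equal(gd$counts, c(1L, 0L, 0L))
  expect_equal(as.integer(gd$histogram), c(2L, 1L))
})

test_that("nearest-origin distance is edge-to-edge from the anchor bin", {
  sites <- data.frame(
    chrom = "chr1", start = 0, end = 1e4, anchor = 5000, site_id = "s1"
  )
  origins <- data.frame(chrom = "chr1", start = 109000, end = 110000)
  # anchor bin [0, 10000); gap to origin start = 99,000 bp
  expect_equal(nearest_origin_distance(sites, origins, bin_size = 1e4), 99000)
  inside <- data.frame(chrom = "chr1", start = 9000, end = 9100)
  expect_equal(nearest_origin_distance(sites, inside, bin_size = 1e4), 0)
  elsewhere <- data.frame(chrom = "chr7", start = 109000, end = 110000)
  expect_true(is.na(nearest_origin_distance(sites, elsewhere, bin_size = 1e4)))
  expect_true(is.na(
    nearest_origin_distance(sites, origins, bin_size = 1e4, max_distance = 5e4)
  ))
})

test_that("fragile-site gene matching is case-insensitive after trimming", {
  res <- cfs_gene_overlap(
    site_genes = c("wwox", "FHIT ", "MYC", "WWOX"),
    cfs_genes = c("WWOX", "FHIT", "PARK2")
  )
  expect_equal(res$n_hit, 2L)
  expect_equal(res$n_total, 3L) # duplicates collapse
  expect_equal(res$fraction, 2 / 3)
  expect_error(cfs_gene_overlap(character(0), "WWOX"), "empty")
})

test_that("gene-size comparison reports medians and a rank-sum p-value", {
  set.seed(82)
  short <- data.frame(chrom = "chr1", start = 0, end = round(rlnorm(60, log(4e4), 0.3)))
  long <- data.frame(chrom = "chr1", start = 0, end = round(rlnorm(60, log(5e5), 0.3)))
  res <- summarize_gene_sizes(long, short)
  expect_equal(res$median_site, median(long$end))
  expect_equal(res$median_ref, median(short$end))
  expect_lt(res$p_value, 1e-6)
  expect_error(summarize_gene_sizes(short[0, ], short), "non-empty")
})

test_that("control regions satisfy every constraint and derive per-set seeds", {
  layout <- genome_layout("chr1", 2e7, bin_size = 1e4)
  domains <- data.frame(
    chrom = "chr1", start = c(0, 1e7), end = c(1e7, 2e7),
    name = c("early", "late")
  )
  rloops <- data.frame(
    chrom = "chr1",
    start = seq(1e5, 9.9e6, by = 2e5), end = seq(1e5, 9.9e6, by = 2e5) + 1e4
  )
  sites <- data.frame(
    chrom = "chr1", start = 4e6, end = 4.02e6, anchor = 4.01e6,
    site_id = "s1", peak_bins = "401"
  )
  sets <- sample_control_regions(
    domains, rloops, sites, layout,
    n = 40, n_sets = 4, exclusion_bins = 50, window = 5e4, seed = 9
  )
  expect_length(sets, 4)
  for (s in sets) {
    expect_equal(nrow(s), 40)
    expect_equal(anyDuplicated(s$bin), 0L) # without replacement
    # early-replicating centers only
    expect_true(all(s$center >= 0 & s$center < 1e7))
    # at least 50 bins from the peak bin
    expect_true(all(abs(s$bin - 401) >= 50))
    # a recorded R-loop within +/- 50 kb
    expect_true(all(s$rloop_count >= 1))
    # direct re-check of the R-loop constraint against the raw intervals
    for (ctr in s$center) {
      expect_true(any(rloops$start < ctr + 5e4 & rloops$end > ctr - 5e4))
    }
  }
  again <- sample_control_regions(
    domains, rloops, sites, layout,
    n = 40, n_sets = 4, exclusion_bins = 50, window = 5e4, seed = 9
  )
  expect_identical(sets, again)
  other <- sample_control_regions(
    domains, rloops, sites, layout,
    n = 40, n_sets = 4, exclusion_bins = 50, window = 5e4, seed = 10
  )
  expect_false(identical(sets[[1]]$bin, other[[1]]$bin))
  expect_error(
    sample_control_regions(domains, rloops, sites, layout,
                           n = 5000, n_sets = 1, seed = 9),
    "infeasible sampling"
  )
})

test_that("control-region sets serialize to a single BED with set labels", {
  layout <- genome_layout("chr1", 2e7, bin_size = 1e4)
  domains <- data.frame(chrom = "chr1", start = 0, end = 2e7, name = "early")
  rloops <- data.frame(chrom = "chr1", start = seq(0, 1.99e7, 1e5),
                       end = seq(0, 1.99e7, 1e5) + 1e4)
  sites <- data.frame(chrom = "chr1", start = 0, end = 1e4, anchor = 5e3,
                      site_id = "s1", peak_bins = "0")
  sets <- sample_control_regions(domains, rloops, sites, layout,
                                 n = 10, n_sets = 2, seed = 3)
  f <- tempfile(fileext = ".bed")
  write_control_regions(sets, f)
  back <- read_intervals(f)
  expect_equal(nrow(back), 20)
  expect_equal(sum(grepl("^set1_", back$name)), 10)
  expect_equal(sum(grepl("^set2_", back$name)), 10)
})
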
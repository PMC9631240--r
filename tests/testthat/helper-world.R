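# Shared fixtures. small_world() memoizes one synthetic genome so tests that
# only inspect structure do not regenerate it.

small_config <- function(...) {
  synthetic_config(
    n_chroms = 1, chrom_length = 3e7, n_planted_sites = 5,
    rt_domain_length = 5e6, ...
  )
}

.world_cache <- new.env(parent = emptyenv())

small_world <- function(seed = 11) {
  key <- paste0("w", seed)
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- generate_world(small_config(), seed = seed)
  }
  .world_cache[[key]]
}

# one-chromosome layout helper
layout1 <- function(n_bins, bin_size = 1e4) {
  genome_layout("chr1", n_bins * bin_size, bin_size = bin_size)
}
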
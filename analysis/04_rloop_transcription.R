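#!/usr/bin/env Rscript

# Stage 4: R-loops and transcription at the called sites.
#
# Measures R-loop coincidence (+/- 50 kb around anchors) and G-quadruplex
# density (110-kb windows), quantifies gene expression as TPM, compares
# site-associated gene expression against all other genes, and draws ten sets
# of matched control regions (early-replicating, R-loop-proximal,
# MiDAS-distal bins). Writes results/rloop_transcription.tsv,
# results/expression_tpm.tsv, results/control_regions.bed and
# results/rloop_summary.json.
#
# Run after: analysis/02_call_sites.R

suppressPackageStartupMessages({
  library(midasmap)
  library(jsonlite)
})

args <- commandArgs(trailingOnly = TRUE)
seed <- if ("--seed" %in% args) as.integer(args[match("--seed", args) + 1]) else 1L

layout <- read_genome_layout("data/world/genome.tsv")
sites <- utils::read.delim("results/sites.tsv")
rloops <- read_intervals("data/world/rloops.bed", kind = "rloop", layout = layout)
g4s <- read_intervals("data/world/g4s.bed", kind = "g4", layout = layout)
genes <- read_intervals("data/world/genes.bed", kind = "gene", layout = layout)
rt <- read_intervals("data/world/rt_domains.bed", kind = "rt_domain", layout = layout)
expr <- utils::read.delim("data/world/expression.tsv")

rf <- rloop_overlap_fraction(sites, rloops, window = 5e4)
g4 <- g4_density(sites, g4s, span = 110000)
per_site <- data.frame(
  site_id = sites$site_id,
  rloop_coincident = rf$coincident,
  g4_per_kb = g4
)
dir.create("results", showWarnings = FALSE)
utils::write.table(per_site, "results/rloop_transcription.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

tpm <- quantify_tpm(expr$count, expr$length_bp, gene_id = expr$gene_id)
utils::write.table(tpm, "results/expression_tpm.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cg <- classify_genic(sites, genes, window = 5e4)
site_gene_names <- unique(unlist(strsplit(cg$genes[cg$genes != ""], ",")))
host <- tpm$gene_id %in% site_gene_names
cmp <- compare_site_expression(tpm$log10_tpm1[host], tpm$log10_tpm1[!host])

controls <- sample_control_regions(
  rt, rloops, sites, layout, genes = genes,
  n = 150, n_sets = 10, exclusion_bins = 50, window = 5e4, seed = seed
)
write_control_regions(controls, "results/control_regions.bed")

summary <- list(
  fraction_rloop_coincident = rf$fraction,
  mean_g4_per_kb = mean(g4),
  tpm_total = sum(tpm$tpm),
  site_gene_log_tpm_mean = cmp$site_mean,
  other_gene_log_tpm_mean = cmp$control_mean,
  expression_p = cmp$p_value,
  n_control_sets = length(controls),
  n_control_regions = sum(vapply(controls, nrow, integer(1)))
)
writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE, digits = NA),
           "results/rloop_summary.json")
cat(sprintf(
  "%.0f%% of sites R-loop coincident; site genes log10(TPM+1) %.2f vs %.2f (p = %.2g)\n",
  100 * rf$fraction, cmp$site_mean, cmp$control_mean, cmp$p_value
))
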
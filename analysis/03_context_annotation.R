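#!/usr/bin/env Rscript

# Stage 3: genomic context of the called sites.
#
# Annotates each called site with its replication timing, genic status and
# local gene content (+/- 50 kb around the anchor), and its distance to the
# nearest replication origin; compares host-gene sizes against the genome-wide
# gene set. Writes results/annotation.tsv and results/context_summary.json.
#
# Run after: analysis/02_call_sites.R

suppressPackageStartupMessages({
  library(midasmap)
  library(jsonlite)
})

layout <- read_genome_layout("data/world/genome.tsv")
sites <- utils::read.delim("results/sites.tsv")
genes <- read_intervals("data/world/genes.bed", kind = "gene", layout = layout)
rt <- read_intervals("data/world/rt_domains.bed", kind = "rt_domain", layout = layout)
origins <- read_intervals("data/world/origins.bed", kind = "origin", layout = layout)

cg <- classify_genic(sites, genes, window = 5e4)
ann <- data.frame(
  site_id = sites$site_id,
  timing = assign_replication_timing(sites, rt),
  genic = cg$genic,
  gene_count = cg$gene_count,
  genes = cg$genes,
  nearest_origin_bp = nearest_origin_distance(sites, origins,
                                              bin_size = layout$bin_size)
)
dir.create("results", showWarnings = FALSE)
utils::write.table(ann, "results/annotation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

site_gene_names <- unique(unlist(strsplit(cg$genes[cg$genes != ""], ",")))
site_genes <- genes[genes$name %in% site_gene_names, ]
sizes <- summarize_gene_sizes(site_genes, genes)

summary <- list(
  n_sites = nrow(sites),
  fraction_genic = mean(ann$genic == "genic"),
  timing = as.list(table(ann$timing) / nrow(ann)),
  n_origin_assigned = sum(!is.na(ann$nearest_origin_bp)),
  median_origin_distance_bp = median(ann$nearest_origin_bp, na.rm = TRUE),
  median_site_gene_bp = sizes$median_site,
  median_genome_gene_bp = sizes$median_ref,
  gene_size_p = sizes$p_value
)
writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE, digits = NA),
           "results/context_summary.json")
cat(sprintf(
  "%d sites: %.0f%% genic, %.0f%% early; median origin distance %s bp\n",
  nrow(sites), 100 * summary$fraction_genic,
  100 * mean(ann$timing == "early"),
  format(summary$median_origin_distance_bp, big.mark = ",")
))
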
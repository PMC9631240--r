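#' Default analysis parameters
#'
#' Every window and threshold of the analysis in one place, overridable via
#' the `params` argument of [run_full_pipeline()]: sigma estimator and peak
#' calling (`threshold` 3 sigma, `min_run` 2 bins, `merge_gap` 2 bins), the
#' +/- 50 kb gene window, the +/- 600 kb site-matching window, the 110-kb G4
#' span, the +/- 200 kb SV window, the RFD ambiguity threshold and averaging
#' span, and the control-sampler settings (150 regions x 10 sets, 50-bin
#' exclusion).
#'
#' @return Named list of defaults.
#' @export
default_params <- function() {
  list(
    sigma_estimator = "robust",
    threshold = 3.0,
    min_run = 2L,
    merge_gap = 2L,
    condition = "",
    gene_window = 50000,
    overlap_window = 600000,
    g4_span = 110000,
    sv_window = 200000,
    rfd_tau = 0.1,
    rfd_span = 150000,
    control_n = 150,
    control_sets = 10,
    exclusion_bins = 50,
    seed = 1
  )
}

stage_inputs <- list(
  sites = c("genome", "counts"),
  annotate = c("genes", "rt_domains", "origins"),
  rloop = "rloops",
  g4 = "g4s",
  expression = "expression",
  orient = c("rfd", "genes"),
  sv = "svs",
  controls = c("rt_domains", "rloops")
)

#' Run the full MiDAS analysis pipeline
#'
#' Stages run in dependency order: sigma normalization and site calling,
#' genomic-context annotation (replication timing, genic classification,
#' origin proximity), R-loop coincidence, G4 density, expression
#' quantification, replication/transcription orientation, and tumor SV
#' frequency. Partial input sets run partial pipelines; explicitly requesting
#' a stage whose input is missing is a configuration error. All outputs are
#' tab-separated tables plus a JSON report and a manifest with input
#' checksums sufficient to re-run the deterministic stages bit-identically.
#'
#' @param inputs named list of file paths. Recognized keys: `genome`
#'   (layout table), `counts` (bedGraph), `genes`, `rt_domains`, `origins`,
#'   `rloops`, `g4s` (BED), `rfd` (bedGraph), `expression` (TSV:
#'   gene_id, count, length_bp), `svs` (TSV: sample_id, cohort, chrom1,
#'   pos1, chrom2, pos2, type) and `cohort_sizes` (JSON).
#' @param outdir output directory.
#' @param params parameter overrides merged over [default_params()].
#' @param stages stages to run; `NULL` (default) infers runnable stages from
#'   the provided inputs. Always includes site calling.
#' @return Invisibly, a list with the stage outputs (`sites`, `annotation`,
#'   `report`, ...).
#' @export
run_full_pipeline <- function(inputs, outdir, params = list(), stages = NULL) {
  p <- utils::modifyList(default_params(), params)
  for (k in c("gene_window", "overlap_window", "g4_span", "sv_window", "rfd_span")) {
    if (p[[k]] <= 0) stop("configuration error: ", k, " must be > 0")
  }
  for (k in c("genome", "counts")) {
    if (is.null(inputs[[k]])) {
      stop("configuration error: stage 'sites' requires input '", k, "'")
    }
  }
  available <- names(stage_inputs)[vapply(stage_inputs, function(req) {
    all(req %in% names(inputs))
  }, logical(1))]
  if (is.null(stages)) {
    stages <- available
  } else {
    stages <- union("sites", stages)
    for (st in stages) {
      if (!st %in% names(stage_inputs)) stop("configuration error: unknown stage '", st, "'")
      miss <- setdiff(stage_inputs[[st]], names(inputs))
      if (length(miss) > 0L) {
        stop(sprintf(
          "configuration error: stage '%s' requires input '%s'", st, miss[1]
        ))
      }
    }
  }
  for (f in unlist(inputs)) {
    if (!file.exists(f)) stop("input validation error: file not found: ", f)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  layout <- read_genome_layout(inputs$genome)
  counts <- load_bin_track(inputs$counts, layout)
  sigma <- compute_sigma(counts, estimator = p$sigma_estimator)
  sites <- call_midas_sites(sigma,
    threshold = p$threshold, min_run = p$min_run,
    merge_gap = p$merge_gap, condition = p$condition
  )
  write_track(sigma, file.path(outdir, "sigma.bedgraph"))
  write_sites(sites, file.path(outdir, "sites.tsv"))
  out <- list(layout = layout, sites = sites)
  results <- list(n_sites = nrow(sites))
  row_counts <- list(sites = nrow(sites))

  annotation <- data.frame(site_id = site_ids(sites), stringsAsFactors = FALSE)
  if ("annotate" %in% stages) {
    genes <- read_intervals(inputs$genes, kind = "gene", layout = layout)
    rt <- read_intervals(inputs$rt_domains, kind = "rt_domain", layout = layout)
    origins <- read_intervals(inputs$origins, kind = "origin", layout = layout)
    cg <- classify_genic(sites, genes, window = p$gene_window)
    annotation$timing <- assign_replication_timing(sites, rt)
    annotation$genic <- cg$genic
    annotation$gene_count <- cg$gene_count
    annotation$genes <- cg$genes
    annotation$nearest_origin_bp <- nearest_origin_distance(
      sites, origins, bin_size = layout$bin_size
    )
    results$fraction_genic <- mean(cg$genic == "genic")
    results$timing_distribution <- as.list(
      table(factor(annotation$timing, c("early", "mid", "late", "undefined"))) /
        max(nrow(sites), 1)
    )
    out$genes <- genes
    out$rt_domains <- rt
  }
  if ("rloop" %in% stages && nrow(sites) > 0L) {
    rloops <- read_intervals(inputs$rloops, kind = "rloop", layout = layout)
    rf <- rloop_overlap_fraction(sites, rloops, window = p$gene_window)
    annotation$rloop_coincident <- rf$coincident
    results$fraction_rloop_coincident <- rf$fraction
    out$rloops <- rloops
  }
  if ("g4" %in% stages && nrow(sites) > 0L) {
    g4s <- read_intervals(inputs$g4s, kind = "g4", layout = layout)
    annotation$g4_per_kb <- g4_density(sites, g4s, span = p$g4_span)
  }
  if ("expression" %in% stages) {
    expr <- utils::read.delim(inputs$expression, stringsAsFactors = FALSE)
    tpm <- quantify_tpm(expr$count, expr$length_bp, gene_id = expr$gene_id)
    utils::write.table(tpm, file.path(outdir, "expression_tpm.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    out$tpm <- tpm
    row_counts$expression <- nrow(tpm)
  }
  if ("orient" %in% stages && nrow(sites) > 0L) {
    rfd <- read_track(inputs$rfd, layout, kind = "rfd")
    genes <- out$genes %||% read_intervals(inputs$genes, kind = "gene", layout = layout)
    calls <- classify_orientation(sites, genes, rfd,
      tau = p$rfd_tau, window = p$gene_window, span = p$rfd_span
    )
    utils::write.table(calls, file.path(outdir, "orientation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    os <- tryCatch(orientation_summary(calls), error = function(e) NULL)
    if (!is.null(os)) results$orientation <- os
    out$orientation <- calls
  }
  if ("sv" %in% stages && nrow(sites) > 0L) {
    svs <- utils::read.delim(inputs$svs, stringsAsFactors = FALSE)
    cohort_sizes <- if (!is.null(inputs$cohort_sizes)) {
      unlist(jsonlite::read_json(inputs$cohort_sizes))
    } else {
      tapply(svs$sample_id, svs$cohort, function(x) length(unique(x)))
    }
    freq <- site_sv_frequency(sites, svs, cohort_sizes, window = p$sv_window)
    utils::write.table(freq, file.path(outdir, "sv_frequency.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    results$sv_mean_percentage <- as.list(
      tapply(freq$percentage, freq$cohort, mean)
    )
    out$sv_frequency <- freq
  }
  utils::write.table(annotation, file.path(outdir, "annotation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  out$annotation <- annotation
  row_counts$annotation <- nrow(annotation)

  report <- generate_report(results)
  writeLines(report$json, file.path(outdir, "report.json"))
  writeLines(report$text, file.path(outdir, "report.txt"))
  out$report <- report$report

  manifest <- list(
    package_version = as.character(utils::packageVersion("midasmap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = p,
    stages = stages,
    inputs = lapply(inputs, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    row_counts = row_counts
  )
  writeLines(
    jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA),
    file.path(outdir, "manifest.json")
  )
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a machine-readable analysis report
#'
#' Collects the headline quantities of a run (site count, genic fraction,
#' replication-timing distribution, R-loop coincidence, transcribed fraction,
#' orientation fractions, per-cohort SV means) into a JSON-serializable list
#' plus human-readable text. With zero sites every fraction is reported as
#' not applicable (`NA`).
#'
#' @param results named list of stage summaries (see [run_full_pipeline()]).
#' @return A list: `report` (the structured summary), `json` (its JSON
#'   serialization) and `text` (human-readable lines).
#' @export
generate_report <- function(results) {
  if (length(results) == 0L) stop("at least one stage output is required")
  n <- results$n_sites %||% NA_integer_
  rep_list <- list(
    n_sites = n,
    fraction_genic = if (isTRUE(n > 0)) results$fraction_genic %||% NA_real_ else NA_real_,
    timing_distribution = if (isTRUE(n > 0)) results$timing_distribution else NULL,
    fraction_rloop_coincident = if (isTRUE(n > 0)) {
      results$fraction_rloop_coincident %||% NA_real_
    } else {
      NA_real_
    },
    fraction_transcribed = if (isTRUE(n > 0)) results$fraction_transcribed %||% NA_real_ else NA_real_,
    orientation = results$orientation,
    sv_mean_percentage = results$sv_mean_percentage
  )
  fmt <- function(x) {
    if (is.null(x) || length(x) == 0 || is.na(x[1])) "not applicable" else format(x, digits = 4)
  }
  text <- c(
    sprintf("MiDAS sites called: %s", fmt(n)),
    sprintf("fraction genic: %s", fmt(rep_list$fraction_genic)),
    sprintf("fraction R-loop coincident: %s", fmt(rep_list$fraction_rloop_coincident))
  )
  if (!is.null(rep_list$orientation)) {
    text <- c(text, sprintf(
      "orientation: %.1f%% co-directional, %.1f%% head-on (n = %d)",
      100 * rep_list$orientation$fraction_codirectional,
      100 * rep_list$orientation$fraction_head_on,
      rep_list$orientation$n
    ))
  }
  if (!is.null(rep_list$sv_mean_percentage)) {
    text <- c(text, vapply(names(rep_list$sv_mean_percentage), function(k) {
      sprintf("mean SV frequency, %s: %.2f%%", k, rep_list$sv_mean_percentage[[k]])
    }, character(1)))
  }
  list(
    report = rep_list,
    json = as.character(
      jsonlite::toJSON(rep_list, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", null = "null")
    ),
    text = text
  )
}
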
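# Configuration handling and the run_all orchestration that chains
# simulate/ingest -> burden -> complex -> TAD stages and writes a consolidated
# report.

CONFIG_KEYS <- c(
  # inputs (either simulate.* or explicit paths)
  "junctions_bedpe", "cn_tsv", "tads_bed", "genes_bed", "expression_tsv",
  "chrom_lengths_tsv", "out_dir", "seed", "simulate", "n_samples",
  # thresholds
  "w_chain", "min_junctions", "min_breakends", "window", "min_oscillations",
  "require_loh", "flank", "bin_size", "min_cases", "min_median", "alpha",
  "tolerance", "hotspot_alpha")

#' Default pipeline configuration
#'
#' @param seed RNG seed (used only when `simulate = TRUE`).
#' @param out_dir Output directory.
#' @return A named list of configuration values.
#' @export
default_config <- function(seed = 1L, out_dir = "svtopo_out") {
  list(simulate = TRUE, seed = seed, n_samples = 200L, out_dir = out_dir,
       junctions_bedpe = NULL, cn_tsv = NULL, tads_bed = NULL,
       genes_bed = NULL, expression_tsv = NULL, chrom_lengths_tsv = NULL,
       w_chain = 1e6, min_junctions = 3L, min_breakends = 10L, window = 5e7,
       min_oscillations = 7L, require_loh = TRUE, flank = 1e6,
       bin_size = 1e6, min_cases = 5L, min_median = 2, alpha = 0.05,
       tolerance = 1000, hotspot_alpha = 0.05)
}

#' Read and validate a YAML pipeline configuration
#'
#' Unknown keys are rejected; thresholds must be positive.
#'
#' @param path Path to a YAML file, or a named list of overrides.
#' @return A validated config list (defaults filled in).
#' @export
read_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  validate_config(utils::modifyList(default_config(), user, keep.null = TRUE))
}

#' @rdname read_config
#' @param config A config list.
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  pos <- c("w_chain", "min_junctions", "min_breakends", "window",
           "min_oscillations", "flank", "bin_size", "min_cases", "tolerance")
  for (k in pos) if (config[[k]] <= 0) stopf("config key '%s' must be positive", k)
  if (config$alpha < 0 || config$alpha > 1) stopf("alpha must lie in [0, 1]")
  config
}

#' Serialize a configuration to YAML
#'
#' @param config A config list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# write a table atomically (temp file + rename)
write_tsv_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  flat <- data.table::as.data.table(x)
  for (col in names(flat)) {
    if (is.list(flat[[col]])) {
      flat[[col]] <- vapply(flat[[col]], paste, character(1), collapse = ",")
    }
  }
  data.table::fwrite(flat, tmp, sep = "\t")
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Simulates (or ingests) a cohort, then runs the burden, hotspot, elbow,
#' complex-event and TAD-expression stages, writing stage TSVs and a JSON
#' summary to `config$out_dir`. Identical config and inputs give identical
#' outputs.
#'
#' @param config A config list (see [default_config()], [read_config()]).
#' @return The report bundle, invisibly: summaries, burden test inputs, events,
#'   flags, hotspots, elbow split, TAD results and the JSON summary list.
#' @export
run_all <- function(config) {
  config <- validate_config(utils::modifyList(default_config(), config,
                                              keep.null = TRUE))
  t0 <- Sys.time()
  msg <- function(fmt, ...) message(sprintf(paste0("[svtopo] ", fmt), ...))
  msg("thresholds: w_chain=%g min_junctions=%d min_breakends=%d min_oscillations=%d require_loh=%s bin_size=%g min_cases=%d min_median=%g alpha=%g",
      config$w_chain, config$min_junctions, config$min_breakends,
      config$min_oscillations, config$require_loh, config$bin_size,
      config$min_cases, config$min_median, config$alpha)

  stage <- function(name, expr) {
    t <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    msg("stage %-12s %.2fs", name, as.numeric(Sys.time() - t, units = "secs"))
    out
  }

  inputs <- stage("ingest", {
    if (isTRUE(config$simulate)) {
      simulate_cohort(sim_params(seed = config$seed,
                                 n_samples = config$n_samples))
    } else {
      cl <- data.table::fread(config$chrom_lengths_tsv, header = FALSE)
      list(junctions = read_sv_bedpe(config$junctions_bedpe),
           cn = read_cn_segments(config$cn_tsv),
           tads = if (!is.null(config$tads_bed)) read_tad_bed(config$tads_bed),
           genes = if (!is.null(config$genes_bed)) read_gene_bed(config$genes_bed),
           expression = if (!is.null(config$expression_tsv))
             read_expression_tsv(config$expression_tsv),
           chrom_lengths = stats::setNames(as.numeric(cl[[2]]),
                                           as.character(cl[[1]])))
    }
  })
  samples <- sort(unique(inputs$junctions$sample_id))

  summaries <- stage("burden", summarize_cohort(inputs$junctions, samples))
  elbow <- stage("elbow", elbow_split(
    stats::setNames(summaries$n_total, summaries$sample_id)))
  hotspots <- stage("hotspots", {
    bins <- bin_translocation_breakends(inputs$junctions, inputs$chrom_lengths,
                                        config$bin_size)
    call_hotspots(bins, length(samples), config$hotspot_alpha)
  })
  cx <- stage("complex", call_complex_events_cohort(
    inputs$junctions, inputs$cn,
    complex_params(w_chain = config$w_chain,
                   min_junctions = config$min_junctions,
                   min_breakends = config$min_breakends,
                   window = config$window,
                   min_oscillations = config$min_oscillations,
                   require_loh = config$require_loh, flank = config$flank),
    sample_ids = samples))
  tad <- if (!is.null(inputs$tads) && !is.null(inputs$genes) &&
             !is.null(inputs$expression)) {
    stage("tad", tad_gene_scan(inputs$junctions, inputs$tads, inputs$genes,
                               inputs$expression, all_samples = samples,
                               min_cases = config$min_cases,
                               min_median = config$min_median,
                               alpha = config$alpha))
  } else NULL

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_atomic(summaries, file.path(config$out_dir, "burden.tsv"))
  write_tsv_atomic(hotspots, file.path(config$out_dir, "hotspots.tsv"))
  write_tsv_atomic(cx$events, file.path(config$out_dir, "complex_events.tsv"))
  write_tsv_atomic(cx$flags, file.path(config$out_dir, "sample_flags.tsv"))
  if (!is.null(tad)) {
    write_tsv_atomic(tad$results, file.path(config$out_dir, "tad_genes.tsv"))
    write_tsv_atomic(tad$neo_tads, file.path(config$out_dir, "neo_tads.tsv"))
    volcano <- tad$results[, list(gene_id, tad_id, log2fc,
                                  neg_log10_p = -log10(p_anova))]
    write_tsv_atomic(volcano, file.path(config$out_dir, "volcano.tsv"))
  }

  summary <- list(
    n_samples = length(samples),
    median_sv_total = stats::median(summaries$n_total),
    n_high_burden = length(elbow$high_ids),
    high_burden_samples = elbow$high_ids,
    event_counts = as.list(table(cx$events$label)),
    n_hotspots = sum(hotspots$is_hotspot),
    significant_genes = if (!is.null(tad))
      tad$results$gene_id[tad$results$passes_filters] else character(),
    thresholds = config[c("w_chain", "min_junctions", "min_breakends",
                          "min_oscillations", "require_loh", "bin_size",
                          "min_cases", "min_median", "alpha")])
  tmp <- file.path(config$out_dir, "summary.json.tmp")
  jsonlite::write_json(summary, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, file.path(config$out_dir, "summary.json"))
  msg("done in %.2fs", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(list(inputs = inputs, summaries = summaries, elbow = elbow,
                 hotspots = hotspots, complex = cx, tad = tad,
                 summary = summary))
}
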
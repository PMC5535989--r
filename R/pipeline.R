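.pipelineDefaults <- function() {
  list(seed = 1L,
       out_dir = NULL,
       n_datasets = 3L,
       sim = list(),
       thresholds = list(r_min = 0.82, omega_range = c(0.22, 0.29),
                         amplitude_min = 0.045),
       schemes = c("TL", "RW", "CW", "RCW", "RCWB"),
       n_blocks = 2L,
       k_clusters = 6L,
       universe = NULL)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full rhythmicity-detection pipeline on synthetic data
#'
#' Config-driven end-to-end run: simulate raw-intensity datasets (one per
#' emulated cell line) -> quantile normalize -> log10 transform -> collapse
#' replicate probes -> cosine fits -> threshold classification ->
#' randomization null comparisons (first dataset) -> phase clustering ->
#' z-scaled heatmap export -> cross-dataset overlap statistics and summary
#' report. All stage outputs are TSV files under \code{out_dir} and are
#' listed in \code{manifest.yaml}; every source of randomness derives from
#' the single root seed (dataset d uses seed + d, scheme s additionally
#' offsets by 100 * s), so a rerun with the same config is bit-identical.
#'
#' @param config a named list, or the path of a YAML file holding one, with
#'   any of: \code{seed} (root seed, default 1), \code{out_dir} (required),
#'   \code{n_datasets} (default 3), \code{sim} (list of \code{\link{simConfig}}
#'   overrides), \code{thresholds} (list: r_min, omega_range, amplitude_min),
#'   \code{schemes} (default all five), \code{n_blocks}, \code{k_clusters},
#'   \code{universe} (default: number of collapsed features).
#' @return the manifest, invisibly: a list of config, seeds, package version
#'   and all output paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(.pipelineDefaults(), config)
  if (is.null(cfg$out_dir)) stop("config must name 'out_dir'")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, sprintf(...))
  thr <- rhythmicityThresholds(cfg$thresholds$r_min,
                               unlist(cfg$thresholds$omega_range),
                               cfg$thresholds$amplitude_min)
  paths <- character(0)
  note <- function(p) { paths <<- c(paths, p); p }

  calls_list <- list()
  norm_first <- NULL
  calls_first <- NULL
  for (d in seq_len(cfg$n_datasets)) {
    ds <- sprintf("dataset%d", d)
    sim_args <- utils::modifyList(cfg$sim, list(seed = cfg$seed + d))
    sim <- .stage(paste0("simulate/", ds), {
      generateExpressionDataset(do.call(simConfig, sim_args),
                                output_scale = "raw")
    })
    writeExpressionTSV(sim$exprs, note(out("%s_raw.tsv", ds)))
    utils::write.table(sim$truth, note(out("%s_truth.tsv", ds)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    norm <- .stage(paste0("preprocess/", ds), {
      collapseProbes(log10Transform(quantileNormalize(sim$exprs)),
                     sim$probe_map)
    })
    writeExpressionTSV(norm, note(out("%s_norm.tsv", ds)))
    fits <- .stage(paste0("fit/", ds), fitCosineMatrix(norm))
    utils::write.table(fitParams(fits), note(out("%s_fits.tsv", ds)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    calls <- .stage(paste0("classify/", ds), classifyRhythmic(fits, thr))
    utils::write.table(calls, note(out("%s_calls.tsv", ds)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    calls_list[[ds]] <- calls
    if (d == 1L) {
      norm_first <- norm
      calls_first <- calls
      exp_fits <- fits
      for (si in seq_along(cfg$schemes)) {
        s <- cfg$schemes[si]
        cmp <- .stage(paste0("compare-null/", s), {
          null_fits <- nullFitEnsemble(norm, s, seed = cfg$seed + 100L * si,
                                       n_blocks = cfg$n_blocks)
          compareNull(exp_fits, null_fits)
        })
        utils::write.table(cmp, note(out("null_%s.tsv", s)), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
  }

  clustering <- .stage("cluster", {
    clusterByPhase(calls_first, k = cfg$k_clusters)
  })
  utils::write.table(clustering, note(out("clusters.tsv")), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  z <- .stage("heatmap", zscaleForHeatmap(norm_first, calls_first, clustering))
  utils::write.table(data.frame(feature_id = rownames(z), z,
                                check.names = FALSE),
                     note(out("heatmap_z.tsv")), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  universe <- if (is.null(cfg$universe)) nrow(norm_first) else cfg$universe
  report <- .stage("report", {
    summarizeCalls(calls_list, universe_size = universe,
                   clustering = clustering)
  })
  utils::write.table(report$summary, note(out("report_summary.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$overlaps)) {
    utils::write.table(report$overlaps, note(out("report_overlaps.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$venn, note(out("report_venn.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "rhythmiR",
    version = as.character(utils::packageVersion("rhythmiR")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    root_seed = cfg$seed,
    universe = universe,
    outputs = basename(paths))
  yaml::write_yaml(manifest, out("manifest.yaml"))
  manifest$outputs <- c(manifest$outputs, "manifest.yaml")
  invisible(manifest)
}
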
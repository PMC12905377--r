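#' Configuration of a full analysis run
#'
#' @param cohort A [cohort_config()] (default: female study defaults).
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it and the stage name, so one integer reproduces the whole run.
#' @param k_range Cluster counts to evaluate (default 2:5).
#' @param out_dir Output directory for tables and figures.
#' @param tsne_steps t-SNE optimization steps (default 1000).
#' @param basal_only Also run the basal-only (pre-ligand frames)
#'   classification variant (default TRUE).
#' @param figures Render PNG figures (default TRUE; tables are always
#'   written).
#' @param feature_net Train the feature-learning network (default TRUE).
#' @param verbose Log one line per stage (default TRUE).
#'
#' @return A `run_config` object.
#' @export
run_config <- function(cohort = default_cohort_config("female"), seed = 1L,
                       k_range = 2:5, out_dir = tempfile("calcitrace_run_"),
                       tsne_steps = 1000, basal_only = TRUE, figures = TRUE,
                       feature_net = TRUE, verbose = TRUE) {
  stopifnot(inherits(cohort, "cohort_config"))
  k_range <- as.integer(k_range)
  if (any(k_range < 2L)) abort("`k_range` values must be >= 2.")
  structure(
    list(cohort = cohort, seed = as.integer(seed), k_range = k_range,
         out_dir = out_dir, tsne_steps = tsne_steps,
         basal_only = isTRUE(basal_only), figures = isTRUE(figures),
         feature_net = isTRUE(feature_net), verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

log_stage <- function(config, fmt, ...) {
  if (config$verbose) message(sprintf("[calcitrace] %s", sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the cohort, computes trace metrics and heatmap
#' ordering, 2D embeddings (PCA, t-SNE, UMAP when available), K-means
#' cluster/composition tables over `k_range` on both the t-SNE plane and the
#' full-dimensional traces, the classical baseline suite plus the
#' feature-learning network (full-trace and basal-only), transfer evaluation
#' and feature-space projection of treated cells, and Grad-CAM saliency.
#' All tables are written as CSV under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param traces Optional pre-loaded [trace_matrix()]; when `NULL` the
#'   cohort is generated from `config$cohort`.
#' @return A `run_report`: list with `tables` (named list of tibbles),
#'   `manifest` (files written), `seeds`, and `wall_time_s`.
#' @export
run_full <- function(config = run_config(), traces = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list()
  stage_seed <- function(stage) {
    s <- derive_seed(config$seed, stage)
    seeds[[stage]] <<- s
    s
  }
  tables <- list()
  manifest <- character(0)
  write_table <- function(tbl, name) {
    path <- file.path(config$out_dir, paste0(name, ".csv"))
    readr::write_csv(tbl, path)
    tables[[name]] <<- tbl
    manifest <<- c(manifest, path)
  }
  write_figure <- function(plot, name) {
    if (!config$figures) return(invisible())
    path <- file.path(config$out_dir, paste0(name, ".png"))
    ok <- tryCatch({
      ggplot2::ggsave(path, plot, width = 7, height = 5, dpi = 150)
      TRUE
    }, error = function(e) {
      inform(sprintf("Figure %s skipped: %s", name, conditionMessage(e)))
      FALSE
    })
    if (ok) manifest <<- c(manifest, path)
  }

  # -- cohort ---------------------------------------------------------------
  if (is.null(traces)) {
    log_stage(config, "generate: %s cohort, seed %d", config$cohort$sex,
              stage_seed("generate"))
    traces <- generate_cohort(config$cohort, seed = seeds$generate)
  }
  save_traces(traces, file.path(config$out_dir, "cohort"))
  manifest <- c(manifest, file.path(config$out_dir, "cohort",
                                    c("traces.csv", "metadata.csv", "grid.json")))

  # -- metrics --------------------------------------------------------------
  log_stage(config, "metrics: %d cells", n_cells(traces))
  write_table(window_stats(traces), "window_stats")
  gt <- group_mean_traces(traces)
  write_table(gt, "group_mean_traces")
  write_table(trace_peaks(gt), "group_peaks")
  write_table(inactive_fraction(traces, first_lh_window(traces$grid)),
              "inactive_first_lh_minute")
  write_table(tibble(rank = seq_len(n_cells(traces)),
                     cell_id = traces$meta$cell_id[heatmap_order(traces)]),
              "heatmap_order")
  write_figure(autoplot(traces), "heatmap")
  write_figure(plot_group_traces(gt, traces$grid), "group_traces")

  # -- embeddings -----------------------------------------------------------
  log_stage(config, "embed: PCA, t-SNE (%d steps), UMAP", config$tsne_steps)
  embeddings <- list(pca = embed_pca(traces))
  embeddings$tsne <- embed_tsne(traces, n_steps = config$tsne_steps,
                                seed = stage_seed("tsne"))
  umap <- embed_umap(traces, seed = stage_seed("umap"))
  if (!is.null(umap)) embeddings$umap <- umap
  for (nm in names(embeddings)) {
    write_table(as_tibble(embeddings[[nm]]), paste0("embedding_", nm))
    write_figure(autoplot(embeddings[[nm]]), paste0("embedding_", nm))
  }

  # -- clustering -----------------------------------------------------------
  comp_rows <- list()
  for (k in config$k_range) {
    for (space in c("tsne", "full")) {
      pts <- if (space == "tsne") embeddings$tsne else traces
      km <- cluster_kmeans(pts, k, seed = stage_seed(sprintf("kmeans_%s_k%d", space, k)),
                           labels = traces$meta$group,
                           silhouette = n_cells(traces) <= 2000)
      comp <- km$composition
      comp$k <- k
      comp$space <- space
      comp$silhouette <- if (!is.null(km$silhouette)) {
        attr(km$silhouette, "cluster_means")$silhouette[match(comp$cluster,
          attr(km$silhouette, "cluster_means")$cluster)]
      } else NA_real_
      comp_rows[[sprintf("%s_k%d", space, k)]] <- comp
    }
  }
  write_table(bind_rows(comp_rows), "cluster_composition")

  # -- classification -------------------------------------------------------
  reports <- list()
  net <- NULL
  {
    # train/evaluate on control vs mutant; treated cells are transfer-only
    has_treated <- "HOM_TREATED" %in% traces$meta$group
    fit_traces <- if (has_treated) traces[traces$meta$group != "HOM_TREATED", ] else traces
    treated <- if (has_treated) traces[traces$meta$group == "HOM_TREATED", ]
    split <- stratified_split(fit_traces, seed = stage_seed("split"))
    log_stage(config, "classify: %d train / %d test cells%s",
              length(split$train), length(split$test),
              if (has_treated) sprintf(" + %d treated (transfer)", n_cells(treated)) else "")
    suite <- run_baseline_suite(fit_traces, split,
                                include_feature_net = config$feature_net,
                                transfer_traces = treated,
                                seed = stage_seed("baselines"))
    net <- attr(suite, "feature_net")
    suite$variant <- "full_trace"
    reports$full <- suite
    if (config$basal_only) {
      basal <- truncate_basal(fit_traces)
      basal_treated <- if (has_treated) truncate_basal(treated)
      log_stage(config, "classify: basal-only variant (%d frames)", n_frames(basal))
      suite_b <- run_baseline_suite(basal, split,
                                    include_feature_net = config$feature_net,
                                    transfer_traces = basal_treated,
                                    seed = stage_seed("baselines_basal"))
      suite_b$variant <- "basal_only"
      reports$basal <- suite_b
    }
    all_reports <- bind_rows(reports)
    write_table(all_reports, "classifier_report")
    jsonlite::write_json(all_reports,
                         file.path(config$out_dir, "classifier_report.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- c(manifest, file.path(config$out_dir, "classifier_report.json"))

    if (!is.null(net) && has_treated && length(net$classes) == 2L) {
      log_stage(config, "explain: feature-space projection + saliency")
      proj <- project_feature_space(net, traces, n_steps = config$tsne_steps,
                                    seed = stage_seed("projection"))
      write_table(as_tibble(proj), "feature_space_projection")
      write_figure(autoplot(proj), "feature_space_projection")
      kmp <- cluster_kmeans(proj, k = 3, seed = stage_seed("kmeans_projection"),
                            labels = traces$meta$group)
      write_table(kmp$composition, "feature_space_composition")
    }
    if (!is.null(net)) {
      sal <- grad_cam_saliency(net, traces)
      sal_summary <- tibble(
        group = traces$meta$group,
        basal_mass = rowMeans(unclass(sal)[, seq_len(traces$grid$lh_start), drop = FALSE]),
        lh_mass = rowMeans(unclass(sal)[, window_cols(resolve_window(traces$grid, "LH")), drop = FALSE])
      ) |>
        group_by(.data$group) |>
        summarise(basal_mass = mean(.data$basal_mass),
                  lh_mass = mean(.data$lh_mass), .groups = "drop")
      write_table(sal_summary, "saliency_window_mass")
      write_figure(autoplot(sal, traces$grid), "saliency")
    }
  }

  report <- structure(
    list(tables = tables, manifest = manifest, seeds = seeds,
         out_dir = config$out_dir,
         wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report"
  )
  jsonlite::write_json(
    list(manifest = manifest, seeds = seeds, wall_time_s = report$wall_time_s),
    file.path(config$out_dir, "run_report.json"), auto_unbox = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d artifacts in %s (%.1f s)\n",
              length(x$manifest), x$out_dir, x$wall_time_s))
  cat(paste(" -", names(x$tables), collapse = "\n"), "\n")
  invisible(x)
}
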
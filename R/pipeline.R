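#' Pipeline configuration
#'
#' Collects every stage parameter and seed into one serializable object. The
#' resolved configuration (defaults filled in) is archived next to the run's
#' outputs together with its hash.
#'
#' @param n_designs library size (default 2176).
#' @param grid_dim chip grid edge (default 66; `2 * n_designs + n_flats`
#'   must equal `grid_dim^2`).
#' @param n_flats flat control slots (default 4).
#' @param seed global seed; stage seeds derive from it.
#' @param design design grammar parameters, a [topo_config()].
#' @param scale raster scale (px/um).
#' @param spacing_tiles,downscale,stop_diameter_px spacing-descriptor
#'   parameters (see [compute_descriptor_matrix()]).
#' @param prune_threshold descriptor correlation threshold.
#' @param screen a [screen_params()].
#' @param n_donors donors per screen.
#' @param snr_threshold SNR exclusion threshold.
#' @param split train fraction.
#' @param top_n features kept by Shapley selection.
#' @param contrast_k group size of the top/bottom contrast.
#' @return list of class `topo_pipeline_config`.
#' @export
pipeline_config <- function(n_designs = 2176, grid_dim = 66, n_flats = 4,
                            seed = 1, design = topo_config(), scale = 10,
                            spacing_tiles = 2, downscale = 5,
                            stop_diameter_px = 3, prune_threshold = 0.85,
                            screen = screen_params(), n_donors = 5,
                            snr_threshold = 2, split = 0.7, top_n = 20,
                            contrast_k = 50) {
  structure(as.list(environment()), class = "topo_pipeline_config")
}

config_hash <- function(config) rlang::hash(config)

#' Run the whole screen pipeline
#'
#' Design generation, chip layout, descriptor extraction and pruning,
#' synthetic screen simulation, aggregation and SNR filtering, attachment
#' and phenotype clustering, model fitting with Shapley ranking, feature
#' selection and refit, and the top/bottom composite contrast. Every stage
#' output is written to `out_dir` as delimited or structured text with the
#' resolved configuration and its hash; rerunning with the same
#' configuration reproduces identical tables.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (default a timestamped directory under
#'   `tempdir()`); created if missing.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with all in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (is.null(out_dir)) {
    out_dir <- file.path(tempdir(),
                         paste0("topomacro_run_", format(Sys.time(), "%Y%m%d_%H%M%S")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cfg_out <- config
  cfg_out$hash <- config_hash(config)
  jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  say("designs: generating ", config$n_designs, " designs")
  library <- stage("design", generate_library(config$n_designs, config$seed,
                                              config$design))
  write_library(library, file.path(out_dir, "library.json"))
  layout <- stage("layout", layout_chip(library, config$grid_dim, config$n_flats))
  write.csv(layout, file.path(out_dir, "layout.csv"), row.names = FALSE)

  say("descriptors: rasterizing and measuring")
  desc <- stage("descriptors",
                compute_descriptor_matrix(library, config$scale,
                                          config$spacing_tiles, config$downscale,
                                          config$stop_diameter_px))
  write.csv(desc, file.path(out_dir, "descriptors.csv"), row.names = FALSE)
  jsonlite::write_json(attr(desc, "manifest"),
                       file.path(out_dir, "descriptor_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  retained_desc <- stage("prune", prune_by_correlation(desc, config$prune_threshold))

  say("screen: simulating ", config$n_donors, " donors")
  screen <- stage("simulate",
                  simulate_screen(layout, desc, config$screen, config$n_donors,
                                  config$seed + 1L))
  write.csv(screen, file.path(out_dir, "screen.csv"), row.names = FALSE)

  say("analyze: aggregating, filtering, clustering")
  summaries <- stage("aggregate", normalize_and_aggregate(screen))
  flagged <- snr_filter(summaries, config$snr_threshold, keep_all = TRUE)
  retained <- dplyr::filter(flagged, .data$retained)
  topo_rows <- dplyr::filter(retained, .data$design_id != "FLAT")
  topo_rows$attach_class <- cluster_attachment(topo_rows$attach_mean,
                                               seed = config$seed)
  topo_rows$phenotype_class <- cluster_phenotype(topo_rows)
  write.csv(flagged, file.path(out_dir, "summaries.csv"), row.names = FALSE)
  consistency <- stage("consistency", rank_and_consistency(screen))

  say("model: fitting tree ensembles")
  model_data <- dplyr::inner_join(
    topo_rows[, c("design_id", "attach_mean", "composite")],
    desc[, c("design_id", retained_desc)], by = "design_id")
  models <- purrr::map(c(attachment = "attach_mean", composite = "composite"),
                       function(tgt) {
    stage(paste0("model_", tgt), {
      ms <- train_models(model_data, tgt, features = retained_desc,
                         split = config$split, seed = config$seed)
      rankings <- purrr::map(ms, shapley_rank)
      selected <- select_features(rankings$gradient_boosted_trees,
                                  list(type = "top_n", n = config$top_n))
      refit <- train_models(model_data, tgt, features = selected,
                            split = config$split, seed = config$seed)
      list(models = ms, rankings = rankings, selected = selected, refit = refit)
    })
  })
  report <- purrr::imap_dfr(models, function(m, tgt) {
    dplyr::bind_rows(purrr::map(m$models, glance),
                     purrr::map(m$refit, function(f) {
                       g <- glance(f); g$family <- paste0(g$family, "_refit"); g
                     }))
  })
  write.csv(report, file.path(out_dir, "model_report.csv"), row.names = FALSE)
  purrr::iwalk(models, function(m, tgt) {
    write.csv(m$rankings$gradient_boosted_trees,
              file.path(out_dir, paste0("shap_ranking_", tgt, ".csv")),
              row.names = FALSE)
  })

  contrast <- if (nrow(topo_rows) >= 2 * config$contrast_k) {
    ct <- stage("contrast", topk_contrast(topo_rows, desc, config$contrast_k))
    write.csv(ct, file.path(out_dir, "topk_contrast.csv"), row.names = FALSE)
    ct
  } else NULL

  manifest <- list(config_hash = cfg_out$hash,
                   files = list.files(out_dir),
                   n_designs = config$n_designs,
                   n_retained = nrow(retained),
                   generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(library = library, layout = layout, descriptors = desc,
                 retained_descriptors = retained_desc, screen = screen,
                 summaries = flagged, units = topo_rows,
                 consistency = consistency, models = models,
                 contrast = contrast, out_dir = out_dir))
}
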
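# End-to-end orchestration: simulate -> features -> score -> cluster,
# with a machine-readable run manifest.

#' Default pipeline configuration
#'
#' Desk-scale defaults: 176 library genes on 2 x 96-well plates,
#' triplicate screens, 50 cells per well drawn with the feature tier,
#' classical Z-scores at threshold 1.5 with the 2-of-3 sign-consistent
#' replicate rule, and average-linkage clustering of the hit genes.
#'
#' @return named list of configuration values; any subset can be
#'   overridden via the `config` argument of [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(seed = 1L,
       n_genes = 176L,
       n_screens = 3L,
       tier = "features",          # or "images"
       cells_per_well = 50L,
       n_fields = 2L,              # image tier only
       cells_per_field = 4L,       # image tier only
       fraction_hits_decrease = 0.10,
       fraction_hits_increase = 0.10,
       effect_magnitude = 0.25,
       sd_screen = 0.06,
       sd_cell = 0.30,
       min_cells = 20L,
       z_threshold = 1.5,
       min_screens = 2L,
       z_variant = "classical",
       require_sign_consistency = TRUE,
       cluster_metric = "euclidean",
       cluster_hits_only = TRUE,
       heatmap = FALSE)
}

#' Run the full screen analysis pipeline
#'
#' Executes simulate -> (morphometry) -> well aggregation -> plate
#' normalization and Z-scoring -> hit calling -> clustering, with all
#' stages communicating through files in `out_dir` (`layout.csv`,
#' `truth.csv`, `cells.csv`, `wells.csv`, `zscores.csv`, `hits.csv`,
#' `summary.json`, `profile_matrix.csv`, `dendrogram.nwk`,
#' `leaf_order.txt`) and a final `manifest.json` recording the config
#' hash, seed, per-stage timings and warnings, output checksums, and
#' recovery statistics against the planted truth. Rerunning with an
#' identical config yields identical data outputs.
#'
#' @param config named list overriding entries of
#'   [default_pipeline_config()]; unknown keys raise an error.
#' @param out_dir output directory.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  defaults <- default_pipeline_config()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_file <- file.path(out_dir, "config.yml")
  yaml::write_yaml(cfg, cfg_file)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_file)),
                   seed = cfg$seed,
                   package_version =
                     as.character(utils::packageVersion("polarityscreen")),
                   stages = list())
  warnings_log <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    nwarn <- 0L
    res <- withCallingHandlers(expr, warning = function(w) {
      nwarn <<- nwarn + 1L
      warnings_log <<- c(warnings_log,
                         paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      warnings = nwarn)
    res
  }

  sconf <- screen_config(z_threshold = cfg$z_threshold,
                         min_screens = cfg$min_screens,
                         n_screens = cfg$n_screens,
                         z_variant = cfg$z_variant,
                         require_sign_consistency =
                           cfg$require_sign_consistency,
                         min_cells = cfg$min_cells)

  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  layout <- plate_layout(genes, n_screens = cfg$n_screens)
  effects <- effect_model(genes,
                          fraction_hits_decrease =
                            cfg$fraction_hits_decrease,
                          fraction_hits_increase =
                            cfg$fraction_hits_increase,
                          effect_magnitude = cfg$effect_magnitude,
                          sd_screen = cfg$sd_screen,
                          sd_cell = cfg$sd_cell,
                          seed = cfg$seed)

  cells <- stage("simulate", {
    if (cfg$tier == "features") {
      sim <- simulate_screens(layout, effects,
                              cells_per_well = cfg$cells_per_well,
                              seed = cfg$seed)
      utils::write.csv(sim$layout, file.path(out_dir, "layout.csv"),
                       row.names = FALSE)
      utils::write.csv(sim$truth, file.path(out_dir, "truth.csv"),
                       row.names = FALSE)
      sim$cells
    } else if (cfg$tier == "images") {
      mask_dir <- file.path(out_dir, "masks")
      simulate_fields(layout, effects, mask_dir,
                      n_fields = cfg$n_fields,
                      cells_per_field = cfg$cells_per_field,
                      seed = cfg$seed)
      file.copy(file.path(mask_dir, c("layout.csv", "truth.csv")),
                out_dir, overwrite = TRUE)
      features_from_masks(mask_dir, layout)
    } else stopf("unknown tier '%s'", cfg$tier)
  })
  utils::write.csv(cells, file.path(out_dir, "cells.csv"),
                   row.names = FALSE)

  wells <- stage("aggregate", {
    w <- aggregate_cells(cells, layout = layout,
                         min_cells = cfg$min_cells)
    utils::write.csv(w, file.path(out_dir, "wells.csv"),
                     row.names = FALSE)
    w
  })

  ztab <- stage("score", {
    z <- score_wells(wells, sconf)
    utils::write.csv(z, file.path(out_dir, "zscores.csv"),
                     row.names = FALSE)
    z
  })

  hits <- stage("hits", {
    h <- call_hits(ztab, sconf)
    utils::write.csv(h, file.path(out_dir, "hits.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summarize_screen(h),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    h
  })

  stage("cluster", {
    genes_cl <- if (cfg$cluster_hits_only) hits$gene[hits$hit]
                else hits$gene
    if (length(genes_cl) >= 2L) {
      pm <- build_profile_matrix(ztab, genes = genes_cl)
      cl <- cluster_profiles(pm, metric = cfg$cluster_metric)
      export_heatmap(cl, out_dir,
                     heatmap_file = if (isTRUE(cfg$heatmap))
                       file.path(out_dir, "heatmap.png") else NULL)
    } else {
      warnf("fewer than 2 genes to cluster; clustering skipped")
      NULL
    }
  })

  manifest$recovery <- stage("evaluate", {
    tr <- utils::read.csv(file.path(out_dir, "truth.csv"))
    evaluate_against_truth(hits, tr)
  })

  outputs <- c("layout.csv", "truth.csv", "cells.csv", "wells.csv",
               "zscores.csv", "hits.csv", "summary.json",
               "profile_matrix.csv", "dendrogram.nwk", "leaf_order.txt")
  outputs <- outputs[file.exists(file.path(out_dir, outputs))]
  manifest$checksums <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(manifest$checksums) <- outputs
  manifest$warnings <- warnings_log
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
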
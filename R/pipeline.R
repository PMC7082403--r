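#' Default end-to-end run configuration
#'
#' @param simulate Logical; generate synthetic inputs (default `TRUE`) or
#'   read them from `paths`.
#' @param seed Master seed; every stage derives its own stream from it via
#'   [derive_seed()], so adding a stage never perturbs earlier stages.
#' @param sim Parameter list passed to [sim_config()].
#' @param width_pct,min_bin_count Frontier parameters, see [li_frontier()].
#' @param r_min,r_cross_max Screening thresholds, see [pearson_screen()].
#' @param k,cv_trees,interp_trees,tree_candidates,n_pdp,pdp_background Model
#'   suite parameters, see [run_scenarios()].
#' @param scenarios Yield scenarios to evaluate.
#' @param paths Named list of input paths (`plots`, `monthly`, `daily`,
#'   `cells`) used when `simulate = FALSE`.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = TRUE, seed = 1, sim = list(),
                       width_pct = 5, min_bin_count = 20,
                       r_min = 0.15, r_cross_max = 0.50,
                       k = 6, cv_trees = 500, interp_trees = 500,
                       tree_candidates = 25, n_pdp = 6,
                       pdp_background = NULL,
                       scenarios = c("A", "B", "C", "D"),
                       paths = list()) {
  cfg <- as.list(environment())
  if (!simulate) {
    needed <- c("plots", "monthly", "daily")
    missing <- setdiff(needed, names(paths))
    if (length(missing)) {
      abort(sprintf("`simulate = FALSE` but path(s) missing: %s.",
                    paste(missing, collapse = ", ")),
            class = "yieldgap_config_error")
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> climate features -> frontier & gaps ->
#' screening, forests, cross-validation and interpretation, writing each
#' stage's artifacts plus a hash manifest into `out_dir`. Stage timings and
#' progress go to the message stream; artifact files are fully determined
#' by the configuration (including the master seed).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The path to `out_dir`, invisibly; artifacts as side effects.
#' @export
run_all <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_all <- Sys.time()
  stage_times <- list()
  artifact <- function(name) file.path(out_dir, name)
  timed <- function(name, expr) {
    t0 <- Sys.time()
    inform(sprintf("[yieldgap] stage %s ...", name))
    res <- tryCatch(expr, error = function(e) {
      writeLines(name, artifact("FAILED"))
      abort(sprintf("Stage `%s` failed: %s", name, conditionMessage(e)),
            class = "yieldgap_stage_error", parent = e)
    })
    stage_times[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    res
  }

  inputs <- timed("simulate", {
    if (config$simulate) {
      sim_args <- utils::modifyList(list(seed = derive_seed(config$seed, "sim")),
                                    config$sim)
      sim <- simulate_dataset(do.call(sim_config, sim_args))
      write_plots(sim$plots, artifact("plots.csv"))
      readr::write_csv(sim$monthly, artifact("monthly_climate.csv"),
                       progress = FALSE)
      readr::write_csv(sim$daily, artifact("daily_weather.csv"),
                       progress = FALSE)
      readr::write_csv(sim$orchards, artifact("cells.csv"), progress = FALSE)
      jsonlite::write_json(
        sim$truth[setdiff(names(sim$truth), "gap")],
        artifact("sim_truth.json"), auto_unbox = TRUE, digits = NA)
      list(plots = sim$plots, monthly = sim$monthly, daily = sim$daily,
           cells = sim$orchards)
    } else {
      plots <- load_plots(config$paths$plots)
      cells <- if (!is.null(config$paths$cells)) {
        readr::read_csv(config$paths$cells, show_col_types = FALSE,
                        progress = FALSE)
      }
      list(
        plots = plots,
        monthly = readr::read_csv(config$paths$monthly,
                                  show_col_types = FALSE, progress = FALSE),
        daily = readr::read_csv(config$paths$daily,
                                show_col_types = FALSE, progress = FALSE),
        cells = cells
      )
    }
  })

  feats <- timed("features", {
    ft <- build_feature_table(inputs$plots, inputs$monthly, inputs$daily,
                              cells = inputs$cells)
    readr::write_csv(ft, artifact("features.csv"), progress = FALSE)
    jsonlite::write_json(features_manifest(), artifact("features_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    ft
  })

  gaps <- timed("frontier", {
    frontier <- li_frontier(inputs$plots, width_pct = config$width_pct,
                            min_bin_count = config$min_bin_count)
    write_frontier(frontier, artifact("frontier.json"))
    g <- compute_gaps(inputs$plots, frontier)
    readr::write_csv(g, artifact("gaps.csv"), progress = FALSE)
    g
  })

  report <- timed("fit", {
    run_scenarios(feats, gaps, seed = derive_seed(config$seed, "fit"),
                  scenarios = config$scenarios, k = config$k,
                  cv_trees = config$cv_trees,
                  interp_trees = config$interp_trees,
                  n_pdp = config$n_pdp,
                  pdp_background = config$pdp_background,
                  tree_candidates = config$tree_candidates,
                  r_min = config$r_min, r_cross_max = config$r_cross_max)
  })

  timed("report", {
    readr::write_csv(scenario_comparison(report),
                     artifact("scenario_comparison.csv"), progress = FALSE)
    jsonlite::write_json(
      purrr::map(report$yield$cv, function(x) as.list(glance(x))),
      artifact("cv_report.json"), auto_unbox = TRUE, digits = NA)
    for (tgt in c("yield", "gap", "li")) {
      blk <- report[[tgt]]
      readr::write_csv(blk$importance,
                       artifact(sprintf("importance_%s.csv", tgt)),
                       progress = FALSE)
      for (f in names(blk$pdp)) {
        readr::write_csv(blk$pdp[[f]],
                         artifact(sprintf("pdp_%s_%s.csv", tgt, f)),
                         progress = FALSE)
      }
      jsonlite::write_json(
        list(oob_rmse = blk$rules$oob_rmse,
             candidate = blk$rules$candidate,
             nodes = blk$rules$nodes,
             rules = blk$rules$rules),
        artifact(sprintf("rules_%s.json", tgt)), auto_unbox = TRUE,
        digits = NA)
      readr::write_csv(as_tibble(blk$screen),
                       artifact(sprintf("screen_%s.csv", tgt)),
                       progress = FALSE)
    }
    invisible(NULL)
  })

  # manifest: deterministic hashes of every artifact; timings go to the log
  files <- sort(setdiff(list.files(out_dir), c("manifest.json", "run_log.txt")))
  manifest <- list(
    seed = config$seed,
    artifacts = lapply(stats::setNames(files, files), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    })
  )
  jsonlite::write_json(manifest, artifact("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("total_seconds: %.1f", as.numeric(Sys.time() - t_all, units = "secs")),
    sprintf("%s_seconds: %.1f", names(stage_times), unlist(stage_times))
  ), artifact("run_log.txt"))
  inform(sprintf("[yieldgap] run complete: %s", out_dir))
  invisible(out_dir)
}
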
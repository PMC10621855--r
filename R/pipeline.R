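# Orchestration of the full computational experiment: all wall models
# crossed with all target currents, lesion metrics per run and linear
# lesion-size-vs-current trends.

#' Experiment configuration
#'
#' @param models subset of "A".."F"
#' @param currents target delivered currents (A)
#' @param threshold lethal field threshold (V/cm)
#' @param geometry a [geometry_spec()]
#' @param scar a [scar_spec()]
#' @param tissues a [tissue_properties()]
#' @param solver a [solver_settings()]
#' @param mesh list of mesh sizes passed to [generate_mesh()]
#' @param resample_h isoline resampling cell size (mm)
#' @param seed integer seed for the model-D fat blob placement
#' @param output_dir optional directory for CSV/VTK/isoline exports
#' @return object of class `run_config`
#' @export
run_config <- function(models = LETTERS[1:6], currents = c(19, 22, 25),
                       threshold = 1000,
                       geometry = geometry_spec(), scar = scar_spec(),
                       tissues = tissue_properties(),
                       solver = solver_settings(),
                       mesh = list(h_fine = 0.05, h_coarse = 1.5,
                                   h_lesion = 0.15),
                       resample_h = 0.025, seed = 1L, output_dir = NULL) {
  stopifnot(all(models %in% LETTERS[1:6]), all(currents > 0), threshold > 0)
  structure(list(models = models, currents = currents,
                 threshold = threshold, geometry = geometry, scar = scar,
                 tissues = tissues, solver = solver, mesh = mesh,
                 resample_h = resample_h, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full model x current experiment
#'
#' For each wall model the mesh is built once; currents are solved in
#' increasing order so each solve warm-starts from the previous
#' conductivity state. Solver failures are recorded per row and the run
#' continues.
#'
#' @param cfg a [run_config()]
#' @param verbose print per-run progress
#' @return data.frame with one row per (model, current): applied voltage,
#'   delivered current, lesion depth and surface width (mm), fat-clamping
#'   flag, satellite count and solver diagnostics
#' @export
run_experiment <- function(cfg = run_config(), verbose = interactive()) {
  rows <- list()
  for (m in cfg$models) {
    map <- build_model(m, cfg$geometry,
                       if (m %in% c("C", "D", "E", "F")) cfg$scar,
                       seed = cfg$seed)
    mesh <- do.call(generate_mesh, c(list(map), cfg$mesh))
    sol <- NULL
    for (I in sort(cfg$currents)) {
      row <- data.frame(model = m, current_A = I, V_applied = NA_real_,
                        I_delivered = NA_real_, depth_mm = NA_real_,
                        surface_width_mm = NA_real_, volume_mm3 = NA_real_,
                        clamped_to_fat = NA, n_satellites = NA_integer_,
                        picard_iters = NA_integer_,
                        n_nodes = mesh$n_nodes, error = "",
                        stringsAsFactors = FALSE)
      res <- tryCatch({
        sol <- solve_at_current(mesh, cfg$tissues, I, cfg$solver,
                                V_init = if (!is.null(sol))
                                  sol$V_applied else 2000)
        les <- lesion_size(sol, cfg$threshold, h = cfg$resample_h)
        row$V_applied <- sol$V_applied
        row$I_delivered <- sol$I_delivered
        row$depth_mm <- les$depth
        row$surface_width_mm <- les$surface_width
        row$volume_mm3 <- les$volume
        row$clamped_to_fat <- les$clamped_to_fat
        row$n_satellites <- les$n_satellites
        row$picard_iters <- sol$picard_iters
        if (!is.null(cfg$output_dir)) {
          dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
          base <- file.path(cfg$output_dir, sprintf("model%s_%gA", m, I))
          write_vtk_solution(sol, paste0(base, "_field.vtk"))
          iso <- extract_isoline(sol, cfg$threshold, h = cfg$resample_h)
          if (length(iso))
            utils::write.csv(
              do.call(rbind, Map(cbind, polyline = seq_along(iso), iso)),
              paste0(base, "_isoline.csv"), row.names = FALSE)
        }
        row
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      if (verbose)
        message(sprintf("model %s at %g A: V = %s, depth = %s mm %s", m, I,
                        format(res$V_applied, digits = 4),
                        format(res$depth_mm, digits = 3),
                        if (nzchar(res$error)) paste0("[", res$error, "]")
                        else ""))
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(cfg$output_dir, "results.csv"),
                     row.names = FALSE)
  }
  out
}

#' Linear lesion-size-vs-current trends
#'
#' Ordinary least-squares slope of lesion depth and surface width against
#' delivered current, per model, plus the pooled mean slopes over every
#' model except the fat-deposition model D (whose depth is clamped by the
#' fat and does not grow with current).
#'
#' @param results a [run_experiment()] table
#' @return list with `per_model` (data.frame of slopes in mm/A) and
#'   `pooled` (named vector: mean depth and width slopes excluding D)
#' @export
fit_trends <- function(results) {
  ok <- !is.na(results$depth_mm)
  results <- results[ok, ]
  models <- unique(results$model)
  per <- do.call(rbind, lapply(models, function(m) {
    d <- results[results$model == m, ]
    if (nrow(d) < 2)
      stop("need at least two currents per model to fit a trend")
    data.frame(model = m,
               slope_depth = unname(stats::coef(
                 stats::lm(depth_mm ~ current_A, data = d))[2]),
               slope_width = unname(stats::coef(
                 stats::lm(surface_width_mm ~ current_A, data = d))[2]))
  }))
  pool <- per[per$model != "D", ]
  list(per_model = per,
       pooled = c(depth = mean(pool$slope_depth),
                  width = mean(pool$slope_width)))
}

#' Serialize / restore an experiment configuration
#'
#' @param cfg a [run_config()]
#' @param path file path (YAML)
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(list(
    models = cfg$models, currents = cfg$currents, threshold = cfg$threshold,
    geometry = unclass(cfg$geometry), scar = unclass(cfg$scar),
    tissues = list(
      sigma0 = stats::setNames(as.list(cfg$tissues$table$sigma0),
                               cfg$tissues$table$label),
      sigma1 = stats::setNames(as.list(cfg$tissues$table$sigma1),
                               cfg$tissues$table$label),
      E_center = cfg$tissues$E_center, E_slope = cfg$tissues$E_slope,
      prefactor = cfg$tissues$prefactor),
    solver = unclass(cfg$solver), mesh = cfg$mesh,
    resample_h = cfg$resample_h, seed = cfg$seed,
    output_dir = cfg$output_dir), path, precision = 17)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$geometry$domain_radius <- y$geometry$domain_radius  # keep names stable
  s0 <- unlist(y$tissues$sigma0)
  s1 <- unlist(y$tissues$sigma1)
  y$scar$fat_blob_size_range <- unlist(y$scar$fat_blob_size_range)
  run_config(
    models = unlist(y$models), currents = unlist(y$currents),
    threshold = y$threshold,
    geometry = do.call(geometry_spec, y$geometry),
    scar = do.call(scar_spec, y$scar),
    tissues = tissue_properties(
      fat_sigma = s0[["FAT"]], myo_sigma0 = s0[["MYOCARDIUM"]],
      myo_sigma1 = s1[["MYOCARDIUM"]], scar_sigma = s0[["FIBROSIS"]],
      blood_sigma = s0[["BLOOD"]], connective_sigma = s0[["CONNECTIVE"]],
      E_center = y$tissues$E_center, E_slope = y$tissues$E_slope,
      prefactor = y$tissues$prefactor),
    solver = do.call(solver_settings, y$solver),
    mesh = y$mesh, resample_h = y$resample_h, seed = y$seed,
    output_dir = y$output_dir)
}
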
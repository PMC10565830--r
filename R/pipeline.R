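#' Load a trajectory ensemble from energy files
#'
#' Expands a directory, glob, or explicit file list into per-trajectory
#' energy files and reads each as one trajectory of the ensemble.
#'
#' @param paths a directory, a glob pattern, or a character vector of
#'   files.
#' @param role system role for the ensemble.
#' @param format `"auto"` (by extension: `.xvg` vs delimited), `"xvg"`, or
#'   `"table"`.
#' @param unit energy unit in the files.
#' @param column XVG series selector ([read_xvg]) — ignored for tables.
#' @param time_col,value_col delimited-table column names ([read_energy_table]).
#' @param atom_count optional atom count for the role.
#' @param stride optional subsampling stride.
#' @return a [trajectory_ensemble].
#' @export
load_ensemble <- function(paths, role, format = c("auto", "xvg", "table"),
                          unit = NULL, column = NULL,
                          time_col = "time", value_col = "energy",
                          atom_count = NA, stride = 1L) {
  format <- match.arg(format)
  files <- character(0)
  for (p in paths) {
    if (dir.exists(p)) {
      files <- c(files, list.files(p, full.names = TRUE,
                                   pattern = "\\.(xvg|csv|tsv|txt)$"))
    } else if (file.exists(p)) {
      files <- c(files, p)
    } else {
      g <- Sys.glob(p)
      if (length(g) == 0L) stop("no files match '", p, "' for role ", role)
      files <- c(files, g)
    }
  }
  files <- sort(unique(files))
  if (length(files) == 0L) stop("no input files for role ", role)
  traces <- lapply(files, function(f) {
    fmt <- if (format != "auto") format
           else if (grepl("\\.xvg$", f)) "xvg" else "table"
    if (fmt == "xvg")
      read_xvg(f, column = column,
               unit = if (is.null(unit)) "kJ/mol" else unit, stride = stride)
    else
      read_energy_table(f, time_col = time_col, value_col = value_col,
                        unit = if (is.null(unit)) "kcal/mol" else unit,
                        stride = stride)
  })
  trajectory_ensemble(traces, role, atom_count = atom_count)
}

default_config <- function() {
  list(format = "auto", unit = NULL, column = NULL,
       time_col = "time", value_col = "energy",
       atom_counts = NULL, stride = 1,
       sem = list(strategy = "max", mode = "pooled"),
       diagnostics = list(convergence = TRUE, heterogeneity = TRUE,
                          n_points = 20, window = 0.2, tol = 0.5),
       benchmark = NULL, output_dir = NULL, seed = NULL)
}

#' Run the full analysis pipeline from a configuration
#'
#' Wires the modules into the complete workflow: read the four system
#' ensembles, estimate the binding enthalpy with reblocked uncertainties,
#' run the convergence and heterogeneity diagnostics, and (optionally)
#' compare against the bundled experimental table. The written report is
#' deterministic for identical config and inputs.
#'
#' @param config a list, or the path of a YAML file, with entries:
#'   `inputs` (named list role -> path/glob, required), and optionally
#'   `format`, `unit`, `column`, `time_col`, `value_col`, `atom_counts`
#'   (named list), `stride`, `sem` (`strategy`, `mode`), `diagnostics`
#'   (`convergence`, `heterogeneity`, `n_points`, `window`, `tol`),
#'   `benchmark` (list with `pdb_id`, optional `limit`), `output_dir`.
#' @return the report (list) invisibly; when `output_dir` is set, writes
#'   `report.json`, `convergence.csv`, and `run.log` there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$inputs) || !all(SYSTEM_ROLES %in% names(cfg$inputs)))
    stop("config must provide 'inputs' for all roles: ",
         paste(SYSTEM_ROLES, collapse = ", "))
  ens <- lapply(SYSTEM_ROLES, function(role) {
    ac <- if (!is.null(cfg$atom_counts)) cfg$atom_counts[[role]] else NA
    tryCatch(
      load_ensemble(cfg$inputs[[role]], role, format = cfg$format,
                    unit = cfg$unit, column = cfg$column,
                    time_col = cfg$time_col, value_col = cfg$value_col,
                    atom_count = if (is.null(ac)) NA else ac,
                    stride = cfg$stride),
      error = function(e)
        stop("while loading role '", role, "': ", conditionMessage(e),
             call. = FALSE))
  })
  names(ens) <- SYSTEM_ROLES
  quad <- build_quadruple(ens$complex, ens$solvent, ens$receptor, ens$ligand)
  est <- delta_h(quad, sem_strategy = cfg$sem$strategy,
                 sem_mode = cfg$sem$mode)
  report <- list(
    package_version = as.character(utils::packageVersion("mdcalor")),
    config_hash = config_hash(cfg),
    delta_h = est$delta_h,
    combined_sem = est$uncertainty$combined_sem,
    per_system_sem = as.list(est$uncertainty$per_system_sem),
    means = as.list(est$means),
    n_trajectories = as.list(est$n_trajectories),
    n_snapshots = as.list(est$n_snapshots))
  conv <- NULL
  if (isTRUE(cfg$diagnostics$convergence)) {
    conv <- convergence_profile(quad, n_points = cfg$diagnostics$n_points,
                                window = cfg$diagnostics$window,
                                tol = cfg$diagnostics$tol)
    report$convergence <- list(final_value = conv$final_value,
                               drift = conv$drift,
                               converged = conv$converged)
  }
  if (isTRUE(cfg$diagnostics$heterogeneity)) {
    het <- trajectory_heterogeneity(quad$complex, quadruple = quad)
    report$heterogeneity <- list(
      n_groups = length(het$groups), gap = het$gap,
      link_threshold = het$link_threshold, flagged = het$flagged,
      group_sizes = as.list(lengths(het$groups)),
      group_delta_h = as.list(het$group_delta_h))
  }
  if (!is.null(cfg$benchmark) && !is.null(cfg$benchmark$pdb_id)) {
    lim <- if (is.null(cfg$benchmark$limit)) 2 else cfg$benchmark$limit
    rec <- itc_benchmark_table()
    cmp <- compare_enthalpies(
      stats::setNames(est$delta_h, cfg$benchmark$pdb_id), rec, limit = lim)
    report$benchmark <- list(pdb_id = cfg$benchmark$pdb_id,
                             exp_delta_h = cmp$per_complex$exp,
                             diff = cmp$per_complex$diff,
                             within_limit = cmp$per_complex$within_limit)
  }
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(conv))
      utils::write.csv(conv$profile,
                       file.path(cfg$output_dir, "convergence.csv"),
                       row.names = FALSE)
    writeLines(c(
      sprintf("mdcalor %s", report$package_version),
      sprintf("config hash: %s", report$config_hash),
      sprintf("trajectories per role: %s",
              paste(names(report$n_trajectories),
                    unlist(report$n_trajectories),
                    sep = "=", collapse = ", ")),
      sprintf("snapshots per role: %s",
              paste(names(report$n_snapshots), unlist(report$n_snapshots),
                    sep = "=", collapse = ", "))),
      file.path(cfg$output_dir, "run.log"))
  }
  invisible(report)
}

config_hash <- function(cfg) {
  # stable short fingerprint without extra dependencies
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                        digits = NA, null = "null", force = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(s)) %% 251 + 1)) %% 4294967296)
}
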
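KJ_PER_KCAL <- 4.184

#' Construct an energy trace
#'
#' An `energy_trace` holds one trajectory's scalar energy time series for a
#' single energy term (e.g. the total potential, or one interaction term).
#' Values are stored internally in kcal/mol regardless of the source unit;
#' kJ/mol input is divided by the exact thermochemical factor 4.184.
#'
#' @param values numeric vector of energies, length >= 2, all finite.
#' @param times numeric vector of timestamps in ps, strictly increasing with
#'   uniform spacing (relative tolerance 1e-6). Defaults to
#'   `(0:(n-1)) * dt`.
#' @param trajectory_id character label identifying the trajectory.
#' @param term energy-term label, e.g. `"Potential"`, `"Coulomb (SR)"`.
#' @param unit unit of `values` as supplied: `"kcal/mol"` or `"kJ/mol"`.
#' @param dt sampling interval in ps; ignored when `times` is given.
#' @return an object of class `energy_trace` with fields `trajectory_id`,
#'   `term`, `times`, `values` (kcal/mol), `source_unit`, `dt`.
#' @export
energy_trace <- function(values, times = NULL, trajectory_id = "traj",
                         term = "Potential",
                         unit = c("kcal/mol", "kJ/mol"), dt = 1) {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("an energy trace needs at least 2 values, got ", length(values))
  if (!all(is.finite(values)))
    stop("non-finite energy values in trajectory '", trajectory_id, "'")
  if (is.null(times)) {
    if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
      stop("'dt' must be a single positive number (ps)")
    times <- (seq_along(values) - 1) * dt
  } else {
    times <- as.numeric(times)
    if (length(times) != length(values))
      stop("'times' and 'values' differ in length")
    d <- diff(times)
    if (any(d <= 0))
      stop("timestamps must be strictly increasing")
    if (length(d) > 1L && max(abs(d - d[1])) > 1e-6 * abs(d[1]))
      stop("non-uniform time spacing beyond relative tolerance 1e-6")
    dt <- d[1]
  }
  if (unit == "kJ/mol") values <- values / KJ_PER_KCAL
  structure(
    list(trajectory_id = as.character(trajectory_id), term = as.character(term),
         times = times, values = values, source_unit = unit, dt = dt),
    class = "energy_trace")
}

#' @export
print.energy_trace <- function(x, ...) {
  cat(sprintf("energy_trace '%s' [%s]: %d snapshots, dt = %g ps, mean = %.4f kcal/mol\n",
              x$trajectory_id, x$term, length(x$values), x$dt, mean(x$values)))
  invisible(x)
}

#' @export
length.energy_trace <- function(x) length(x$values)

#' Read a GROMACS XVG energy file
#'
#' Parses the Grace XVG dialect emitted by `gmx energy`: lines starting with
#' `#` are comments, lines starting with `@` are plot metadata (including
#' `@ sN legend "term"` lines naming the data series), and data rows are
#' whitespace-separated numbers with time in the first column.
#'
#' @param path path to the XVG file.
#' @param column series selector: a legend name (e.g. `"Potential"`) or a
#'   1-based data-column index (not counting the time column). When `NULL`
#'   and the file holds a single series, that series is read.
#' @param unit unit of the energies in the file; GROMACS writes kJ/mol,
#'   which is the default and is converted to kcal/mol on read.
#' @param trajectory_id label for the resulting trace; defaults to the file
#'   name without extension.
#' @param stride keep every `stride`-th row (default 1 = no subsampling).
#' @return an [energy_trace].
#' @export
read_xvg <- function(path, column = NULL, unit = c("kJ/mol", "kcal/mol"),
                     trajectory_id = NULL, stride = 1L) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(lines, "#")
  is_meta <- startsWith(lines, "@")
  legends <- character(0)
  leg <- regmatches(lines[is_meta],
                    regexec("^@\\s*s(\\d+)\\s+legend\\s+\"([^\"]*)\"", lines[is_meta]))
  for (m in leg) if (length(m) == 3L) legends[as.integer(m[2]) + 1L] <- m[3]
  data_idx <- which(!is_comment & !is_meta & nzchar(trimws(lines)))
  if (length(data_idx) == 0L) stop("no data rows in ", path)
  fields <- strsplit(trimws(lines[data_idx]), "\\s+")
  ncol <- length(fields[[1]])
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(fields, use.names = FALSE)),
           ncol = ncol, byrow = TRUE))
  bad <- which(!stats::complete.cases(mat) | lengths(fields) != ncol)
  if (length(bad))
    stop("non-numeric or ragged data at line ", data_idx[bad[1]], " of ", path)
  nseries <- ncol - 1L
  if (is.null(column)) {
    if (nseries != 1L)
      stop("file has ", nseries, " series; pick one of: ",
           paste(if (length(legends)) legends else seq_len(nseries), collapse = ", "))
    sel <- 1L
  } else if (is.numeric(column)) {
    sel <- as.integer(column)
    if (sel < 1L || sel > nseries)
      stop("column index ", sel, " out of range 1..", nseries)
  } else {
    sel <- match(column, legends)
    if (is.na(sel))
      stop("no series legend '", column, "' in ", path, "; available: ",
           paste(legends, collapse = ", "))
  }
  term <- if (sel <= length(legends) && !is.na(legends[sel])) legends[sel]
          else if (is.character(column)) column else "Potential"
  stride <- max(1L, as.integer(stride))
  keep <- seq(1L, nrow(mat), by = stride)
  if (is.null(trajectory_id))
    trajectory_id <- sub("\\.[^.]*$", "", basename(path))
  energy_trace(mat[keep, sel + 1L], times = mat[keep, 1L],
               trajectory_id = trajectory_id, term = term, unit = unit)
}

#' Write an energy trace to an XVG file
#'
#' Inverse of [read_xvg]; values are converted back to the requested unit.
#'
#' @param trace an [energy_trace].
#' @param path output path.
#' @param unit unit to write the energies in.
#' @export
write_xvg <- function(trace, path, unit = c("kJ/mol", "kcal/mol")) {
  unit <- match.arg(unit)
  v <- trace$values
  if (unit == "kJ/mol") v <- v * KJ_PER_KCAL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# trajectory %s", trace$trajectory_id),
    "@    title \"Energies\"",
    "@    xaxis  label \"Time (ps)\"",
    sprintf("@    yaxis  label \"(%s)\"", unit),
    sprintf("@ s0 legend \"%s\"", trace$term)), con)
  writeLines(sprintf("%.10g %.17g", trace$times, v), con)
  invisible(path)
}

#' Read an energy trace from a delimited table
#'
#' Accepts comma- or tab-delimited text with a header row. The delimiter is
#' auto-detected from the header line unless given.
#'
#' @param path path to the file.
#' @param time_col,value_col names of the time (ps) and energy columns.
#' @param unit unit of the energy column.
#' @param delim `","`, `"\t"`, or `NULL` to auto-detect.
#' @param trajectory_id,term labels for the resulting trace; defaults as in
#'   [read_xvg].
#' @param stride keep every `stride`-th row.
#' @return an [energy_trace].
#' @export
read_energy_table <- function(path, time_col = "time", value_col = "energy",
                              unit = c("kcal/mol", "kJ/mol"), delim = NULL,
                              trajectory_id = NULL, term = "Potential",
                              stride = 1L) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  if (is.null(delim))
    delim <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.delim(path, sep = delim, check.names = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path)
  for (cn in c(time_col, value_col))
    if (!cn %in% names(df))
      stop("column '", cn, "' not found in ", path, "; available: ",
           paste(names(df), collapse = ", "))
  stride <- max(1L, as.integer(stride))
  keep <- seq(1L, nrow(df), by = stride)
  if (is.null(trajectory_id))
    trajectory_id <- sub("\\.[^.]*$", "", basename(path))
  energy_trace(df[[value_col]][keep], times = df[[time_col]][keep],
               trajectory_id = trajectory_id, term = term, unit = unit)
}

#' Write an energy trace as CSV
#'
#' @param trace an [energy_trace].
#' @param path output path.
#' @param unit unit for the energy column.
#' @export
write_energy_table <- function(trace, path, unit = c("kcal/mol", "kJ/mol")) {
  unit <- match.arg(unit)
  v <- trace$values
  if (unit == "kJ/mol") v <- v * KJ_PER_KCAL
  df <- data.frame(time = trace$times, energy = v)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

SYSTEM_ROLES <- c("complex", "solvent", "receptor", "ligand")

#' Bundle traces of one simulated system into an ensemble
#'
#' @param traces list of [energy_trace] objects sharing one term label and
#'   source unit, with unique trajectory ids.
#' @param system_role one of `"complex"`, `"solvent"`, `"receptor"`,
#'   `"ligand"` — the four boxes of the direct method.
#' @param atom_count number of atoms in the simulation box, or `NA` when
#'   unknown (then the atom-balance check is skipped with a warning).
#' @return an object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(traces, system_role, atom_count = NA) {
  system_role <- match.arg(system_role, SYSTEM_ROLES)
  if (inherits(traces, "energy_trace")) traces <- list(traces)
  if (length(traces) < 1L) stop("ensemble needs at least one trace")
  if (!all(vapply(traces, inherits, logical(1), "energy_trace")))
    stop("'traces' must be energy_trace objects")
  ids <- vapply(traces, `[[`, character(1), "trajectory_id")
  if (anyDuplicated(ids))
    stop("duplicate trajectory ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  terms <- unique(vapply(traces, `[[`, character(1), "term"))
  if (length(terms) > 1L)
    stop("mixed energy terms in one ensemble: ", paste(terms, collapse = ", "))
  units <- unique(vapply(traces, `[[`, character(1), "source_unit"))
  if (length(units) > 1L)
    stop("mixed source units in one ensemble: ", paste(units, collapse = ", "))
  lens <- vapply(traces, function(t) length(t$values), integer(1))
  if (length(unique(lens)) > 1L)
    warning("trajectories of unequal length (", min(lens), "..", max(lens),
            "); each still contributes one equally weighted mean")
  names(traces) <- ids
  structure(list(system_role = system_role, traces = traces,
                 atom_count = atom_count),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  ns <- sum(vapply(x$traces, function(t) length(t$values), integer(1)))
  cat(sprintf("trajectory_ensemble [%s]: K = %d trajectories, %d snapshots total, term '%s'\n",
              x$system_role, length(x$traces), ns, x$traces[[1]]$term))
  invisible(x)
}

trajectory_ids <- function(ensemble) names(ensemble$traces)

#' Assemble the four-system quadruple of the direct method
#'
#' The direct (multibox) method computes the binding enthalpy from four
#' simulations: the solvated complex, a pure-water box, the apo receptor in
#' water and the free peptide in water. Atom counts must balance between the
#' bound side (complex + water) and the unbound side (receptor + ligand) so
#' that the potential energies are comparable; the check is enforced
#' whenever all four counts are supplied.
#'
#' @param complex,solvent,receptor,ligand [trajectory_ensemble] objects with
#'   the matching `system_role`.
#' @return an object of class `system_quadruple`.
#' @export
build_quadruple <- function(complex, solvent, receptor, ligand) {
  ens <- list(complex = complex, solvent = solvent,
              receptor = receptor, ligand = ligand)
  for (role in SYSTEM_ROLES) {
    e <- ens[[role]]
    if (!inherits(e, "trajectory_ensemble"))
      stop("'", role, "' is not a trajectory_ensemble")
    if (e$system_role != role)
      stop("ensemble passed as '", role, "' has role '", e$system_role, "'")
  }
  units <- unique(vapply(ens, function(e) e$traces[[1]]$source_unit, character(1)))
  if (length(units) > 1L)
    stop("mixed source units across roles: ", paste(units, collapse = ", "))
  counts <- vapply(ens, function(e) as.numeric(e$atom_count), numeric(1))
  if (all(!is.na(counts))) {
    bound <- counts["complex"] + counts["solvent"]
    unbound <- counts["receptor"] + counts["ligand"]
    if (bound != unbound)
      stop(sprintf("atom counts do not balance: complex + solvent = %d, receptor + ligand = %d",
                   as.integer(bound), as.integer(unbound)))
  } else {
    warning("atom counts absent for some roles; atom-balance check skipped")
  }
  structure(ens, class = "system_quadruple")
}

#' @export
print.system_quadruple <- function(x, ...) {
  cat("system_quadruple:\n")
  for (role in SYSTEM_ROLES) {
    e <- x[[role]]
    ns <- sum(vapply(e$traces, function(t) length(t$values), integer(1)))
    cat(sprintf("  %-9s K = %2d, snapshots = %d\n", role, length(e$traces), ns))
  }
  invisible(x)
}
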
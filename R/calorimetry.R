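#' Ensemble mean energy over independent trajectories
#'
#' The expected energy of a system is the unweighted mean of the K
#' per-trajectory means: each trajectory contributes equally regardless of
#' its length, so a trajectory trapped in a metastable state carries the
#' same weight as any other. A pooled-snapshot weighting (the grand mean of
#' all snapshots) is available but non-default; the two coincide when all
#' trajectories have equal length.
#'
#' @param ensemble a [trajectory_ensemble].
#' @param weighting `"trajectory"` (default) or `"snapshot"`.
#' @return mean energy in kcal/mol.
#' @export
ensemble_mean <- function(ensemble, weighting = c("trajectory", "snapshot")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  if (length(ensemble$traces) == 0L) stop("empty ensemble")
  if (weighting == "trajectory") {
    mean(vapply(ensemble$traces, function(t) mean(t$values), numeric(1)))
  } else {
    mean(unlist(lapply(ensemble$traces, `[[`, "values"), use.names = FALSE))
  }
}

#' Quadrature combination of per-system SEMs
#'
#' The binding enthalpy is an additive combination of four independent mean
#' energies, so its SEM is the square root of the sum of squared
#' per-system SEMs.
#'
#' @param per_system_sem numeric vector of per-system SEMs (kcal/mol), all
#'   non-negative; typically named by role.
#' @return list of class `uncertainty_estimate` with `per_system_sem` and
#'   `combined_sem`.
#' @export
sem_delta_h <- function(per_system_sem) {
  s <- as.numeric(per_system_sem)
  if (any(!is.finite(s)) || any(s < 0))
    stop("per-system SEMs must be finite and non-negative")
  structure(list(per_system_sem = per_system_sem,
                 combined_sem = sqrt(sum(s^2))),
            class = "uncertainty_estimate")
}

#' Pressure-volume correction hook
#'
#' The pV contribution to the binding enthalpy at ambient pressure is
#' negligible for condensed-phase systems; this hook exists so the term is
#' explicit in the bookkeeping, and returns zero.
#'
#' @param quadruple a [build_quadruple] result (unused).
#' @return 0 (kcal/mol).
#' @export
pv_correction <- function(quadruple) 0

#' Absolute binding enthalpy by the direct method
#'
#' Computes `dH = <E>_complex + <E>_solvent - <E>_receptor - <E>_ligand`
#' from the four system ensembles: the bound state is the solvated complex
#' plus a pure-water box, the unbound state the apo receptor and the free
#' peptide each in water. Atom counts balance between the two sides, so
#' the large solvent self-energies cancel in expectation and the residual
#' difference is the binding enthalpy. Per-system SEMs come from
#' reblocking ([ensemble_sem]) and combine in quadrature. No
#' pressure-volume term is added (see [pv_correction]).
#'
#' @param quadruple a [build_quadruple] result; all traces must share one
#'   energy term.
#' @param sem_strategy `"max"` (conservative default) or `"heuristic"`,
#'   passed to [select_sem].
#' @param sem_mode `"pooled"` or `"per-trajectory"`, see [ensemble_sem].
#' @param weighting trajectory-mean weighting, see [ensemble_mean].
#' @return object of class `enthalpy_estimate`: `delta_h` (kcal/mol),
#'   `uncertainty` ([sem_delta_h] result), `means` (per role),
#'   `n_trajectories` and `n_snapshots` (per role), `term`, and
#'   `components` (NULL; see [decompose_enthalpy]).
#' @export
delta_h <- function(quadruple, sem_strategy = c("max", "heuristic"),
                    sem_mode = c("pooled", "per-trajectory"),
                    weighting = c("trajectory", "snapshot")) {
  sem_strategy <- match.arg(sem_strategy)
  sem_mode <- match.arg(sem_mode)
  weighting <- match.arg(weighting)
  stopifnot(inherits(quadruple, "system_quadruple"))
  terms <- unique(vapply(quadruple,
                         function(e) e$traces[[1]]$term, character(1)))
  if (length(terms) > 1L)
    stop("mixed energy terms across roles: ", paste(terms, collapse = ", "))
  means <- vapply(quadruple, ensemble_mean, numeric(1), weighting = weighting)
  sems <- vapply(quadruple,
                 function(e) as.numeric(ensemble_sem(e, sem_strategy, sem_mode)),
                 numeric(1))
  dh <- means[["complex"]] + means[["solvent"]] -
    means[["receptor"]] - means[["ligand"]] + pv_correction(quadruple)
  structure(
    list(delta_h = dh,
         uncertainty = sem_delta_h(sems),
         means = means,
         n_trajectories = vapply(quadruple, function(e) length(e$traces),
                                 integer(1)),
         n_snapshots = vapply(quadruple, function(e)
           sum(vapply(e$traces, function(t) length(t$values), integer(1))),
           integer(1)),
         term = terms, components = NULL),
    class = "enthalpy_estimate")
}

#' @export
print.enthalpy_estimate <- function(x, ...) {
  cat(sprintf("binding enthalpy (direct method): dH = %.4f +/- %.4f kcal/mol [term '%s']\n",
              x$delta_h, x$uncertainty$combined_sem, x$term))
  cat(sprintf("  K = %s trajectories; N = %s snapshots\n",
              paste(x$n_trajectories, collapse = "/"),
              paste(x$n_snapshots, collapse = "/")))
  if (!is.null(x$components)) {
    cm <- x$components
    cat(sprintf("  components: Val %.2f +/- %.2f, Coul %.2f +/- %.2f, LJ %.2f +/- %.2f\n",
                cm$val, cm$sem["val"], cm$coul, cm$sem["coul"],
                cm$lj, cm$sem["lj"]))
  }
  invisible(x)
}

#' Default GROMACS energy-term grouping for the decomposition
#'
#' Maps GROMACS energy-file term names onto the three physical components
#' of the binding enthalpy: valence (bond stretch, angle bend, dihedral),
#' Coulomb electrostatics (short-range plus reciprocal-space), and
#' Lennard-Jones (short-range plus dispersion correction). Restraint terms
#' are deliberately absent and should be warned about upstream.
#'
#' @return named list of character vectors for groups `val`, `coul`, `lj`.
#' @export
gromacs_term_groups <- function() {
  list(val = c("Bond", "Angle", "Proper Dih.", "Improper Dih."),
       coul = c("Coulomb (SR)", "Coul. recip."),
       lj = c("LJ (SR)", "Disp. corr."))
}

#' Decompose the binding enthalpy into Val/Coul/LJ components
#'
#' Applies the direct-method balance independently to each term group, so
#' that when the per-snapshot component energies sum to the total potential,
#' the component enthalpies sum to the total binding enthalpy. Each
#' component carries its own quadrature SEM.
#'
#' @param group_quadruples named list with entries `val`, `coul`, `lj`,
#'   each a [build_quadruple] of traces for that term group.
#' @param ... passed to [delta_h] (SEM strategy/mode, weighting).
#' @return object of class `energy_components`: component values `val`,
#'   `coul`, `lj` (kcal/mol), `sem` (named vector), `total` (their sum),
#'   `total_sem` (quadrature), and `estimates` (the per-group
#'   [delta_h] results).
#' @export
decompose_enthalpy <- function(group_quadruples, ...) {
  groups <- c("val", "coul", "lj")
  missing <- setdiff(groups, names(group_quadruples))
  if (length(missing))
    stop("missing term group(s): ", paste(missing, collapse = ", "))
  est <- lapply(group_quadruples[groups], delta_h, ...)
  vals <- vapply(est, `[[`, numeric(1), "delta_h")
  sems <- vapply(est, function(e) e$uncertainty$combined_sem, numeric(1))
  structure(list(val = vals[["val"]], coul = vals[["coul"]], lj = vals[["lj"]],
                 sem = sems, total = sum(vals), total_sem = sqrt(sum(sems^2)),
                 estimates = est),
            class = "energy_components")
}

#' @export
print.energy_components <- function(x, ...) {
  cat(sprintf("enthalpy components (kcal/mol): Val %.2f +/- %.2f, Coul %.2f +/- %.2f, LJ %.2f +/- %.2f; sum %.2f +/- %.2f\n",
              x$val, x$sem["val"], x$coul, x$sem["coul"], x$lj, x$sem["lj"],
              x$total, x$total_sem))
  invisible(x)
}
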
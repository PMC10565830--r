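#' Cumulative-average convergence profile of the binding enthalpy
#'
#' Recomputes the binding enthalpy on growing prefixes of the data: for
#' each fraction f of the grid, every trajectory of all four systems is
#' truncated to its first `ceiling(f * length)` snapshots and the direct
#' method is re-applied. Truncating every trajectory proportionally (rather
#' than concatenating) keeps both within-trajectory drift and
#' between-trajectory disagreement visible in the profile. The drift
#' statistic is the absolute difference between the enthalpy estimated
#' from only the trailing window of every trajectory (by default the last
#' 20 percent of snapshots) and the full cumulative value; data whose tail
#' still disagrees with the whole by more than the tolerance are flagged
#' as not converged.
#'
#' @param quadruple a [build_quadruple] result.
#' @param n_points number of grid points (fractions `1/n .. 1`), >= 2.
#' @param window trailing fraction of each trajectory used for the drift
#'   statistic, in (0, 1); default 0.2 (the last 20 percent).
#' @param tol convergence tolerance in kcal/mol; default 0.5, one quarter
#'   of the 2 kcal/mol accuracy band used when judging predictions against
#'   experiment.
#' @param weighting passed to [ensemble_mean].
#' @return object of class `convergence_profile`: data frame `profile`
#'   (`fraction`, `cumulative_delta_h`), `final_value`, `drift`,
#'   `converged`, `tol`, `window`.
#' @export
convergence_profile <- function(quadruple, n_points = 20L, window = 0.2,
                                tol = 0.5,
                                weighting = c("trajectory", "snapshot")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(quadruple, "system_quadruple"))
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("grid needs at least 2 points")
  if (!(window > 0 && window < 1)) stop("'window' must be in (0, 1)")
  fractions <- seq_len(n_points) / n_points
  # cumulative sums per trace make each truncated mean O(1)
  csums <- lapply(quadruple, function(e)
    lapply(e$traces, function(t) cumsum(t$values)))
  lens <- lapply(quadruple, function(e)
    vapply(e$traces, function(t) length(t$values), numeric(1)))
  role_mean_at <- function(role, f) {
    cs <- csums[[role]]
    ln <- lens[[role]]
    k <- pmax(1, ceiling(f * ln))
    m <- vapply(seq_along(cs), function(i) cs[[i]][k[i]] / k[i], numeric(1))
    if (weighting == "trajectory") mean(m) else sum(m * k) / sum(k)
  }
  # mean over only the last `window` fraction of each trajectory
  role_tail_mean <- function(role) {
    cs <- csums[[role]]
    ln <- lens[[role]]
    j <- pmax(1, ln - ceiling(window * ln))  # window starts after index j
    m <- vapply(seq_along(cs), function(i) {
      tot <- cs[[i]][ln[i]] - cs[[i]][j[i]]
      tot / (ln[i] - j[i])
    }, numeric(1))
    if (weighting == "trajectory") mean(m) else sum(m * (ln - j)) / sum(ln - j)
  }
  cum_dh <- vapply(fractions, function(f)
    role_mean_at("complex", f) + role_mean_at("solvent", f) -
      role_mean_at("receptor", f) - role_mean_at("ligand", f), numeric(1))
  final <- cum_dh[n_points]
  tail_dh <- role_tail_mean("complex") + role_tail_mean("solvent") -
    role_tail_mean("receptor") - role_tail_mean("ligand")
  drift <- abs(tail_dh - final)
  structure(list(profile = data.frame(fraction = fractions,
                                      cumulative_delta_h = cum_dh),
                 final_value = final, drift = drift,
                 converged = drift <= tol, tol = tol, window = window),
            class = "convergence_profile")
}

#' @export
print.convergence_profile <- function(x, ...) {
  cat(sprintf("convergence_profile: final dH = %.4f kcal/mol, drift (last %.0f%%) = %.4f, %s at tol %.2g\n",
              x$final_value, 100 * x$window, x$drift,
              if (x$converged) "converged" else "NOT converged", x$tol))
  invisible(x)
}

#' Detect metastable-state heterogeneity across trajectories
#'
#' Independent trajectories trapped in different conformational substates
#' (a folded terminal tail, a transient helix) show up as well-separated
#' per-trajectory mean energies, which directly bias the ensemble mean.
#' This detector clusters the K per-trajectory means on the real line by
#' single linkage: means are sorted and split wherever the gap between
#' neighbours exceeds the merge threshold. The ensemble is flagged when at
#' least two groups each contain at least two trajectories — one stray
#' trajectory is noise, two coherent populations are a sampling problem.
#'
#' Externally derived group labels (e.g. from a structural clustering of
#' the trajectories) can be supplied via `groups` and are then used as-is.
#'
#' @param ensemble a [trajectory_ensemble] with K >= 2.
#' @param link_threshold merge threshold in kcal/mol; default 3 times the
#'   pooled per-trajectory SEM, `3 * sqrt(mean(sem_t^2))` with `sem_t` from
#'   per-trajectory reblocking.
#' @param groups optional externally supplied partition: a named vector or
#'   list mapping trajectory ids to group labels.
#' @param quadruple,role optional: the full [build_quadruple] and the role
#'   of `ensemble` within it; when given, the binding enthalpy is
#'   recomputed per group (that role restricted to the group, the other
#'   three ensembles untouched).
#' @return object of class `heterogeneity_report`: `per_trajectory_means`,
#'   `groups` (list of id vectors, ordered by group mean),
#'   `group_means`, `gap` (largest separation between adjacent groups, 0
#'   for a single group), `link_threshold`, `flagged`, and `group_delta_h`
#'   (named numeric, NA-free only when `quadruple` is supplied).
#' @export
trajectory_heterogeneity <- function(ensemble, link_threshold = NULL,
                                     groups = NULL, quadruple = NULL,
                                     role = NULL) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  K <- length(ensemble$traces)
  if (K < 2L) stop("heterogeneity detection needs at least 2 trajectories")
  means <- vapply(ensemble$traces, function(t) mean(t$values), numeric(1))
  if (is.null(link_threshold)) {
    sems <- vapply(ensemble$traces,
                   function(t) reblock(t$values)$selected_sem, numeric(1))
    link_threshold <- 3 * sqrt(mean(sems^2))
  }
  if (is.null(groups)) {
    ord <- order(means)
    gaps <- diff(means[ord])
    cut_after <- which(gaps > link_threshold)
    grp_id <- cumsum(c(1L, as.integer(seq_len(K - 1L) %in% cut_after)))
    part <- split(names(means)[ord], grp_id)
  } else {
    labels <- unlist(groups)
    if (!setequal(names(labels), names(means)))
      stop("'groups' must label exactly the ensemble's trajectory ids")
    part <- split(names(labels), labels)
    part <- part[order(vapply(part, function(ids) mean(means[ids]), numeric(1)))]
  }
  names(part) <- paste0("group", seq_along(part))
  gmeans <- vapply(part, function(ids) mean(means[ids]), numeric(1))
  gap <- if (length(part) < 2L) 0 else {
    # single-linkage separation between adjacent groups on the line
    seps <- vapply(seq_len(length(part) - 1L), function(i)
      min(means[part[[i + 1L]]]) - max(means[part[[i]]]), numeric(1))
    max(seps)
  }
  flagged <- sum(lengths(part) >= 2L) >= 2L
  gdh <- stats::setNames(rep(NA_real_, length(part)), names(part))
  if (!is.null(quadruple)) {
    if (is.null(role)) role <- ensemble$system_role
    for (g in names(part)) {
      sub <- stats::setNames(list(part[[g]]), role)
      gdh[g] <- conditional_delta_h(quadruple, sub)$delta_h
    }
  }
  structure(list(per_trajectory_means = means, groups = part,
                 group_means = gmeans, gap = gap,
                 link_threshold = link_threshold, flagged = flagged,
                 group_delta_h = gdh),
            class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("heterogeneity_report: %d group(s), gap = %.3f kcal/mol (threshold %.3f), %s\n",
              length(x$groups), x$gap, x$link_threshold,
              if (x$flagged) "FLAGGED: multiple populated states" else "not flagged"))
  for (g in names(x$groups))
    cat(sprintf("  %s: %d trajectories, mean %.4f%s\n", g,
                length(x$groups[[g]]), x$group_means[g],
                if (is.na(x$group_delta_h[g])) ""
                else sprintf(", dH %.4f", x$group_delta_h[g])))
  invisible(x)
}

restrict_ensemble <- function(ensemble, ids) {
  if (length(ids) == 0L)
    stop("empty trajectory subset for role '", ensemble$system_role, "'")
  unknown <- setdiff(ids, names(ensemble$traces))
  if (length(unknown))
    stop("unknown trajectory id(s) for role '", ensemble$system_role, "': ",
         paste(unknown, collapse = ", "))
  trajectory_ensemble(ensemble$traces[ids], ensemble$system_role,
                      ensemble$atom_count)
}

#' Binding enthalpy conditioned on a trajectory subset
#'
#' Recomputes the direct-method enthalpy with one or more ensembles
#' restricted to named trajectories — e.g. only the complex trajectories in
#' which a binding-competent conformation (helix formed, tail docked) was
#' observed. Roles absent from `subset` keep their full ensembles. With a
#' single trajectory per role the SEM still comes from within-trajectory
#' reblocking.
#'
#' @param quadruple a [build_quadruple] result.
#' @param subset named list mapping roles to character vectors of
#'   trajectory ids; each given subset must be non-empty and contained in
#'   that role's ensemble.
#' @param ... passed to [delta_h].
#' @return an `enthalpy_estimate` (see [delta_h]) with attribute
#'   `"subset_sizes"` recording the number of trajectories used per role.
#' @export
conditional_delta_h <- function(quadruple, subset, ...) {
  stopifnot(inherits(quadruple, "system_quadruple"))
  bad <- setdiff(names(subset), SYSTEM_ROLES)
  if (length(bad))
    stop("unknown role(s) in subset: ", paste(bad, collapse = ", "))
  ens <- lapply(SYSTEM_ROLES, function(role) {
    if (role %in% names(subset))
      restrict_ensemble(quadruple[[role]], subset[[role]])
    else quadruple[[role]]
  })
  names(ens) <- SYSTEM_ROLES
  sub_quad <- suppressWarnings(
    build_quadruple(ens$complex, ens$solvent, ens$receptor, ens$ligand))
  est <- delta_h(sub_quad, ...)
  attr(est, "subset_sizes") <- vapply(ens, function(e) length(e$traces),
                                      integer(1))
  est
}
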
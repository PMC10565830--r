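#' Ornstein-Uhlenbeck parameters for a synthetic energy trace
#'
#' Sampled at a fixed interval, an OU process is a first-order
#' autoregressive series with lag-1 coefficient `phi = exp(-dt/tau)` — a
#' minimal stand-in for fluctuating MD potential energies: stationary,
#' Gaussian, exponentially autocorrelated.
#'
#' @param mu stationary mean (kcal/mol).
#' @param sigma stationary standard deviation (kcal/mol), >= 0.
#' @param tau correlation time (ps), >= 0; `tau = 0` gives white noise.
#' @param dt sampling interval (ps), > 0.
#' @return object of class `ou_params` with the implied `phi`.
#' @export
ou_params <- function(mu, sigma, tau, dt) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma >= 0,
            is.finite(tau), tau >= 0, is.finite(dt), dt > 0)
  phi <- if (tau == 0) 0 else exp(-dt / tau)
  structure(list(mu = mu, sigma = sigma, tau = tau, dt = dt, phi = phi),
            class = "ou_params")
}

#' Generate one synthetic energy trace
#'
#' Exact discretization of the OU process: `E_0 ~ N(mu, sigma^2)`,
#' `E_{i+1} = mu + phi (E_i - mu) + eps_i` with
#' `eps_i ~ N(0, sigma^2 (1 - phi^2))`, so every snapshot has the exact
#' stationary marginal. A fixed seed gives bit-reproducible output.
#'
#' @param params an [ou_params].
#' @param n number of snapshots, >= 2.
#' @param seed integer seed for this trace's private stream.
#' @param trajectory_id,term labels for the trace.
#' @param mu_override optional mean replacing `params$mu` (used for
#'   metastable-state offsets).
#' @return an [energy_trace] in kcal/mol.
#' @export
gen_trace <- function(params, n, seed, trajectory_id = "synth",
                      term = "Potential", mu_override = NULL) {
  stopifnot(inherits(params, "ou_params"), n >= 2)
  mu <- if (is.null(mu_override)) params$mu else mu_override
  set.seed(as.integer(seed))
  dev <- if (params$sigma == 0) {
    rep(0, n)
  } else {
    innov <- c(stats::rnorm(1L, 0, params$sigma),
               stats::rnorm(n - 1L, 0, params$sigma * sqrt(1 - params$phi^2)))
    if (params$phi == 0) innov
    else as.numeric(stats::filter(innov, params$phi, method = "recursive"))
  }
  energy_trace(mu + dev, trajectory_id = trajectory_id, term = term,
               unit = "kcal/mol", dt = params$dt)
}

norm_offsets <- function(so) {
  if (is.null(so)) return(NULL)
  so <- as.data.frame(so)
  stopifnot(all(c("offset", "weight") %in% names(so)))
  if (abs(sum(so$weight) - 1) > 1e-9)
    stop("state-offset mixture weights must sum to 1")
  so
}

role_spec <- function(params, K, N, state_offsets = NULL) {
  stopifnot(inherits(params, "ou_params"), K >= 1, N >= 2)
  list(params = params, K = as.integer(K), N = as.integer(N),
       state_offsets = norm_offsets(state_offsets))
}

#' Define a synthetic four-system study with known ground truth
#'
#' Declares, per system role, the OU parameters, the number of independent
#' trajectories K, the snapshots per trajectory N, and optionally a set of
#' metastable-state mean offsets with mixture weights (each trajectory is
#' assigned one state for its whole length, emulating trajectories trapped
#' in distinct conformational substates). The ground-truth binding
#' enthalpy is exactly recomputable from the declaration:
#' `mu_complex + mu_solvent - mu_receptor - mu_ligand` with each mean
#' mixture-weighted over its state offsets.
#'
#' Defaults mirror the sampling design of a production study: K = 20
#' trajectories for the solvated complex and the apo receptor, K = 10 for
#' the peptide-in-water and water-only boxes; energy fluctuations of
#' sigma = 30 kcal/mol with a 1 ps correlation time sampled every 0.1 ps;
#' N = 1e5 snapshots per trajectory; system means chosen so the true
#' binding enthalpy is -8.00 kcal/mol.
#'
#' @param complex,solvent,receptor,ligand per-role lists as built by the
#'   defaults: `list(params = ou_params(...), K =, N =, state_offsets =)`.
#'   `state_offsets` is `NULL` or a data frame with columns `offset`
#'   (kcal/mol) and `weight` (summing to 1).
#' @param seed integer base seed; each trajectory derives a private stream
#'   from it by a fixed counter offset, so adding trajectories or roles
#'   never perturbs earlier ones.
#' @return object of class `synthetic_study_spec` with `roles`, `seed`,
#'   `true_delta_h`, and `true_state_delta_h` (per role with offsets: the
#'   enthalpy conditional on that role sitting in each state, other roles
#'   at their mixture means).
#' @export
synthetic_study_spec <- function(
    complex = list(params = ou_params(-100, 30, 1, 0.1), K = 20, N = 1e5),
    solvent = list(params = ou_params(-50, 30, 1, 0.1), K = 10, N = 1e5),
    receptor = list(params = ou_params(-80, 30, 1, 0.1), K = 20, N = 1e5),
    ligand = list(params = ou_params(-62, 30, 1, 0.1), K = 10, N = 1e5),
    seed = 1L) {
  roles <- list(complex = complex, solvent = solvent,
                receptor = receptor, ligand = ligand)
  roles <- lapply(roles, function(r)
    role_spec(r$params, r$K, r$N, r$state_offsets))
  sign <- c(complex = 1, solvent = 1, receptor = -1, ligand = -1)
  wmean <- vapply(roles, function(r) {
    m <- r$params$mu
    if (!is.null(r$state_offsets))
      m <- m + sum(r$state_offsets$offset * r$state_offsets$weight)
    m
  }, numeric(1))
  true_dh <- sum(sign * wmean)
  state_dh <- list()
  for (role in names(roles)) {
    so <- roles[[role]]$state_offsets
    if (!is.null(so)) {
      # enthalpy if this role sat entirely in state s, others at mixture means
      base_wo <- true_dh - sign[[role]] *
        sum(so$offset * so$weight)
      state_dh[[role]] <- stats::setNames(
        base_wo + sign[[role]] * so$offset,
        paste0("state", seq_len(nrow(so))))
    }
  }
  structure(list(roles = roles, seed = as.integer(seed),
                 true_delta_h = true_dh, true_state_delta_h = state_dh),
            class = "synthetic_study_spec")
}

# fixed counter offsets: role index * 1000 + trajectory index (+ group * 1e5
# for component traces); base seeds are kept below 1e9 so sums stay well
# under .Machine$integer.max
stream_seed <- function(base, role, t, group = 0L) {
  role_i <- match(role, SYSTEM_ROLES)
  (as.integer(base) %% 1000000000L) + 100000L * group + 1000L * role_i + t
}

sample_states <- function(rspec, base, role) {
  so <- rspec$state_offsets
  if (is.null(so)) return(rep(NA_integer_, rspec$K))
  vapply(seq_len(rspec$K), function(t) {
    set.seed(stream_seed(base, role, t) + 500L)
    sample.int(nrow(so), 1L, prob = so$weight)
  }, integer(1))
}

#' Generate a synthetic system quadruple with known ground truth
#'
#' Draws K independent OU traces per role under the study spec. When a
#' role carries state offsets, each trajectory first samples its state
#' (from its own stream) and keeps that mean shift for its whole length —
#' the synthetic analogue of a trajectory trapped in one conformational
#' substate.
#'
#' @param spec a [synthetic_study_spec].
#' @return list with `quadruple` (a [build_quadruple] result),
#'   `true_delta_h`, `true_state_delta_h`, and `state_assignments` (per
#'   role, the sampled state index per trajectory, NA without offsets).
#' @export
gen_quadruple <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  states <- list()
  ens <- list()
  for (role in SYSTEM_ROLES) {
    r <- spec$roles[[role]]
    st <- sample_states(r, spec$seed, role)
    states[[role]] <- stats::setNames(st, sprintf("%s%02d", role, seq_len(r$K)))
    traces <- lapply(seq_len(r$K), function(t) {
      mu <- r$params$mu
      if (!is.na(st[t])) mu <- mu + r$state_offsets$offset[st[t]]
      gen_trace(r$params, r$N, stream_seed(spec$seed, role, t),
                trajectory_id = sprintf("%s%02d", role, t),
                mu_override = mu)
    })
    ens[[role]] <- suppressWarnings(trajectory_ensemble(traces, role))
  }
  quad <- suppressWarnings(build_quadruple(ens$complex, ens$solvent,
                                           ens$receptor, ens$ligand))
  list(quadruple = quad, true_delta_h = spec$true_delta_h,
       true_state_delta_h = spec$true_state_delta_h,
       state_assignments = states)
}

#' Generate component traces whose per-snapshot sum is the total
#'
#' For each role and trajectory, three OU component traces (val, coul, lj)
#' are drawn and the total-potential trace is defined as their per-snapshot
#' sum, so the decomposition additivity of [decompose_enthalpy] is exact by
#' construction. Component means split the role mean by `proportions`;
#' component standard deviations are `sigma / sqrt(3)` each.
#'
#' @param spec a [synthetic_study_spec] (state offsets are not supported
#'   here and must be absent).
#' @param proportions length-3 numeric summing to 1: the share of each
#'   role's mean assigned to val, coul, lj.
#' @return list with quadruples `val`, `coul`, `lj`, `total`, plus
#'   `true_delta_h` and per-component truths `true_components`.
#' @export
gen_component_quadruples <- function(spec,
                                     proportions = c(val = 0.1, coul = 0.3,
                                                     lj = 0.6)) {
  stopifnot(inherits(spec, "synthetic_study_spec"),
            abs(sum(proportions) - 1) < 1e-9)
  if (any(!vapply(spec$roles, function(r) is.null(r$state_offsets), logical(1))))
    stop("component generation does not support state offsets")
  groups <- c("val", "coul", "lj")
  quads <- list()
  for (g in seq_along(groups)) {
    ens <- list()
    for (role in SYSTEM_ROLES) {
      r <- spec$roles[[role]]
      gp <- ou_params(r$params$mu * proportions[[g]],
                      r$params$sigma / sqrt(3), r$params$tau, r$params$dt)
      traces <- lapply(seq_len(r$K), function(t)
        gen_trace(gp, r$N, stream_seed(spec$seed, role, t, group = g),
                  trajectory_id = sprintf("%s%02d", role, t),
                  term = groups[g]))
      ens[[role]] <- suppressWarnings(trajectory_ensemble(traces, role))
    }
    quads[[groups[g]]] <- suppressWarnings(build_quadruple(
      ens$complex, ens$solvent, ens$receptor, ens$ligand))
  }
  total_ens <- list()
  for (role in SYSTEM_ROLES) {
    r <- spec$roles[[role]]
    traces <- lapply(seq_len(r$K), function(t) {
      v <- Reduce(`+`, lapply(groups, function(g)
        quads[[g]][[role]]$traces[[t]]$values))
      energy_trace(v, trajectory_id = sprintf("%s%02d", role, t),
                   term = "Potential", unit = "kcal/mol", dt = r$params$dt)
    })
    total_ens[[role]] <- suppressWarnings(trajectory_ensemble(traces, role))
  }
  sign <- c(complex = 1, solvent = 1, receptor = -1, ligand = -1)
  mus <- vapply(spec$roles, function(r) r$params$mu, numeric(1))
  true_comp <- vapply(seq_along(groups), function(g)
    sum(sign * mus * proportions[[g]]), numeric(1))
  names(true_comp) <- groups
  list(val = quads$val, coul = quads$coul, lj = quads$lj,
       total = suppressWarnings(build_quadruple(
         total_ens$complex, total_ens$solvent,
         total_ens$receptor, total_ens$ligand)),
       true_delta_h = spec$true_delta_h, true_components = true_comp)
}
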
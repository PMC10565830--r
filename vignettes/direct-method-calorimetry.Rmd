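---
title: "Absolute binding enthalpies by the direct method: models, uncertainties, diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute binding enthalpies by the direct method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdcalor)
```

## The model

Isothermal titration calorimetry measures the binding enthalpy ΔH of a
protein–peptide association directly. The direct (multibox) computational
route estimates the same quantity as a difference of mean potential
energies over four separately simulated boxes:

$$\Delta H \;=\; \langle E\rangle_\mathrm{complex}
  + \langle E\rangle_\mathrm{solvent}
  - \langle E\rangle_\mathrm{receptor}
  - \langle E\rangle_\mathrm{ligand}$$

with the solvated complex and a pure-water box on the bound side and the
apo receptor and free peptide (each in water) on the unbound side. The
critical bookkeeping constraint — enforced by `build_quadruple()` whenever
atom counts are supplied — is that atoms balance exactly between the two
sides, so the enormous solvent self-energies cancel in expectation and
the O(10) kcal/mol binding signal survives the O(10⁵) kcal/mol absolute
energies. The pressure–volume term is negligible at ambient pressure;
`pv_correction()` exists as an explicit hook and returns zero.

Each $\langle E\rangle$ is an ensemble average over K independent
trajectories,

$$\langle E\rangle = \frac{1}{K}\sum_{t=1}^{K}
  \frac{1}{N_t}\sum_{n=1}^{N_t} E_{t,n},$$

the *unweighted mean of per-trajectory means*: a trajectory trapped in a
metastable conformational substate contributes exactly one vote, no more,
regardless of its length. `ensemble_mean()` implements this as the
default; a pooled-snapshot weighting is available
(`weighting = "snapshot"`) and coincides with it for equal-length
trajectories. Traces of unequal length are accepted with a warning for
the same reason.

## Uncertainty: pairwise reblocking

Energy snapshots 100 fs apart are strongly autocorrelated, so the naive
SEM underestimates the true uncertainty by roughly
$\sqrt{(1+\varphi)/(1-\varphi)}$ for lag-1 correlation $\varphi$.
`reblock()` applies Flyvbjerg–Petersen blocking: average adjacent
non-overlapping pairs, recompute the SEM from the unbiased variance of
the $m$ block values ($\mathrm{sem} = \sqrt{s^2/m}$, with uncertainty
$\mathrm{sem}/\sqrt{2(m-1)}$), and recurse until fewer than two blocks
remain. A trailing odd element is discarded at each level rather than
truncating the input to a power of two up front. Once the block size
exceeds the correlation length the estimates plateau at the true SEM.

Two selection rules are exposed by `select_sem()`:

* **`"max"`** (default): the maximum SEM over all levels with ≥ 2
  blocks. This is deliberately conservative — it can only overestimate —
  and in practice sits some tens of percent above the plateau because the
  few-block levels fluctuate widely (their relative sd is
  $1/\sqrt{2(m-1)}$).
* **`"heuristic"`**: estimate the correlation length at each level as
  $n_\mathrm{corr} = (\mathrm{sem}_B/\mathrm{sem}_0)^2$ — the statistical
  inefficiency, constant at the plateau — and take the smallest block
  size with $B^3 \ge 2\,n\,n_\mathrm{corr}^2$. On AR(1) test data
  ($\varphi = 0.9$, $n = 2^{15}$) this lands within a few percent of the
  closed-form SEM; if no level qualifies it falls back to `"max"` with a
  warning.

For an ensemble, `ensemble_sem()` defaults to reblocking the pooled
concatenation of trajectories (in trajectory-id order): block boundaries
spanning independent trajectories can only *reduce* apparent correlation,
keeping the max-rule estimate conservative. A per-trajectory mode
combines individual SEMs as $\sqrt{\sum_t \mathrm{sem}_t^2}/K$, the SEM
of the unweighted mean of means. Per-system SEMs combine in quadrature
(`sem_delta_h()`), since ΔH is an additive combination of four
independent means.

## Decomposition

`decompose_enthalpy()` applies the same four-box balance per energy-term
group: **Val** (bond stretch, angle bend, dihedral), **Coul**
(short-range Coulomb plus reciprocal-space), **LJ** (short-range
Lennard-Jones plus dispersion correction). `gromacs_term_groups()` gives
the default mapping from GROMACS energy-file term names; restraint terms
are excluded. When the per-snapshot component energies sum to the total
potential, the component enthalpies sum to the total ΔH to floating-point
accuracy — the synthetic generator (`gen_component_quadruples()`)
constructs data with this property so the invariant is testable
end to end.

## Sampling diagnostics

The dominant failure mode of the direct method is not force-field error
but *conformational trapping*: a subset of trajectories stuck in a
substate (a mis-docked terminal tail, an unformed helix) whose mean
energy differs by several kcal/mol, which biases the equally weighted
ensemble mean directly. Two diagnostics operationalize this:

**Convergence** (`convergence_profile()`): ΔH is recomputed on growing
prefixes — every trajectory truncated to its first ⌈f·N⌉ snapshots for a
grid of fractions f — so within-trajectory drift and between-trajectory
disagreement both remain visible (concatenation would hide the former).
The drift statistic compares the enthalpy estimated from only the
trailing window of every trajectory (default: the last 20 %) with the
full cumulative value; this choice makes a slow ramp of amplitude
2 kcal/mol produce a drift of 0.8 kcal/mol (the tail of the ramp averages
1.8 versus a full mean of 1.0), which correctly fails the default
tolerance. The alternative — averaging the cumulative profile itself over
the trailing grid — is nearly proportional to the final value by
construction and detects almost nothing. Note the statistic is
stochastic, with a standard deviation of roughly twice the combined SEM
for stationary data, so the default tolerance of 0.5 kcal/mol (one
quarter of the 2 kcal/mol accuracy band used against experiment) is a
meaningful test only once the SEM is a few tenths of a kcal/mol or
better, i.e. at production data volumes. Both tolerance and window are
arguments.

**Heterogeneity** (`trajectory_heterogeneity()`): the quantity that
actually biases the estimate is the set of per-trajectory mean energies,
so the detector works directly on those (a structure-space clustering can
be supplied as external labels via `groups` and is used verbatim).
Single-linkage clustering on the real line reduces to sorting means and
cutting gaps larger than the merge threshold, which defaults to 3× the
pooled per-trajectory reblocked SEM — gaps that mere estimation noise
could plausibly produce are not split. An ensemble is flagged when at
least two groups each hold at least two trajectories: one stray
trajectory is noise, two coherent populations are a sampling problem.
`conditional_delta_h()` then recomputes ΔH on a named trajectory subset
(e.g. only binding-competent complex trajectories), with SEMs from the
restricted ensembles; a single trajectory per role still yields a finite
SEM from within-trajectory blocking.

## Benchmarking

`compare_enthalpies()` reports per-complex differences, a within-limit
flag (default 2 kcal/mol), RMSE, and R². R² is the *squared Pearson
correlation* of calculated versus experimental values by default; the
coefficient of determination about the identity line is available
(`r2_method = "identity"`) but is largely redundant with RMSE. The
bundled tables carry the 11-complex experimental ITC set (with printed
uncertainties, which are carried through but not used as weights) and the
corresponding Val/Coul/LJ component values. The component sums and the
headline experimental values were produced by different trajectory
subsets in the source data, so small inconsistencies between the two
tables (≈ 0.1 kcal/mol for one complex) are preserved verbatim rather
than reconciled.

## The synthetic generator

`gen_trace()` draws exact-discretization Ornstein–Uhlenbeck series:
$E_0 \sim N(\mu, \sigma^2)$,
$E_{i+1} = \mu + \varphi(E_i - \mu) + \varepsilon_i$ with
$\varepsilon_i \sim N(0, \sigma^2(1-\varphi^2))$ and
$\varphi = e^{-\Delta t/\tau}$. This reproduces the second-order
statistics that the estimator actually consumes — a stationary mean,
a marginal variance, an exponential correlation time — and, through
per-trajectory state offsets with mixture weights, the metastable
between-trajectory structure that breaks it. It does *not* emulate slow
intra-trajectory transitions between states, fat-tailed energy
fluctuations, or equilibration transients; passing tests therefore show
the estimator is correct for stationary, Gaussian, exponentially
correlated input with trajectory-level trapping, not that any given MD
data set satisfies those assumptions.

Each trajectory derives a private seed from the study seed by a fixed
counter offset (role index × 1000 + trajectory index, + 10⁵ × group for
component traces), so enlarging a study never perturbs existing
trajectories. Default study conditions: K = 20 trajectories for complex
and receptor, 10 for solvent and ligand; σ = 30 kcal/mol, τ = 1 ps,
Δt = 0.1 ps (φ ≈ 0.905); N = 10⁵ snapshots per trajectory; system means
(−100, −50, −80, −62) kcal/mol giving a ground truth of −8.00 kcal/mol.
These give a combined SEM of ≈ 0.25 kcal/mol — the same order as a
production study's per-component uncertainties — while keeping a
50-replicate validation run in the minutes range. Where a sharper
statistical target needed smaller fluctuations (the convergence-rate
check), tests use σ of a few kcal/mol and say so inline; the
heterogeneity checks use N = 2048 so the within-state per-trajectory SEM
is ≈ 0.5 kcal/mol against an 8 kcal/mol state gap.

## Numerical choices and edge cases

* Internal unit is kcal/mol everywhere; kJ/mol input (the GROMACS
  default) is divided by exactly 4.184 on read and multiplied back on
  write, a lossless linear map.
* Timestamps must be strictly increasing and uniform to a relative
  tolerance of 10⁻⁶; XVG values are written with 17 significant digits so
  round trips are exact to double precision.
* Zero-variance series reblock to SEM 0 at every level (not an error);
  series shorter than 4 points are rejected.
* The SEM at each blocking level uses the unbiased (m−1) variance over m
  blocks; conventions dividing by m differ by O(1/m).
* Single-linkage ties at exactly the threshold merge (strict `>` splits).
* `NA` atom counts skip the balance check with a warning instead of
  failing, since energy files alone do not carry atom counts.

## Limitations

The package analyses energy time series; it does not run MD, parse
binary energy/trajectory formats (export XVG or CSV first), compute
secondary structure or hydrogen bonds, or estimate free energies or
entropies. The heterogeneity detector sees only energetic signatures of
metastability — substates with near-identical mean energies are invisible
to it, though external structural labels can be supplied. And the
2 kcal/mol benchmark band is an accuracy statement about the estimator
given converged sampling; the diagnostics can flag non-convergence but
cannot manufacture the missing conformational transitions.
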
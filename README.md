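# mdcalor

Computational calorimetry from molecular dynamics energy ensembles:
absolute protein–peptide binding enthalpies by the direct (multibox)
method, with reblocked uncertainties, component decomposition,
sampling diagnostics, and benchmarking against experimental isothermal
titration calorimetry (ITC) data.

## Who this is for

Simulators who run plain MD of a protein–peptide complex and want the
binding enthalpy ΔH — the quantity ITC measures directly — without
alchemical transformations or temperature derivatives, plus honest error
bars and a way to tell when conformational sampling, not the force field,
is what broke the prediction.

## The method

The binding enthalpy is the difference of mean potential energies between
the bound and unbound states, each represented by solvated simulation
boxes whose atom counts balance exactly:

    ΔH = ⟨E⟩_complex + ⟨E⟩_solvent − ⟨E⟩_receptor − ⟨E⟩_ligand

where the four terms are time-averaged potential energies of (1) the
solvated complex, (2) a pure-water box, (3) the apo receptor in water,
and (4) the free peptide in water. The pressure–volume contribution is
negligible at ambient conditions and is not added.

Each ⟨E⟩ is the unweighted mean of K independent trajectories' means
(K trajectories sample the conformational landscape far better than one
long run of the same total length). Because snapshots are strongly
autocorrelated, the SEM of each mean comes from Flyvbjerg–Petersen
pairwise reblocking: block the series into pairs, re-estimate, and repeat
until the estimate plateaus; the package defaults to the conservative
maximum over blocking levels, with an optimal-block-size heuristic as an
alternative. The four SEMs combine in quadrature:

    σ(ΔH) = sqrt(σ²_complex + σ²_solvent + σ²_receptor + σ²_ligand)

The same balance applied per energy-term group splits ΔH into valence
(bond/angle/dihedral), Coulomb, and Lennard-Jones components. Two
diagnostics target the dominant failure mode — trajectories trapped in
metastable conformational states: a cumulative-average convergence
profile with a drift statistic, and single-linkage clustering of
per-trajectory mean energies that flags multi-modal ensembles.

## Worked example

Synthetic study with known ground truth ΔH = −8.00 kcal/mol (20/10/20/10
trajectories of 10⁴ snapshots, fluctuations of 30 kcal/mol with a 1 ps
correlation time):

```r
library(mdcalor)
spec <- synthetic_study_spec(
  complex  = list(params = ou_params(-100, 30, 1, 0.1), K = 20, N = 1e4),
  solvent  = list(params = ou_params(-50, 30, 1, 0.1),  K = 10, N = 1e4),
  receptor = list(params = ou_params(-80, 30, 1, 0.1),  K = 20, N = 1e4),
  ligand   = list(params = ou_params(-62, 30, 1, 0.1),  K = 10, N = 1e4),
  seed = 42)
g <- gen_quadruple(spec)
delta_h(g$quadruple)
#> binding enthalpy (direct method): dH = -9.1916 +/- 0.8677 kcal/mol [term 'Potential']
#>   K = 20/10/20/10 trajectories; N = 200000/100000/200000/100000 snapshots
convergence_profile(g$quadruple)
#> convergence_profile: final dH = -9.1916 kcal/mol, drift (last 20%) = 0.7534, NOT converged at tol 0.5
```

The truth (−8.00) sits within 1.4 combined SEM of the estimate, and the
convergence diagnostic correctly reports that 10⁴ snapshots per
trajectory are not enough for a sub-0.5 kcal/mol call at this noise
level — at the production scale of 10⁶ snapshots the same profile
converges and the SEM drops by an order of magnitude.

Benchmarking component-sum predictions against the bundled experimental
ITC table:

```r
comp <- enthalpy_components_table()
calc <- setNames(comp$val + comp$coul + comp$lj, comp$pdb_id)
compare_enthalpies(calc, components = comp)
#> benchmark_report: 11 complexes, RMSE = 1.59 kcal/mol, R^2 = 0.89, 8/11 within 2 kcal/mol
#>  pdb_id   calc    exp exp_sem  diff within_limit
#>    1DPU -15.24 -16.80    0.28  1.56         TRUE
#>    1RST -10.06 -12.56    0.09  2.50        FALSE
#>    2LQC  -7.63  -6.91    0.07 -0.72         TRUE
#>    ...
#> Pearson r of components vs experimental dH:
#>   val  coul    lj
#> -0.11  0.52  0.29
```

The 2LQC row reproduces the 0.72 kcal/mol calculated-vs-experimental
difference; the Coulomb component correlates with the experimental
enthalpies at r = 0.52, while valence and Lennard-Jones components show
little linear relationship — electrostatics carry most of the
across-complex signal.

A shell front end wrapping the same functions ships in `inst/cli/`:

```sh
inst/cli/mdcalor simulate --out sim/ --seed 7 --n 10000
inst/cli/mdcalor compute-dh --complex 'sim/complex/*.xvg' --solvent 'sim/solvent/*.xvg' \
    --receptor 'sim/receptor/*.xvg' --ligand 'sim/ligand/*.xvg'
inst/cli/mdcalor benchmark --calc calculated.csv
```

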
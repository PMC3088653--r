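# cellcontour

Contour dynamics of a cell membrane coupled to curvature-sensing membrane
proteins.

`cellcontour` simulates a one-dimensional membrane contour — either a closed
curve (the outline of a spread cell) or a periodic flat edge segment in Monge
representation — coupled to a single conserved species of convex,
curvature-sensing protein complexes that locally recruit protrusive forces:
actin polymerization (a normal push proportional to coverage) and adhesion
(an energy gain that lowers the local effective membrane tension).  The
positive feedback between membrane shape and protein transport spontaneously
produces protrusions that grow, migrate and coalesce, reproducing
filopodium-like tents (adhesion-dominated), lamellipodium-like fans
(actin-dominated) and crescent, motile-looking shapes.

The model is a Helfrich-type free energy (curvature mismatch, tension with
optional nonlinear hardening, adhesion, harmonic pinning, mixing entropy,
direct protein aggregation) whose exact discrete gradients drive overdamped
normal motion, plus a finite-volume conservation law for the coverage with
four tangential currents (curvature attraction, dispersion, direct
aggregation, thermal diffusion).  A full linear stability analysis (flat and
round geometries) is built in and is cross-checked against the nonlinear
simulator by the test suite.  The integrator core is compiled (Rcpp);
million-step runs take seconds.

See the methods vignette (`vignettes/membrane-shape-model.Rmd`) for the
model, the numerical scheme, parameter choices and the reproduced
phenomenology.

## Quick start

Simulate an adhesion-driven flat membrane segment from seeded noise to its
single-protrusion steady state:

```r
library(cellcontour)

p <- model_params(alpha_adh = 3600)     # adhesion strength above onset

## where is onset, and what grows fastest?
critical_boundary(model_params(), "alpha")$value
#> [1] 1516.983
mu <- most_unstable_mode(p)
c(mu$omega_max, mu$lambda_max)
#> [1] 1.042659 1.456915                 # 1/s, um

## run: 8 um segment, 51 nodes, seeded coverage noise
st <- init_flat(p, N = 51, L = 8, spec = init_spec(rng_seed = 1))
tr <- run(st, p, run_config(t_end = 3000, record_dt = 4, safety = 0.35))
tr
#> trajectory: 751 records to t = 3000 s (t_end); final amplitude 0.6796 um,
#>   1 protrusion(s)

coalescence_time(tr)                    # protrusions merged into one at...
#> [1] 228 s
count_protrusions(tr$state)
#> [1] 1

## the steady coverage tracks the curvature (H ~ Hbar * phi + const)
steady_state_density_curvature_check(tr$state, p)$rank_correlation
#> [1] 0.9841629

## protein mass is conserved to rounding error
s <- tr$summary
max(abs(s$M_total / s$M_total[1] - 1))
#> [1] 7.571721e-14
```

Round-geometry linear stability (mode 1 is a rigid translation and is
exactly neutral):

```r
dispersion_round(0:4, p)
#>   q omega_minus   omega_plus
#> 1 0  -0.8112118 1.734723e-18
#> 2 1  -0.2246929 0.000000e+00
#> 3 2  -0.8765572 4.748463e-02
#> 4 3  -1.9871826 1.259275e-01
#> 5 4  -3.5913356 2.327702e-01
```

Other entry points: `init_round()` + `run()` for closed-cell simulations,
`force_breakdown()` / `flux_breakdown()` for per-node diagnostics,
`dispersion_flat()`, `classify_regime()`, `critical_boundary()` for the
phase diagram, `coalescence_scan()`, `protrusion_count_vs_driver()`,
`crescent_scan()`, `net_active_force()` for the headline analyses, and
`load_config()` / `write_snapshot()` / `write_manifest()` for file I/O.

## Command line

A thin CLI wraps the exported functions:

```sh
Rscript inst/cli/cellcontour.R simulate --config cfg.yaml --seed 7 --out out/
Rscript inst/cli/cellcontour.R stability --out out/
Rscript inst/cli/cellcontour.R scan-coalescence --seed 1 --out out/
```

Subcommands: `simulate`, `stability`, `phase-diagram`, `scan-coalescence`,
`scan-counts`, `scan-crescent`, `analyze`.  Configuration is YAML (sections
`params`, `init`, `run`, plus `geometry`, `N`, `L`); outputs are CSV, and
every artifact-producing command writes a JSON run manifest with checksums.

## Tests

```r
testthat::test_dir("tests/testthat", package = "cellcontour",
                   load_package = "installed")
```

`tests/testthat/test-acceptance.R` holds the end-to-end phenomenology
checks (one block per criterion).  One criterion — the combined-force
orderings — is knowingly unmet by this calibration and its test fails
honestly; see the vignette ("Combined forces") for the analysis.

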
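# saim

Simulators for two architectures of the **selective attention for
identification model (SAIM)**, a neural-network account of how a visual
system selects one object among several and identifies it in a
translation-invariant way.

Three coupled networks share the work: a *Selection Network* performs a
winner-take-all over candidate focus-of-attention (FOA) placements, a
linear *Contents Network* holds the FOA contents routed from the image by
multiplicative (Sigma-pi) gating, and a *Knowledge Network* identifies the
contents by template matching. Every unit descends one global energy
(soft constraint satisfaction in the Hopfield–Tank style), integrated by a
noisy Euler scheme

x(t) = x(t−1) − η ∂E/∂y + ξ,  ξ ~ N(0, σ),

and the simulated reaction time (RT) is the number of iterations until a
template unit's rate first crosses a threshold. The package implements
both feedback architectures:

- **EM** (excitatory matching): top-down terms are matching terms entering
  with negative sign — object knowledge *boosts* consistent contents, and
  contents boost consistent locations. Energy components include the
  winner-take-all form `a/2 (Σy − 1)² − b Σ y·I`.
- **PE** (prediction error): the same constraints recast as Gaussian
  log-densities, i.e. half-squared prediction errors
  `ε_CN = I_CN − x_CN` and `ε_KN,k = x_CN − y_k·w_k`; all coupling flows
  through subtracted predictions (inhibitory feedback) and the location
  competition becomes a loser-take-all over unexplained input.

Both variants reproduce the classic **multiple-object cost**: adding a
non-target object to the scene slows identification, with zero
recognition errors on single-object scenes — and they make diverging
predictions about measurable population activity, which the package also
computes. Analytic gradients of both energies are verified against finite
differences in the test suite.

## A worked example

```r
library(saim)

templates <- saim_templates(size = 7)      # "+" and "2" bitmaps, M = 7
scenes <- reference_scenes(templates)      # single +, single 2, and +/2

# one noisy run on the two-object scene
run_em(scenes$both, templates, seed = 42)
#> <saim_result> em run, seed 42
#>   rt: 910 iterations; winner: plus

# the three-condition study: 20 seeded runs per condition + pooled t-tests
study <- compare_conditions("em", templates, saim_params("em"),
                            scenes, n_runs = 20, base_seed = 1)
study
#> <saim_study> em three-condition study, 20 runs each
#>   single +  mean rt   641.0 (sd  36.1)  errors 0  timeouts 0
#>   single 2  mean rt   797.5 (sd  22.0)  errors 0  timeouts 0
#>   +/2       mean rt   940.5 (sd  80.7)  errors 0  timeouts 0
#>   +/2 vs +  t(38) =  15.15, p = 1.1e-17
#>   +/2 vs 2  t(38) =   7.64, p = 3.4e-09
#>   2 vs +    t(38) =  16.55, p = 5.8e-19
```

The two-object scene costs roughly 150–300 iterations over either single
object (a highly significant contrast at 20 runs per condition), no run
misidentifies its object, and the cross always wins the two-object
competition. `run_pe()` / `compare_conditions("pe", ...)` run the
prediction-error variant the same way; `plot_activation()`,
`plot_study()` and `neuronal_response()` visualise single runs, batch
RTs, and the simulated population-activity time courses whose trends
distinguish the two feedback schemes.

A command-line interface over the same functions ships in
`inst/cli/saim.R`:

```sh
Rscript inst/cli/saim.R simulate  --config cfg.yaml --seed 1 --out out/
Rscript inst/cli/saim.R compare   --config cfg.yaml --out out/
Rscript inst/cli/saim.R gradcheck
```

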
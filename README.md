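# neurogeom

Tools for asking *how* learning improves a neural population code.

Perceptual training makes stimuli more discriminable from population
activity — in spiking data, BOLD responses and artificial networks alike —
but the improvement can arrive through very different changes in the
geometry of the trial-by-trial response distributions. `neurogeom`
estimates stimulus-conditioned response manifolds, computes the averaged
linear Fisher information (aLFI)

    aLFI = (1/n) · df' Σ̄⁻¹ df / Δθ²

(with `df` the signal vector between the two condition means, `Σ̄` the
pooled covariance, `n` the unit count and `Δθ` the stimulus separation),
and decomposes a pre-to-post change in aLFI into four geometric mechanisms
via the eigendecomposition form of the information:

| mechanism          | geometric change                                   |
|--------------------|----------------------------------------------------|
| signal enhancement | signal separation `|df|` grows                     |
| manifold shrinkage | mean variance λ̄ of Σ̄ falls                         |
| signal rotation    | direction of `df` changes vs the covariance axes   |
| manifold warping   | eigenstructure changes at fixed total variance     |

The four marginal contributions telescope exactly onto the total
information change. The package also provides the surrounding toolkit:
single-unit metrics (tuning curves, Fano factor, noise/signal
correlations, threshold-versus-noise interpolation), cross-validated linear
decoding (Fisher linear discriminant and logistic readouts, half-split /
10-fold / leave-one-trial-out schemes, sliding time-window search), a
moment-based multivariate Poisson log-normal estimator for spike counts,
and a synthetic population generator that injects each mechanism with
analytically known information gains, so everything is testable against
exact ground truth.

## Worked example

Simulate a learning episode on a direction-tuned population (20 units,
45° vs 49° discrimination) in which training rotates the signal vector by
60° and halves the covariance — strong manifold shrinkage and no signal
enhancement — then recover the decomposition from 1,000 sampled trials per
condition:

```r
library(neurogeom)

spec <- population_spec(n_units = 20, period = 360, stimulus_pair = c(45, 49),
                        preferred_stimuli = seq(5, 85, length.out = 20),
                        tuning_amplitude = 60, tuning_width = 20, corr_decay = 60)
pre_geom <- make_population(spec)
inj <- apply_mechanism(pre_geom, list(mech_rotation(60, plane = "signal"),
                                      mech_shrinkage(0.5)))
inj$truth
#> <ground_truth: rotation+shrinkage; aLFI 0.025544 -> 0.02473>
#>   gains: se=+6.9389e-18, ms=+0.025544, sr=-0.026359, mw=+0

pre  <- sample_trials(pre_geom, 1000, seed = 1, phase = "pre")
post <- sample_trials(inj$post, 1000, seed = 2, phase = "post")
g_pre  <- estimate_geometry(pre)
g_post <- estimate_geometry(post)
stepwise_decomposition(g_pre, g_post)
#> <stepwise_decomposition: n=20, dtheta=4>
#>   aLFI pre 0.0255247 -> post 0.0256641 (gain 0.000139448)
#>   marginal contributions:
#>     se +0.000361224
#>     ms +0.0262289
#>     sr -0.0283665
#>     mw +0.00191576
#>   signal rotation angle 63.76 deg

pc_comparison(g_pre, g_post)
#> <geometry_comparison: 20 matched PCs at 99% coverage>
#>   PC rotation angles (deg): 6.8, 17.5, 50.5, ...
#>   total variance pre 1201 -> post 596.5
```

Reading the output: the analytic ground truth says shrinkage alone would
have added +0.0255 aLFI while the 60° rotation removed a comparable amount
(their near-cancellation is why the *total* gain is small even though both
geometric changes are pronounced). The estimates from sampled trials
recover this pattern — dominant positive shrinkage contribution, near-zero
enhancement, a 63.8° measured rotation angle, and total variance halved
(1201 → 596).

A thin command-line front end over the same functions is installed at
`inst/cli/neurogeom` (subcommands `validate`, `simulate`, `filter`,
`select-top`, `metrics`, `decode`, `decompose`, `pln-fit`, `run`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/neurogeom", package="neurogeom"))')" \
  decompose --pre pre.csv --post post.csv --dtheta 4
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it simulates the rotation-plus-shrinkage learning scenario above at the
given seed, executes the full pipeline (unit filtering, geometry
estimation, stepwise decomposition, PC comparison, decoding), prints the
recovered quantities against the analytic ground truth, and writes the
JSON summary to the requested path:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/neural-geometry.Rmd`) describes the model
and its assumptions, the estimator's finite-sample bias, the synthetic
generator's scope, numerical conventions, and known limitations. Function
reference lives in the roxygen comments in `R/`.
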
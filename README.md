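# odekinetics

Kinetic modeling of genomic time series with the logistic ODE.

## The problem

Developmental time courses of gene expression (RNA-seq, log2 TPM) and
chromatin accessibility (DNase-/ATAC-seq) are short — often eight time
points — and noisy, yet each series hides an interpretable kinetic story:
how fast a gene ramps up or shuts down, and how close it is to saturation.
`odekinetics` is for computational biologists who want to compress such
series into two biophysically meaningful parameters and reason about them
genome-wide.

A signal `z(t)` constrained to `[a, b]` is modeled with the generalized
logistic ODE

    dz/dt = k (z − a) (1 − (z − a)/(b − a))

where `k` is the growth/decay rate constant (per day; `k > 0` activated,
`k < 0` repressed) and `b` the saturation level. Because three-parameter
fits are unstable on eight points, each series is min–max normalized
(to `[1e-5, 1]` or, for deceleration-phase profiles, to `[1 + 1e-5, 2]`)
and fit with the simplified form

    dy*/dt = k* y* (1 − y*/b*),   y*(t_start) = y*_start

whose closed-form solution is fitted by nonlinear least squares over
`(k*, b*)` from four initial-guess/range combinations; the lowest-MSE
candidate wins and its parameters are mapped back to the original units
(`k` is invariant). The inflection

    t_switch = (1/k*) ln(b*/y*_start − 1) + t_start

classifies every feature as a **switcher** (inflection inside the observed
window), **decelerator** (before it) or **accelerator** (after it).

On top of the fitter the package provides preprocessing (batch correction,
positive shift, quantile normalization, polynomial time-course testing),
fit-quality triage with a two-component Gaussian mixture on the MSEs,
piecewise two-segment fits for peak-shaped profiles, cCRE-to-nearest-gene
linking with enhancer/silencer and mono-/poly-pattern annotation, a
bidirectional recurrent network that predicts a gene's expression
trajectory from up to 60 linked cCRE accessibility tracks, and seeded
synthetic-data generators for every component.

## Worked example

```r
library(odekinetics)

spec <- simulation_spec(n_features = 100, noise_sd_fraction = 0.02, seed = 7)
sim  <- simulate_logistic_matrix(spec)        # 100 x 8 matrix + truth table
res  <- fit_matrix(sim$matrix, sim$times)     # fit every row

head(res$params[, c("feature_id", "converged", "range_used", "k", "b",
                    "mse", "t_switch", "kinetic_class")], 5)
#>   feature_id converged range_used      k    b      mse t_switch kinetic_class
#> 1     feat_1      TRUE    shifted -0.703 2.88 2.26e-04     21.0   accelerator
#> 2     feat_2      TRUE    shifted  0.646 8.16 2.46e-04     10.5   decelerator
#> 3     feat_3      TRUE       unit -1.227 4.01 3.11e-05     11.4      switcher
#> 4     feat_4      TRUE    shifted  1.389 5.47 2.02e-04     10.5   decelerator
#> 5     feat_5      TRUE    shifted  0.539 5.03 3.33e-04     10.5   decelerator

fit_gmm2(res$params$mse[res$params$converged])
#> <gmm_partition> means 0.000295 / 0.006048, sds 0.000179 / 0.00636, weights 0.92 / 0.08
#>   cutpoint 0.00093431; 93 acceptable, 7 unacceptable (EM iters 16)

cl <- cluster_quadrants(res$params$k[res$params$converged],
                        res$params$b[res$params$converged])
table(cl$quadrant); cl$q4_empty
#> Q1 Q2 Q3
#> 43 52  5
#> [1] TRUE
```

Reading the output: each row of `params` carries the fitted rate `k`
(per day), saturation `b` in the original signal units, the normalized-space
fit MSE, and the switching time with its kinetic class over the window
(days 10.5–21; day 21 encodes the first postnatal day). The mixture
partition separates the low-MSE mode (acceptable fits, here 93/100) from
the high-MSE mode at an equal-posterior cut point; rejected rows are
candidates for piecewise (peak) fitting via `fit_piecewise()`. The k-means
quadrants show the characteristic L-shape: high-rate/high-saturation
combinations (Q4) are absent.

A command-line wrapper with subcommands
(`preprocess`, `fit`, `gmm`, `piecewise`, `link`, `predict`, `simulate`)
is installed under `exec/odekinetics`.

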
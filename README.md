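# robustavg

Simulation and model-fitting toolkit for studying **robust averaging** in
perceptual decision making: why observers who average the tilt of several
gratings give more weight to inlying elements (close to the reference
orientation) than to outliers — and why that seemingly wasteful policy can
*improve* categorisation accuracy when decisions are corrupted by noise
arising after integration ("late" noise).

The package is aimed at computational/psychophysics researchers who want a
tested, reproducible implementation of the full modelling pipeline:
synthetic task generation, a family of transducer models, maximum-likelihood
grid fitting, probit decision-weight (psychophysical kernel) estimation, and
accuracy-surface simulations — with no external data required.

## The models

Each trial presents 8 tilts $X_1,\dots,X_8$ (radians, relative to a
reference orientation); the observer reports clockwise (CW) vs
counter-clockwise (CCW). The core model transduces and sums:

$$DV = \sum_{i=1}^{8} \mathrm{sign}(X_i)\,|X_i|^k, \qquad
  P(\mathrm{CW}) = \frac{1}{1 + e^{-DV/s}}$$

* $k < 1$ compresses outlying tilts (robust averaging); $k = 1$ is linear
  integration; $s$ is the inverse slope of the choice function, acting as
  late noise.
* The **equivalent gain** $g = 2/(1+k)$ equates the average
  input-to-output magnification of the power and linear transducers over a
  flat unit feature space, modelling a fixed neural resource; the yoked
  linear model uses $DV = g \sum_i X_i$.
* An **early-noise** variant corrupts each sample before transduction
  ($x_i = X_i + \varepsilon_i$, $\varepsilon_i \sim N(0,\xi^2)$) and
  chooses by a step function — it fails to produce robust averaging.
* A **population-coding** variant derives the same transfer-function
  family from 600 Gaussian-tuned neurons whose amplitudes scale as
  $|f_j|^{k-1}$.

Fitting is by exhaustive grid search ($k \in [0.02, 2]$,
$s \in [0.05, 10]$) minimising the Bernoulli negative log-likelihood;
decision weights come from a probit regression of choice on 8 binned
feature sums, where an inverted-U coefficient profile is the signature of
robust averaging.

## Worked example

```r
library(robustavg)

trials   <- generate_session(session_config(seed = 1))   # 1024-trial session
observer <- observer_params("power_late", k = 0.5, s = 1) # compressive observer
choices  <- simulate_observer(trials, observer, seed = 2)

mean(choices$correct)
#> [1] 0.9521484

grid_fit(trials, choices)
#> <fit_result> model=power_late objective=180.7185 on 894 trials
#> <observer_params> model=power_late k=0.48 s=1.056 xi=0 eps=0.5

weighting_profile(trials, choices)
#> <weighting_profile> 894 trials
#>   bin_center_rad coefficient        se
#> 1     -0.7500000   0.4127276 0.2945486
#> 2     -0.5357143   0.6775354 0.2067700
#> 3     -0.3214286   0.5370519 0.2963016
#> 4     -0.1071429   1.4729903 0.6927627
#> 5      0.1071429   1.8602034 0.7012267
#> 6      0.3214286   1.2927591 0.3007936
#> 7      0.5357143   0.9816312 0.2122260
#> 8      0.7500000   0.2613944 0.2438640
#> inlier mean 1.2908  outlier mean 0.5833  contrast 0.7074
```

Reading the output: 130 of the 1024 trials (12.7%) are "wraparound" trials
(a tilt beyond 0.79 rad) and are excluded, leaving 894. The grid fit
recovers the generating parameters ($\hat k = 0.48$ vs true 0.5;
$\hat s = 1.06$ vs true 1). The weighting profile is an inverted U — the
four inlying bins carry a mean weight of 1.29 against 0.58 for the four
outlying bins (contrast 0.71) — the robust-averaging signature that a
$k = 1$ observer does not show.

Higher-level analyses follow the same pattern: `simulate_accuracy_surface()`
and `difference_surface()` map where compression beats gain-matched linear
integration over the $(k, s)$ plane; `fit_early_noise()` fits the
early-noise alternative to psychometric functions;
`split_half_link_regression()` links fitted $(k, s)$ to held-out accuracy
across a cohort; `run_pipeline()` wires everything end to end with one
master seed and writes hashed, byte-reproducible artifacts.

See the vignette (`vignettes/robust-averaging-methods.Rmd`) for the model
assumptions, numerical choices and known limitations.

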
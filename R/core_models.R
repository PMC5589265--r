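#' Observer model parameterisation
#'
#' Bundles the parameters of the decision models. `k` is the exponent of the
#' sign-preserving power-law transducer (k < 1 compresses outlying tilts,
#' i.e. robust averaging; k = 1 is linear; k > 1 expands outliers). `s` is
#' the inverse slope of the logistic choice function and plays the role of
#' late (post-integration) noise. `xi` is the SD, in radians, of independent
#' early noise added to each sample before transduction. `eps` is the tuning
#' width of the population-coding variant. Fields irrelevant to the tagged
#' model are stored but ignored.
#'
#' @param model one of `"power_late"`, `"linear_equivalent_gain"`,
#'   `"power_constant_gain"`, `"early_noise"`, `"popcode"`.
#' @param k transducer exponent, > 0 (fit grid spans 0.02 to 2).
#' @param s late-noise inverse slope, > 0 (fit grid spans 0.05 to 10).
#' @param xi early-noise SD in radians, >= 0.
#' @param eps population tuning width, > 0.
#' @return an object of class `observer_params`.
#' @export
observer_params <- function(model = c("power_late", "linear_equivalent_gain",
                                      "power_constant_gain", "early_noise",
                                      "popcode"),
                            k = 1, s = 0.5, xi = 0, eps = 0.5) {
  model <- match.arg(model)
  stopifnot(k > 0, s > 0, xi >= 0, eps > 0)
  structure(list(model = model, k = k, s = s, xi = xi, eps = eps),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("<observer_params> model=%s k=%.4g s=%.4g xi=%.4g eps=%.4g\n",
              x$model, x$k, x$s, x$xi, x$eps))
  invisible(x)
}

as_feature_matrix <- function(features_rad) {
  if (is.matrix(features_rad)) features_rad else matrix(features_rad, nrow = 1)
}

#' Power-law decision variable
#'
#' The decision variable is the sum of sign-preserving power-transduced
#' tilts: `dv = sum_i sign(X_i) * |X_i|^k`. At k = 1 this is the plain sum of
#' tilts, which is also the experimenter's feedback rule.
#'
#' @param features_rad an 8-vector of tilts (radians) or an n x 8 matrix.
#' @param k transducer exponent, > 0.
#' @return scalar dv for a vector input, a vector of dvs for a matrix.
#' @export
power_dv <- function(features_rad, k) {
  stopifnot(k > 0)
  X <- as_feature_matrix(features_rad)
  dv <- rowSums(sign(X) * abs(X)^k)
  if (is.matrix(features_rad)) dv else dv[[1]]
}

#' Logistic choice probability under late noise
#'
#' `cp = 1 / (1 + exp(-dv / s))`: the probability of a clockwise choice given
#' decision variable `dv` and inverse slope `s`. Larger `s` (more late noise)
#' pulls cp towards 0.5; evaluated via `plogis` so extreme `dv/s` never
#' overflows.
#'
#' @param dv decision variable(s).
#' @param s inverse slope, > 0.
#' @export
choice_probability <- function(dv, s) {
  if (!is.numeric(s) || length(s) != 1 || s <= 0) stop("s must be a positive scalar")
  stats::plogis(dv / s)
}

#' Equivalent gain factor
#'
#' The average input-to-output magnification of the power transducer over a
#' hypothetical flat (uniform, positive) feature space, relative to a linear
#' transducer: `g = 2 / (1 + k)`. Multiplying a linear model by `g` equates
#' its total gain with the power model's, modelling a fixed neural resource.
#'
#' @param k transducer exponent, > -1.
#' @export
equivalent_gain <- function(k) {
  if (any(k <= -1)) stop("k must exceed -1")
  2 / (1 + k)
}

#' Equivalent-gain linear decision variable
#'
#' `dv = g(k) * sum_i X_i`: a linear integrator whose overall gain is yoked
#' to that of the power model with exponent `k`.
#'
#' @inheritParams power_dv
#' @export
linear_equivalent_dv <- function(features_rad, k) {
  X <- as_feature_matrix(features_rad)
  dv <- equivalent_gain(k) * rowSums(X)
  if (is.matrix(features_rad)) dv else dv[[1]]
}

#' Constant-gain power decision variable
#'
#' `dv = power_dv(X, k) / g(k)`. Comparing this model across k against its
#' own k = 1 case is mathematically identical to comparing the raw power
#' model against the equivalent-gain linear model.
#'
#' @inheritParams power_dv
#' @export
constant_gain_dv <- function(features_rad, k) {
  power_dv(features_rad, k) / equivalent_gain(k)
}

#' Early-noise step choice
#'
#' Each sample is corrupted by independent Gaussian noise of SD `xi` before
#' transduction: `x_i = X_i + e_i`, then `dv = sum sign(x_i)|x_i|^k` and the
#' choice is clockwise iff dv > 0 (a step function; there is no late noise).
#'
#' @inheritParams power_dv
#' @param xi early-noise SD in radians, >= 0.
#' @param seed optional seed.
#' @return `"CW"`/`"CCW"` per trial (vector for matrix input).
#' @export
early_noise_choice <- function(features_rad, k, xi, seed = NULL) {
  stopifnot(xi >= 0, k > 0)
  maybe_set_seed(seed)
  X <- as_feature_matrix(features_rad)
  x <- X + matrix(stats::rnorm(length(X), 0, xi), nrow(X), ncol(X))
  dv <- rowSums(sign(x) * abs(x)^k)
  ch <- ifelse(dv > 0, "CW", "CCW")
  if (is.matrix(features_rad)) ch else ch[[1]]
}

#' Population-coding specification
#'
#' A bank of `M` model neurons with Gaussian tuning curves whose preferred
#' feature values `f_j` are linearly spaced across `feature_space`. Each
#' neuron's amplitude is scaled by the gain `G_j = |f_j|^(k-1)`, so k < 1
#' boosts neurons preferring inlying features (near the boundary at 0).
#' `eps` is the common tuning width; by convention it is the SD of the
#' tuning curve (set `eps_is_variance = TRUE` for the variance reading).
#' Firing rates are additionally scaled by `rho / M`, the ratio of the
#' feature-space range to the population size, which makes the read-out
#' invariant to those bookkeeping choices.
#'
#' @param M number of neurons.
#' @param feature_space interval covered by the preferred values; the default
#'   600-point grid over `[-3, 3]` contains no exact zero, so the gain is
#'   finite for every k.
#' @param eps tuning width, > 0.
#' @param k gain exponent.
#' @param eps_is_variance interpret `eps` as the tuning-curve variance.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(M = 600L, feature_space = c(-3, 3), eps = 0.5,
                            k = 1, eps_is_variance = FALSE) {
  stopifnot(M >= 2, length(feature_space) == 2,
            feature_space[2] > feature_space[1], eps > 0, k > 0)
  f <- seq(feature_space[1], feature_space[2], length.out = M)
  if (any(f == 0)) stop("preferred-value grid must not contain exact zero")
  structure(
    list(M = as.integer(M), feature_space = feature_space,
         rho = diff(feature_space), f = f, gain = abs(f)^(k - 1),
         eps = eps, sd = if (eps_is_variance) sqrt(eps) else eps, k = k),
    class = "population_spec")
}

#' Population estimate of a feature value
#'
#' The firing rate of neuron j to stimulus x is
#' `R_j = N(x; f_j, eps) * G_j * rho / M`, and the population estimate is the
#' preferred-value-weighted sum `Theta(x) = sum_j R_j * f_j`. Odd-symmetric
#' in x; compressive (concave on x > 0) for k < 1, recreating the power-law
#' transfer-function family.
#'
#' @param x feature value(s) within the spec's feature space.
#' @param spec a [population_spec()].
#' @export
popcode_estimate <- function(x, spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (any(x < spec$feature_space[1] | x > spec$feature_space[2])) {
    stop("feature value outside the population feature space")
  }
  w <- spec$gain * spec$f * (spec$rho / spec$M)
  drop(stats::dnorm(outer(x, spec$f, "-"), sd = spec$sd) %*% w)
}

#' Population-coding decision variable
#'
#' Sums the population estimates of the 8 samples: `dv = sum_i Theta(X_i)`,
#' which is then passed through [choice_probability()] for likelihoods.
#'
#' @inheritParams power_dv
#' @param spec a [population_spec()].
#' @export
popcode_dv <- function(features_rad, spec) {
  X <- as_feature_matrix(features_rad)
  dv <- rowSums(matrix(popcode_estimate(as.vector(X), spec),
                       nrow(X), ncol(X)))
  if (is.matrix(features_rad)) dv else dv[[1]]
}

# Dispatch the deterministic decision variable for the late-noise model
# family; the early-noise model is stochastic and handled separately.
model_dv <- function(features_rad, params) {
  stopifnot(inherits(params, "observer_params"))
  switch(params$model,
         power_late = power_dv(features_rad, params$k),
         linear_equivalent_gain = linear_equivalent_dv(features_rad, params$k),
         power_constant_gain = constant_gain_dv(features_rad, params$k),
         popcode = popcode_dv(features_rad,
                              population_spec(eps = params$eps, k = params$k)),
         stop("no deterministic decision variable for model '",
              params$model, "'"))
}
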
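#' Uniform-feature stimulus design
#'
#' A control stimulus regime in which the 8 tilts are drawn i.i.d. uniform on
#' `feature_range` (relative to the reference) instead of the Gaussian task
#' design. The correct category is still the sign of the summed tilts. Used
#' to show that the performance benefit of compressive transduction depends
#' on the feature distribution having its mode at the category boundary.
#'
#' The default range is the unit interval `[-1, 1]`: the equivalent gain
#' `g = 2/(1+k)` equates power and linear transducers averaged over a flat
#' unit feature space, so only on this support is the gain-matched
#' comparison exactly fair. A narrower uniform support (e.g. the
#' post-exclusion range `[-0.79, 0.79]`) leaves the power model with a
#' slight residual gain advantage for k < 1 (by the factor
#' `0.79^(k-1) > 1`), which shows up as a spurious benefit at high late
#' noise.
#'
#' @param n_trials number of trials.
#' @param n_samples samples per trial.
#' @param feature_range interval (radians) inside `(-pi/2, pi/2)`.
#' @param seed optional seed.
#' @return a trial table with the standard columns (mu/sigma/duration `NA`).
#' @export
uniform_feature_design <- function(n_trials, n_samples = 8L,
                                   feature_range = c(-1, 1),
                                   seed = NULL) {
  stopifnot(length(feature_range) == 2,
            feature_range[1] < feature_range[2],
            feature_range[1] > -pi / 2, feature_range[2] < pi / 2)
  maybe_set_seed(seed)
  tilt_deg <- rad2deg(matrix(stats::runif(n_trials * n_samples,
                                          feature_range[1], feature_range[2]),
                             n_trials, n_samples))
  build_trial_table(tilt_deg, reference_deg = 0, session_id = "uniform",
                    session_kind = "uniform_features",
                    block = 1L, trial_index = seq_len(n_trials) - 1L,
                    mu_deg = NA_real_, sigma_deg = NA_real_,
                    duration_ms = NA_real_,
                    wrap_threshold_rad = max(abs(feature_range)) + 1e-9)
}

#' Simulated accuracy surface over the (k, s) plane
#'
#' For every cell of the k x s grid, simulates choices of the given model on
#' a common stimulus set (the same trials and the same uniform comparison
#' draws in every cell - common random numbers) and records the proportion
#' of choices matching the sign-of-sum correct category. The analytic
#' Bernoulli-mean accuracy (mean over trials of cp when the correct category
#' is CW, else 1 - cp) is reported alongside as a variance-free counterpart.
#'
#' @param trials stimulus table; wraparound trials are excluded first.
#' @param model `"power"` (raw power transducer), `"linear_equivalent"`
#'   (linear with yoked gain) or `"power_constant_gain"`.
#' @param k_grid,s_grid simulation grids (defaults: k in `[0.02, 2]`,
#'   s log-spaced in `[0.05, 5]`).
#' @param seed seed for the common uniform comparison draws.
#' @param keep_trials keep the per-trial correctness matrix (needed for
#'   paired difference standard errors).
#' @return object of class `accuracy_surface`: long data.frame `surface`
#'   with columns `k, s, accuracy, accuracy_analytic, se, n_reps`, plus the
#'   grids, model, regime and (optionally) the correctness array.
#' @export
simulate_accuracy_surface <- function(trials,
                                      model = c("power", "linear_equivalent",
                                                "power_constant_gain"),
                                      k_grid = seq(0.02, 2, length.out = 100),
                                      s_grid = exp(seq(log(0.05), log(5),
                                                       length.out = 20)),
                                      seed = 1, keep_trials = FALSE) {
  model <- match.arg(model)
  trials <- exclude_trials(trials)$trials
  X <- feature_matrix(trials)
  n <- nrow(X)
  cw <- trials$correct_category == "CW"
  maybe_set_seed(seed)
  u <- stats::runif(n)
  dv_fun <- switch(model,
                   power = power_dv,
                   linear_equivalent = linear_equivalent_dv,
                   power_constant_gain = constant_gain_dv)
  acc <- acc_an <- se <- matrix(NA_real_, length(s_grid), length(k_grid))
  correct_arr <- if (keep_trials) {
    array(NA, c(n, length(s_grid), length(k_grid)))
  }
  for (j in seq_along(k_grid)) {
    dv <- dv_fun(X, k_grid[j])
    for (i in seq_along(s_grid)) {
      cp <- choice_probability(dv, s_grid[i])
      choice_cw <- u < cp
      corr <- choice_cw == cw
      acc[i, j] <- mean(corr)
      acc_an[i, j] <- mean(ifelse(cw, cp, 1 - cp))
      se[i, j] <- stats::sd(corr) / sqrt(n)
      if (keep_trials) correct_arr[, i, j] <- corr
    }
  }
  surface <- data.frame(
    k = rep(k_grid, each = length(s_grid)),
    s = rep(s_grid, length(k_grid)),
    accuracy = as.vector(acc),
    accuracy_analytic = as.vector(acc_an),
    se = as.vector(se),
    n_reps = n)
  structure(
    list(surface = surface, accuracy = acc, accuracy_analytic = acc_an,
         se = se, k_grid = k_grid, s_grid = s_grid, model = model,
         regime = if (identical(trials$session_kind[1], "uniform_features"))
           "uniform_features" else "gaussian_design",
         n_reps = n, seed = seed,
         correct = correct_arr),
    class = "accuracy_surface")
}

#' @export
print.accuracy_surface <- function(x, ...) {
  cat(sprintf("<accuracy_surface> model=%s regime=%s %d x %d grid, %d trials/cell\n",
              x$model, x$regime, length(x$s_grid), length(x$k_grid), x$n_reps))
  invisible(x)
}

#' Accuracy difference surface (power minus equivalent-gain linear)
#'
#' Elementwise difference of two accuracy surfaces computed on identical
#' grids, stimuli and comparison draws. When both surfaces carry per-trial
#' correctness, the paired Monte-Carlo standard error of the difference is
#' returned; otherwise the (conservative) independent-sum SE.
#'
#' @param power_surface,linear_surface [simulate_accuracy_surface()] results
#'   built from the same stimuli and seed.
#' @return list of class `difference_surface` with matrices `difference`
#'   (s x k), `se`, plus the shared grids.
#' @export
difference_surface <- function(power_surface, linear_surface) {
  stopifnot(inherits(power_surface, "accuracy_surface"),
            inherits(linear_surface, "accuracy_surface"))
  if (!isTRUE(all.equal(power_surface$k_grid, linear_surface$k_grid)) ||
      !isTRUE(all.equal(power_surface$s_grid, linear_surface$s_grid))) {
    stop("surfaces were computed on different grids")
  }
  if (power_surface$n_reps != linear_surface$n_reps ||
      !identical(power_surface$seed, linear_surface$seed)) {
    stop("surfaces must share stimuli and comparison draws")
  }
  d <- power_surface$accuracy - linear_surface$accuracy
  if (!is.null(power_surface$correct) && !is.null(linear_surface$correct)) {
    n <- power_surface$n_reps
    se <- sqrt(apply(power_surface$correct - linear_surface$correct,
                     c(2, 3), stats::var) / n)
  } else {
    se <- sqrt(power_surface$se^2 + linear_surface$se^2)
  }
  structure(list(difference = d, se = se,
                 difference_analytic = power_surface$accuracy_analytic -
                   linear_surface$accuracy_analytic,
                 k_grid = power_surface$k_grid,
                 s_grid = power_surface$s_grid,
                 n_reps = power_surface$n_reps),
            class = "difference_surface")
}
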
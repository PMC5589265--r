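#' Default maximum-likelihood search grids
#'
#' The exhaustive search covers k in `[0.02, 2]` (linear spacing) and s in
#' `[0.05, 10]` (log spacing, since s acts multiplicatively on the decision
#' variable).
#' @param n number of grid points.
#' @export
default_k_grid <- function(n = 100) seq(0.02, 2, length.out = n)

#' @rdname default_k_grid
#' @export
default_s_grid <- function(n = 100) exp(seq(log(0.05), log(10), length.out = n))

CP_EPS <- 1e-12

#' Negative log-likelihood of a late-noise model
#'
#' `nll = -sum_t [c_t log cp_t + (1 - c_t) log(1 - cp_t)]` with `c_t = 1` for
#' clockwise choices and cp from the tagged model. Wraparound trials are
#' excluded first (the same rule as every analysis). Choice probabilities are
#' clamped to `[1e-12, 1 - 1e-12]`; a warning is raised if a saturated cp
#' disagrees with the observed choice.
#'
#' @param trials trial table.
#' @param choices aligned choice table.
#' @param params an [observer_params()] tagged `power_late`,
#'   `linear_equivalent_gain`, `power_constant_gain` or `popcode`.
#' @param exclude_wraparound apply the wraparound exclusion (default TRUE).
#' @export
negloglik <- function(trials, choices, params, exclude_wraparound = TRUE) {
  if (params$model == "early_noise") {
    stop("the early-noise model has no trialwise likelihood; use fit_early_noise()")
  }
  if (exclude_wraparound) {
    ex <- exclude_trials(trials, choices)
    trials <- ex$trials
    choices <- ex$choices
  } else {
    choices <- align_choices(trials, choices)
  }
  X <- feature_matrix(trials)
  cp <- choice_probability(model_dv(X, params), params$s)
  cw <- choices$choice == "CW"
  saturated <- cp <= 0 | cp >= 1
  if (any(saturated & (cw != (cp >= 1)))) {
    warning("saturated choice probabilities disagree with observed choices; clamped")
  }
  cp <- clamp(cp, CP_EPS, 1 - CP_EPS)
  -sum(ifelse(cw, log(cp), log1p(-cp)))
}

#' Exhaustive grid fit of (k, s) by maximum likelihood
#'
#' Evaluates the negative log-likelihood on the full k x s grid and returns
#' the argmin. Deterministic; ties are broken towards smaller k, then smaller
#' s. A local-minimum count over the grid (4-neighbourhood) is reported as an
#' automated stand-in for a visual convexity check.
#'
#' @param trials,choices aligned tables; wraparound trials are excluded.
#' @param model late-noise model tag (see [observer_params()]).
#' @param k_grid,s_grid search grids.
#' @param eps population tuning width (popcode model only).
#' @return object of class `fit_result`: `model`, `best_params`, `objective`
#'   (minimised nll), `grid_values` (s x k matrix of nll), `k_grid`,
#'   `s_grid`, `n_trials_used`, `n_local_minima`.
#' @export
grid_fit <- function(trials, choices,
                     model = c("power_late", "linear_equivalent_gain",
                               "power_constant_gain", "popcode"),
                     k_grid = default_k_grid(), s_grid = default_s_grid(),
                     eps = 0.5) {
  model <- match.arg(model)
  ex <- exclude_trials(trials, choices)
  if (nrow(ex$trials) == 0) stop("no included trials to fit")
  X <- feature_matrix(ex$trials)
  cw <- ex$choices$choice == "CW"
  nll <- matrix(NA_real_, length(s_grid), length(k_grid),
                dimnames = list(NULL, NULL))
  inv_s <- 1 / s_grid
  for (j in seq_along(k_grid)) {
    p <- observer_params(model, k = k_grid[j], eps = eps)
    dv <- model_dv(X, p)
    cp <- clamp(stats::plogis(outer(dv, inv_s)), CP_EPS, 1 - CP_EPS)
    ll <- log(cp)
    ll[!cw, ] <- log1p(-cp[!cw, , drop = FALSE])
    nll[, j] <- -colSums(ll)
  }
  # column-major scan: smallest k first, then smallest s within that k
  best <- arrayInd(which.min(nll), dim(nll))
  k_hat <- k_grid[best[2]]
  s_hat <- s_grid[best[1]]
  structure(
    list(model = model,
         best_params = observer_params(model, k = k_hat, s = s_hat, eps = eps),
         objective = nll[best[1], best[2]],
         grid_values = nll, k_grid = k_grid, s_grid = s_grid,
         n_trials_used = nrow(ex$trials),
         n_local_minima = count_local_minima(nll)),
    class = "fit_result")
}

# Count strict 4-neighbourhood local minima of an objective surface; 1 means
# the discretised surface is unimodal (the automated convexity diagnostic).
count_local_minima <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  n <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- m[i, j]
      if ((i == 1 || v < m[i - 1, j]) && (i == nr || v < m[i + 1, j]) &&
          (j == 1 || v < m[i, j - 1]) && (j == nc || v < m[i, j + 1])) {
        n <- n + 1L
      }
    }
  }
  n
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model=%s objective=%.4f on %d trials\n",
              x$model, x$objective, x$n_trials_used))
  print(x$best_params)
  invisible(x)
}

#' Empirical psychometric table
#'
#' The conditional probability of a clockwise response given the presence of
#' a sample tilt in each of 9 equally spaced feature bins (centers spanning
#' -0.75 to 0.75 rad). Every sample of every included trial contributes its
#' trial's choice to the bin containing its tilt.
#'
#' @param trials,choices aligned tables; wraparound trials are excluded.
#' @param centers psychometric bin centers.
#' @param edge_limit outer edge of the first/last bin, radians.
#' @return data.frame of class `psychometric_table` with columns
#'   `bin_center_rad`, `p_cw`, `n_samples` (empty bins carry `NA` p_cw).
#' @export
empirical_psychometric <- function(trials, choices,
                                   centers = seq(-0.75, 0.75, length.out = 9),
                                   edge_limit = 0.79) {
  ex <- exclude_trials(trials, choices)
  X <- feature_matrix(ex$trials)
  y <- as.numeric(ex$choices$choice == "CW")
  edges <- bin_edges_from_centers(centers, edge_limit)
  idx <- findInterval(X, edges, rightmost.closed = TRUE)
  ytab <- matrix(y, nrow(X), ncol(X))  # each sample inherits its trial's choice
  n_b <- tabulate(idx, nbins = length(centers))
  s_b <- vapply(seq_along(centers),
                function(b) sum(ytab[idx == b]), numeric(1))
  out <- data.frame(bin_center_rad = centers,
                    p_cw = ifelse(n_b > 0, s_b / n_b, NA_real_),
                    n_samples = n_b)
  class(out) <- c("psychometric_table", "data.frame")
  out
}

# Monte-Carlo predicted psychometric table for the early-noise model at one
# (k, xi), using a fixed noise array E (8 x n x reps laid out as a matrix)
# so the objective is smooth across grid points (common random numbers).
predict_psychometric_early <- function(X, E, k, xi, bin_idx, centers) {
  n <- nrow(X)
  Xbig <- X[rep(seq_len(n), nrow(E) / n), , drop = FALSE]
  x <- Xbig + xi * E
  dv <- rowSums(sign(x) * abs(x)^k)
  p_trial <- rowMeans(matrix(as.numeric(dv > 0), n))  # n x reps collapse
  ptab <- matrix(p_trial, n, ncol(X))
  n_b <- tabulate(bin_idx, nbins = length(centers))
  s_b <- vapply(seq_along(centers),
                function(b) sum(ptab[bin_idx == b]), numeric(1))
  ifelse(n_b > 0, s_b / n_b, NA_real_)
}

#' Fit the early-noise model to psychometric functions
#'
#' Grid search over the early-noise SD `xi` (20 linearly spaced values in
#' `[0, 3]`) and, by default, the exponent `k` jointly (so the model has the
#' same number of free parameters as the late-noise model; set
#' `k_grid = 1` to fix a linear transducer). For each grid point the
#' predicted psychometric table is computed by Monte-Carlo simulation of the
#' noise-then-step choice rule with common random numbers across grid
#' points; the objective is the mean squared error against the observed
#' psychometric table over non-empty bins.
#'
#' @param trials,choices aligned tables; wraparound trials are excluded.
#' @param xi_grid early-noise SD grid.
#' @param k_grid exponent grid (scalar to fix k).
#' @param mc_reps Monte-Carlo noise draws per trial per grid point (>= 100).
#' @param centers,edge_limit psychometric bin geometry.
#' @param seed optional seed for the common noise draws.
#' @return a `fit_result` whose `objective` is the minimised MSE and whose
#'   `grid_values` is the xi x k MSE matrix.
#' @export
fit_early_noise <- function(trials, choices,
                            xi_grid = seq(0, 3, length.out = 20),
                            k_grid = seq(0.02, 2, length.out = 20),
                            mc_reps = 1000,
                            centers = seq(-0.75, 0.75, length.out = 9),
                            edge_limit = 0.79, seed = NULL) {
  stopifnot(mc_reps >= 100)
  maybe_set_seed(seed)
  obs <- empirical_psychometric(trials, choices, centers, edge_limit)
  if (all(is.na(obs$p_cw))) stop("all psychometric bins are empty")
  ex <- exclude_trials(trials, choices)
  X <- feature_matrix(ex$trials)
  edges <- bin_edges_from_centers(centers, edge_limit)
  bin_idx <- findInterval(X, edges, rightmost.closed = TRUE)
  E <- matrix(stats::rnorm(nrow(X) * mc_reps * ncol(X)),
              nrow(X) * mc_reps, ncol(X))
  ok <- !is.na(obs$p_cw)
  mse <- matrix(NA_real_, length(xi_grid), length(k_grid))
  for (j in seq_along(k_grid)) {
    for (i in seq_along(xi_grid)) {
      pred <- predict_psychometric_early(X, E, k_grid[j], xi_grid[i],
                                         bin_idx, centers)
      mse[i, j] <- mean((pred[ok] - obs$p_cw[ok])^2)
    }
  }
  best <- arrayInd(which.min(mse), dim(mse))
  structure(
    list(model = "early_noise",
         best_params = observer_params("early_noise", k = k_grid[best[2]],
                                       xi = xi_grid[best[1]]),
         objective = mse[best[1], best[2]],
         grid_values = mse, xi_grid = xi_grid, k_grid = k_grid,
         observed_psychometric = obs,
         n_trials_used = nrow(X),
         n_local_minima = count_local_minima(mse)),
    class = "fit_result")
}

#' Parameter-recovery study
#'
#' For each pair of generating values on an equally spaced (k, s) grid,
#' simulates a power-model observer's choices on a synthetic session and
#' refits by [grid_fit()], recording generating and recovered values. When
#' the fit recovers the generating parameters, recovered-vs-actual scatter
#' falls on the identity line.
#'
#' @param trials stimulus table to reuse for every observer; generated from
#'   `config` when NULL.
#' @param config a [session_config()] used when `trials` is NULL.
#' @param k_true,s_true generating parameter grids.
#' @param k_grid,s_grid fitting grids passed to [grid_fit()].
#' @param seed master seed; each (k, s) cell gets a derived seed.
#' @return data.frame with `k_true, s_true, k_hat, s_hat, objective, seed`.
#' @export
parameter_recovery <- function(trials = NULL, config = session_config(seed = 1),
                               k_true = seq(0.02, 2, length.out = 20),
                               s_true = seq(0.05, 10, length.out = 20),
                               k_grid = default_k_grid(),
                               s_grid = default_s_grid(),
                               seed = 1) {
  if (is.null(trials)) trials <- generate_session(config)
  grid <- expand.grid(k_true = k_true, s_true = s_true,
                      KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell_seed <- derive_seed(seed, 3L, i)
    ch <- simulate_observer(
      trials, observer_params("power_late", k = grid$k_true[i],
                              s = grid$s_true[i]),
      seed = cell_seed)
    fit <- grid_fit(trials, ch, "power_late", k_grid, s_grid)
    res[[i]] <- data.frame(k_true = grid$k_true[i], s_true = grid$s_true[i],
                           k_hat = fit$best_params$k,
                           s_hat = fit$best_params$s,
                           objective = fit$objective, seed = cell_seed)
  }
  do.call(rbind, res)
}
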
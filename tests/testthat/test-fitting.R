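test_that("negative log-likelihood matches closed form and a loop oracle", {
  # all-zero features give dv = 0, cp = 0.5, nll = n log 2 for any choices
  Z <- toy_trials(matrix(0, 40, 8))
  ch <- choices_from(Z, rep(c("CW", "CCW"), 20))
  p <- observer_params("power_late", k = 0.7, s = 0.9)
  expect_equal(negloglik(Z, ch, p), 40 * log(2))

  trials <- fixture_session(42)[1:200, ]
  choices <- simulate_observer(trials,
                               observer_params("power_late", k = 0.6, s = 1),
                               seed = 5)
  params <- observer_params("power_late", k = 0.8, s = 0.7)
  got <- negloglik(trials, choices, params)
  ex <- exclude_trials(trials, choices)
  X <- feature_matrix(ex$trials)
  oracle <- 0
  for (t in seq_len(nrow(X))) {
    cp <- 1 / (1 + exp(-power_dv(X[t, ], 0.8) / 0.7))
    cp <- min(max(cp, 1e-12), 1 - 1e-12)
    oracle <- oracle - if (ex$choices$choice[t] == "CW") log(cp) else log(1 - cp)
  }
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_error(negloglik(trials, choices, observer_params("early_noise")),
               "early-noise")
})

test_that("expected likelihood is minimised at the generating parameters", {
  trials <- fixture_session(42)
  gens <- list(c(0.5, 0.5), c(1, 1), c(1.5, 2))
  alts <- list(c(0.9, 0.5), c(1, 3), c(0.6, 2))
  for (g in seq_along(gens)) {
    truth <- observer_params("power_late", k = gens[[g]][1], s = gens[[g]][2])
    alt <- observer_params("power_late", k = alts[[g]][1], s = alts[[g]][2])
    nll_truth <- nll_alt <- numeric(10)
    for (r in 1:10) {
      ch <- simulate_observer(trials, truth, seed = 600 + 10 * g + r)
      nll_truth[r] <- negloglik(trials, ch, truth)
      nll_alt[r] <- negloglik(trials, ch, alt)
    }
    expect_lt(mean(nll_truth), mean(nll_alt))
  }
})

test_that("grid_fit is deterministic and recovers compressive exponents", {
  trials <- fixture_session(42)
  ch <- simulate_observer(trials, observer_params("power_late", k = 0.5, s = 1),
                          seed = 21)
  f1 <- grid_fit(trials, ch)
  f2 <- grid_fit(trials, ch)
  expect_identical(f1$best_params$k, f2$best_params$k)
  expect_identical(f1$grid_values, f2$grid_values)
  expect_lt(f1$best_params$k, 1)
  expect_equal(f1$objective, min(f1$grid_values))
  expect_true(all(is.finite(f1$grid_values)))
  expect_equal(f1$n_trials_used, sum(!trials$wraparound))
  expect_error(grid_fit(trials[0, ], ch[0, ]), "no included trials")
})

test_that("recovered late noise is approximately unbiased at k = 1", {
  trials <- fixture_session(42)
  s_hat <- vapply(1:15, function(r) {
    ch <- simulate_observer(trials, observer_params("power_late", k = 1, s = 0.5),
                            seed = 3000 + r)
    grid_fit(trials, ch)$best_params$s
  }, numeric(1))
  expect_lt(abs(median(s_hat) - 0.5) / 0.5, 0.1)
})

test_that("the empirical psychometric table matches a re-binning oracle", {
  trials <- fixture_session(42)[1:300, ]
  ch <- simulate_observer(trials, observer_params("power_late", k = 1, s = 0.5),
                          seed = 31)
  tab <- empirical_psychometric(trials, ch)
  expect_equal(nrow(tab), 9L)
  expect_equal(tab$bin_center_rad, seq(-0.75, 0.75, length.out = 9))
  expect_equal(sum(tab$n_samples),
               8L * sum(!trials$wraparound))

  ex <- exclude_trials(trials, ch)
  X <- feature_matrix(ex$trials)
  centers <- tab$bin_center_rad
  half <- diff(centers)[1] / 2
  edges <- c(-0.79, centers[-9] + half, 0.79)
  for (b in 1:9) {
    num <- den <- 0
    for (t in seq_len(nrow(X))) {
      for (i in 1:8) {
        lo <- edges[b]
        hi <- edges[b + 1]
        inb <- X[t, i] > lo & X[t, i] <= hi
        if (b == 1) inb <- X[t, i] >= lo & X[t, i] <= hi
        if (inb) {
          den <- den + 1
          num <- num + (ex$choices$choice[t] == "CW")
        }
      }
    }
    expect_equal(tab$n_samples[b], den)
    if (den > 0) expect_equal(tab$p_cw[b], num / den)
  }

  # monotone in the bin center for a low-noise linear observer
  expect_true(all(diff(tab$p_cw[!is.na(tab$p_cw)]) >= 0))
})

test_that("psychometric symmetry holds for a symmetric observer", {
  trials <- fixture_session(42)
  ch <- simulate_observer(trials, observer_params("power_late", k = 0.8, s = 1),
                          seed = 41)
  tab <- empirical_psychometric(trials, ch)
  for (b in 1:4) {
    n1 <- tab$n_samples[b]
    n2 <- tab$n_samples[10 - b]
    if (n1 > 20 && n2 > 20) {
      se <- sqrt(0.25 / n1 + 0.25 / n2)
      expect_lt(abs(tab$p_cw[b] + tab$p_cw[10 - b] - 1), 4 * se)
    }
  }
})

test_that("early-noise fitting recovers the noise scale and nails the noiseless case", {
  cfg <- session_config(n_blocks = 2L, trials_per_block = 128L, seed = 51)
  trials <- generate_session(cfg)
  truth <- observer_params("early_noise", k = 1, xi = 1)
  ch <- simulate_observer(trials, truth, seed = 52)
  hits <- 0L
  xi_grid <- seq(0, 3, length.out = 20)
  for (r in 1:5) {
    chr <- simulate_observer(trials, truth, seed = 520 + r)
    fit <- fit_early_noise(trials, chr, xi_grid = xi_grid, k_grid = 1,
                           mc_reps = 400, seed = 530 + r)
    if (abs(fit$best_params$xi - 1) <= diff(xi_grid)[1] + 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 4L)

  # xi = 0 with the generating exponent reproduces the noiseless step
  # psychometric exactly: zero MSE at that grid point
  ch0 <- simulate_observer(trials, observer_params("early_noise", k = 1, xi = 0),
                           seed = 54)
  fit0 <- fit_early_noise(trials, ch0, xi_grid = c(0, 1), k_grid = 1,
                          mc_reps = 100, seed = 55)
  expect_equal(fit0$grid_values[1, 1], 0)
  expect_equal(fit0$best_params$xi, 0)
})

test_that("parameter recovery falls near the identity line on a coarse grid", {
  trials <- fixture_session(42)
  rec <- parameter_recovery(trials,
                            k_true = seq(0.2, 1.8, length.out = 5),
                            s_true = c(0.3, 0.8),
                            k_grid = default_k_grid(40),
                            s_grid = default_s_grid(40),
                            seed = 9)
  expect_equal(nrow(rec), 10L)
  expect_gt(cor(rec$k_true, rec$k_hat, method = "spearman"), 0.8)
  expect_gt(cor(rec$s_true, rec$s_hat, method = "spearman"), 0.8)
})
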
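#' Session configuration for the orientation-averaging task
#'
#' Describes one synthetic testing session of the categorisation task: on each
#' trial eight gratings are tilted relative to a central reference, with tilts
#' drawn from a Gaussian whose mean (mu) and standard deviation (sigma) are
#' counterbalanced within every block, and the observer reports whether the
#' array mean falls clockwise (CW) or counter-clockwise (CCW) of the
#' reference.
#'
#' @param session_kind `"fixed_reference"` (one reference per block) or
#'   `"variable_reference"` (a fresh reference every trial).
#' @param n_blocks number of blocks per session.
#' @param trials_per_block trials in each block; must be a multiple of the
#'   number of (mu, sigma, duration) cells so the design counterbalances.
#' @param mu_levels_deg signed tilt means in degrees.
#' @param sigma_levels_deg tilt standard deviations in degrees (all > 0).
#' @param duration_levels_ms stimulus durations carried as metadata only;
#'   duration never influences simulated choices.
#' @param tolerance_deg resampling tolerance: a sampled 8-tilt array is
#'   accepted only when its sample mean and SD are within this many degrees of
#'   the nominal (mu, sigma).
#' @param sd_denominator convention for the sample SD in the tolerance
#'   check: `"n"` (population SD, the default - it keeps the pooled tilt SD
#'   unbiased and reproduces the task's wraparound-exclusion rate) or
#'   `"n-1"`.
#' @param wrap_threshold_rad absolute tilt (radians) beyond which a trial is
#'   flagged `wraparound` and excluded from analysis.
#' @param max_resample cap on full-array resamples per trial before the
#'   (mu, sigma, tolerance) combination is declared infeasible.
#' @param session_id identifier copied into the trial table.
#' @param seed integer seed making the session reproducible, or `NULL`.
#' @return an object of class `session_config`.
#' @seealso [generate_session()]
#' @export
session_config <- function(session_kind = c("fixed_reference", "variable_reference"),
                           n_blocks = 8L,
                           trials_per_block = 128L,
                           mu_levels_deg = c(-20, -10, 10, 20),
                           sigma_levels_deg = c(8, 16),
                           duration_levels_ms = c(250, 500, 750, 1000),
                           tolerance_deg = 1,
                           sd_denominator = c("n", "n-1"),
                           wrap_threshold_rad = 0.79,
                           max_resample = 10000L,
                           session_id = "session1",
                           seed = NULL) {
  session_kind <- match.arg(session_kind)
  sd_denominator <- match.arg(sd_denominator)
  if (length(mu_levels_deg) == 0 || length(sigma_levels_deg) == 0 ||
      length(duration_levels_ms) == 0) {
    stop("level lists must be non-empty")
  }
  if (any(sigma_levels_deg <= 0)) stop("sigma levels must be positive")
  if (tolerance_deg <= 0) stop("tolerance_deg must be positive")
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  if (n_blocks < 1 || trials_per_block < 1) stop("block counts must be positive")
  n_cells <- length(mu_levels_deg) * length(sigma_levels_deg) *
    length(duration_levels_ms)
  if (trials_per_block %% n_cells != 0) {
    stop("trials_per_block (", trials_per_block, ") must be a multiple of the ",
         n_cells, " (mu, sigma, duration) cells for counterbalancing")
  }
  structure(
    list(session_kind = session_kind, n_blocks = n_blocks,
         trials_per_block = trials_per_block, mu_levels_deg = mu_levels_deg,
         sigma_levels_deg = sigma_levels_deg,
         duration_levels_ms = duration_levels_ms,
         tolerance_deg = tolerance_deg,
         sd_denominator = sd_denominator,
         wrap_threshold_rad = wrap_threshold_rad,
         max_resample = as.integer(max_resample),
         session_id = session_id, seed = seed),
    class = "session_config")
}

# Whole-array rejection sampler: draws n 8-tilt arrays i.i.d.
# Normal(mu, sigma^2) and keeps only arrays whose sample mean and sample SD
# land within tolerance of nominal. The SD uses the population (1/n)
# denominator by default: that convention reproduces both the task's
# printed wraparound-exclusion rate and an unbiased pooled tilt SD, whereas
# the 1/(n-1) convention under-disperses accepted arrays. Vectorised in
# batches; the per-trial attempt cap translates into a cap on total draws.
sample_tilt_arrays <- function(n, mu_deg, sigma_deg, tolerance_deg,
                               n_samples = 8L, max_resample = 10000L,
                               sd_denominator = c("n", "n-1")) {
  sd_denominator <- match.arg(sd_denominator)
  stopifnot(sigma_deg > 0, tolerance_deg > 0, n >= 1)
  out <- matrix(NA_real_, n, n_samples)
  got <- 0L
  drawn <- 0
  budget <- as.numeric(max_resample) * n
  while (got < n) {
    batch <- min(max(512L, (n - got) * 64L), 65536L)
    cand <- matrix(stats::rnorm(batch * n_samples, mu_deg, sigma_deg),
                   batch, n_samples)
    m <- rowMeans(cand)
    den <- if (sd_denominator == "n") n_samples else n_samples - 1L
    s2 <- pmax(rowSums(cand^2) - n_samples * m^2, 0) / den
    ok <- which(abs(m - mu_deg) <= tolerance_deg &
                  abs(sqrt(s2) - sigma_deg) <= tolerance_deg)
    drawn <- drawn + batch
    if (length(ok)) {
      take <- ok[seq_len(min(length(ok), n - got))]
      out[got + seq_along(take), ] <- cand[take, , drop = FALSE]
      got <- got + length(take)
    }
    if (got < n && drawn >= budget) {
      stop("resampling cap reached: (mu = ", mu_deg, ", sigma = ", sigma_deg,
           ", tolerance = ", tolerance_deg, ") appears infeasible after ",
           drawn, " full-array draws")
    }
  }
  out
}

# Assemble the wide trial table from tilts (degrees) and references.
build_trial_table <- function(tilt_deg, reference_deg, session_id,
                              session_kind, block, trial_index, mu_deg,
                              sigma_deg, duration_ms, wrap_threshold_rad) {
  ori <- (reference_deg + tilt_deg) %% 180
  x_rad <- deg2rad(wrap_ori_diff_deg(ori - reference_deg))
  trials <- data.frame(
    session_id = session_id, session_kind = session_kind, block = block,
    trial_index = trial_index, reference_deg = reference_deg,
    mu_deg = mu_deg, sigma_deg = sigma_deg, duration_ms = duration_ms,
    stringsAsFactors = FALSE)
  colnames(ori) <- paste0("ori", 1:8, "_deg")
  colnames(x_rad) <- paste0("x", 1:8, "_rad")
  trials <- cbind(trials, ori, x_rad)
  trials$correct_category <- ifelse(rowSums(x_rad) > 0, "CW", "CCW")
  trials$wraparound <- rowSums(abs(x_rad) > wrap_threshold_rad) > 0
  rownames(trials) <- NULL
  trials
}

#' Sample a single stimulus trial
#'
#' Draws one 8-tilt array relative to `reference_deg`, resampling the whole
#' array until its sample mean and SD are within `tolerance_deg` of the
#' nominal (mu, sigma). Absolute orientations are the reference plus tilt,
#' wrapped to the 180-degree orientation circle.
#'
#' @inheritParams session_config
#' @param mu_deg,sigma_deg nominal tilt mean (signed) and SD in degrees.
#' @param reference_deg absolute reference orientation in `[0, 180)`.
#' @param duration_ms stimulus duration metadata.
#' @param seed optional seed.
#' @return one-row trial table (see [generate_session()] for columns).
#' @export
sample_trial <- function(mu_deg, sigma_deg, reference_deg,
                         tolerance_deg = 1, duration_ms = NA_real_,
                         sd_denominator = c("n", "n-1"),
                         wrap_threshold_rad = 0.79, max_resample = 10000L,
                         seed = NULL) {
  maybe_set_seed(seed)
  tilt <- sample_tilt_arrays(1L, mu_deg, sigma_deg, tolerance_deg,
                             max_resample = max_resample,
                             sd_denominator = sd_denominator)
  build_trial_table(tilt, reference_deg, "adhoc", NA_character_, 1L, 0L,
                    mu_deg, sigma_deg, duration_ms, wrap_threshold_rad)
}

#' Generate a full synthetic session
#'
#' Produces `n_blocks * trials_per_block` trials. Within every block the
#' (mu, sigma, duration) levels are fully counterbalanced and presented in
#' random order. Under a fixed reference one orientation is drawn uniformly
#' per block; under a variable reference one per trial. Identical seeds give
#' identical tables.
#'
#' @param config a [session_config()].
#' @return a data.frame with one row per trial and columns
#'   `session_id, session_kind, block, trial_index, reference_deg, mu_deg,
#'   sigma_deg, duration_ms, ori1_deg..ori8_deg, x1_rad..x8_rad,
#'   correct_category, wraparound`. `trial_index` is session-global and
#'   0-based; `xN_rad` are the signed tilts relative to the reference in
#'   radians, in (-pi/2, pi/2].
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  maybe_set_seed(config$seed)
  cells <- expand.grid(mu_deg = config$mu_levels_deg,
                       sigma_deg = config$sigma_levels_deg,
                       duration_ms = config$duration_levels_ms,
                       KEEP.OUT.ATTRS = FALSE)
  reps <- config$trials_per_block / nrow(cells)
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    design <- cells[rep(seq_len(nrow(cells)), reps), , drop = FALSE]
    design <- design[sample.int(nrow(design)), , drop = FALSE]
    if (config$session_kind == "fixed_reference") {
      ref <- rep(stats::runif(1, 0, 180), nrow(design))
    } else {
      ref <- stats::runif(nrow(design), 0, 180)
    }
    tilt <- matrix(NA_real_, nrow(design), 8L)
    for (cell in unique(paste(design$mu_deg, design$sigma_deg))) {
      rows <- which(paste(design$mu_deg, design$sigma_deg) == cell)
      tilt[rows, ] <- sample_tilt_arrays(
        length(rows), design$mu_deg[rows[1]], design$sigma_deg[rows[1]],
        config$tolerance_deg, max_resample = config$max_resample,
        sd_denominator = config$sd_denominator)
    }
    blocks[[b]] <- build_trial_table(
      tilt, ref, config$session_id, config$session_kind, b,
      trial_index = 0L,  # filled below
      design$mu_deg, design$sigma_deg, design$duration_ms,
      config$wrap_threshold_rad)
  }
  trials <- do.call(rbind, blocks)
  trials$trial_index <- seq_len(nrow(trials)) - 1L
  trials
}

#' Simulate an observer's choices on a trial table
#'
#' Computes each trial's choice probability (CP) under the tagged model and
#' emits a clockwise choice when a uniform draw falls below CP. For the
#' early-noise model the choice is a step function of the noise-corrupted
#' decision variable, so the recorded `cp` is the realised 0/1 probability.
#'
#' @param trials a trial table from [generate_session()].
#' @param params an [observer_params()] object.
#' @param seed optional seed.
#' @return data.frame with columns `session_id, trial_index, choice, correct,
#'   cp, rt_ms` (the latter `NA` for simulated observers).
#' @export
simulate_observer <- function(trials, params, seed = NULL) {
  stopifnot(inherits(params, "observer_params"))
  maybe_set_seed(seed)
  X <- feature_matrix(trials)
  if (params$model == "early_noise") {
    ch <- early_noise_choice(X, params$k, params$xi)
    cp <- as.numeric(ch == "CW")
    choice <- ch
  } else {
    dv <- model_dv(X, params)
    cp <- choice_probability(dv, params$s)
    choice <- ifelse(stats::runif(nrow(X)) < cp, "CW", "CCW")
  }
  data.frame(session_id = trials$session_id,
             trial_index = trials$trial_index,
             choice = choice,
             correct = choice == trials$correct_category,
             cp = cp, rt_ms = NA_real_,
             stringsAsFactors = FALSE)
}
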
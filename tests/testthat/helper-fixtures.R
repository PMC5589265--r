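# Fixtures are generated in code; sessions used by several tests are cached
# per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture_session <- function(seed = 42, ...) {
  key <- paste0("s", seed, paste(..., collapse = "_"))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_session(session_config(seed = seed, ...))
  }
  .fixture_env[[key]]
}

# Build a minimal trial table straight from a feature matrix (radians),
# reference at 0 deg.
toy_trials <- function(X, wrap_threshold = 0.79) {
  n <- nrow(X)
  O <- (X * 180 / pi) %% 180
  colnames(O) <- paste0("ori", 1:8, "_deg")
  XX <- X
  colnames(XX) <- paste0("x", 1:8, "_rad")
  df <- data.frame(session_id = "toy", session_kind = "toy", block = 1L,
                   trial_index = seq_len(n) - 1L, reference_deg = 0,
                   mu_deg = NA_real_, sigma_deg = NA_real_,
                   duration_ms = NA_real_)
  df <- cbind(df, O, XX)
  df$correct_category <- ifelse(rowSums(X) > 0, "CW", "CCW")
  df$wraparound <- rowSums(abs(X) > wrap_threshold) > 0
  df
}

choices_from <- function(trials, choice, cp = NA_real_) {
  data.frame(session_id = trials$session_id,
             trial_index = trials$trial_index, choice = choice,
             correct = choice == trials$correct_category,
             cp = cp, rt_ms = NA_real_, stringsAsFactors = FALSE)
}

random_features <- function(n, scale = 0.3) {
  matrix(stats::runif(n * 8, -scale, scale), n, 8)
}
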
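# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @noRd
# Signed acute difference between two orientations on the 180-degree circle,
# mapped to (-90, 90] degrees.
wrap_ori_diff_deg <- function(d) {
  out <- ((d + 90) %% 180) - 90
  out[out == -90] <- 90
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Extract the 8-column feature matrix (tilts relative to reference, radians)
#' from a trial table.
#' @param trials a trial table as produced by [generate_session()].
#' @return numeric matrix, one row per trial, one column per array sample.
#' @export
feature_matrix <- function(trials) {
  cols <- paste0("x", 1:8, "_rad")
  missing <- setdiff(cols, names(trials))
  if (length(missing)) {
    stop("trial table lacks feature columns: ", paste(missing, collapse = ", "))
  }
  as.matrix(trials[, cols])
}

# Set the RNG only when a seed is supplied; callers that pass seed = NULL
# consume the ambient RNG stream.
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Deterministic per-stage seed derivation from a master seed; keeps results
# below .Machine$integer.max for any small master seed.
derive_seed <- function(master, stage, unit = 0L) {
  (as.integer(master) %% 100000L) * 20011L + stage * 211L + unit * 7L
}

# Align a choice table to a trial table on trial_index; order follows trials.
align_choices <- function(trials, choices) {
  idx <- match(trials$trial_index, choices$trial_index)
  if (anyNA(idx)) {
    stop("choices table is missing trial_index values present in trials")
  }
  choices[idx, , drop = FALSE]
}
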
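# Readers/writers for the pipeline artifacts. CSV with headers is the
# interchange format for tables (inspectable, diff-able), JSON for configs
# and fit results. Numeric columns are serialised with 17 significant
# digits so write -> read round-trips at full double precision.

TRIAL_COLUMNS <- c("session_id", "session_kind", "block", "trial_index",
                   "reference_deg", "mu_deg", "sigma_deg", "duration_ms",
                   paste0("ori", 1:8, "_deg"), paste0("x", 1:8, "_rad"),
                   "correct_category", "wraparound")

CHOICE_COLUMNS <- c("session_id", "trial_index", "choice", "correct", "cp",
                    "rt_ms")

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
}

write_precise_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write / read a trial table
#'
#' The CSV carries the exact column contract of [generate_session()];
#' reading validates the schema and the feature columns.
#'
#' @param trials a trial table.
#' @param path file path.
#' @export
write_trials <- function(trials, path) {
  require_columns(trials, TRIAL_COLUMNS, "trial table")
  write_precise_csv(trials[, TRIAL_COLUMNS], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, TRIAL_COLUMNS, basename(path))
  num <- setdiff(TRIAL_COLUMNS,
                 c("session_id", "session_kind", "correct_category",
                   "wraparound"))
  for (cc in num) df[[cc]] <- as.numeric(df[[cc]])
  df$wraparound <- as.logical(df$wraparound)
  xcols <- paste0("x", 1:8, "_rad")
  if (anyNA(as.matrix(df[, xcols]))) {
    stop("trial table contains missing feature values")
  }
  df
}

#' Write / read a choice table
#'
#' Validates that `cp` lies in `[0, 1]`; `rt_ms` may be empty (simulated
#' observers have no reaction times).
#'
#' @param choices a choice table.
#' @param path file path.
#' @export
write_choices <- function(choices, path) {
  require_columns(choices, CHOICE_COLUMNS, "choice table")
  validate_choices(choices)
  write_precise_csv(choices[, CHOICE_COLUMNS], path)
  invisible(path)
}

#' @rdname write_choices
#' @export
read_choices <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, CHOICE_COLUMNS, basename(path))
  df$correct <- as.logical(df$correct)
  df$cp <- as.numeric(df$cp)
  df$rt_ms <- as.numeric(df$rt_ms)
  validate_choices(df)
  df
}

validate_choices <- function(choices) {
  bad <- !is.na(choices$cp) & (choices$cp < 0 | choices$cp > 1)
  if (any(bad)) {
    stop("choice table has cp outside [0, 1] on ", sum(bad), " row(s)")
  }
  if (!all(choices$choice %in% c("CW", "CCW") | is.na(choices$choice))) {
    stop("choice must be 'CW', 'CCW' or missing")
  }
  invisible(TRUE)
}

#' Write / read a session configuration as JSON
#' @param config a [session_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(session_config, raw)
}

#' Write / read a fit result as JSON (including the full objective grid)
#' @param fit a `fit_result`.
#' @param path file path.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  out <- fit
  out$best_params <- unclass(out$best_params)
  out$grid_values <- as.vector(out$grid_values)
  if (!is.null(out$observed_psychometric)) {
    out$observed_psychometric <- as.data.frame(out$observed_psychometric)
  }
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$best_params <- do.call(observer_params, as.list(raw$best_params))
  rows <- if (!is.null(raw$s_grid)) length(raw$s_grid) else length(raw$xi_grid)
  raw$grid_values <- matrix(raw$grid_values, rows, length(raw$k_grid))
  class(raw) <- "fit_result"
  raw
}

#' Write / read a weighting profile
#' @param profile a `weighting_profile`.
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "weighting_profile"))
  write_precise_csv(data.frame(bin_center_rad = profile$bin_centers_rad,
                               coefficient = profile$coefficients,
                               se = profile$standard_errors), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("bin_center_rad", "coefficient", "se"),
                  basename(path))
  df
}

#' Write / read an accuracy surface (long CSV)
#' @param surface an `accuracy_surface`.
#' @param path file path.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "accuracy_surface"))
  write_precise_csv(surface$surface, path)
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("k", "s", "accuracy", "accuracy_analytic", "se",
                        "n_reps"), basename(path))
  df
}
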
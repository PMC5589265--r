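#' Exclude wraparound and unanswered trials
#'
#' Drops trials flagged `wraparound` (any sample tilted more than the
#' threshold, default 0.79 rad ~ 45 deg, from the reference) and, when a
#' choice table is supplied, trials whose choice is missing. These are the
#' exclusion rules applied before every analysis.
#'
#' @param trials trial table.
#' @param choices optional choice table aligned on `trial_index`.
#' @return list with elements `trials`, `choices` (NULL if not supplied),
#'   `excluded_fraction`, `n_wraparound`, `n_missing_choice`.
#' @export
exclude_trials <- function(trials, choices = NULL) {
  n0 <- nrow(trials)
  drop_wrap <- trials$wraparound
  drop_missing <- rep(FALSE, n0)
  if (!is.null(choices)) {
    ch <- choices$choice[match(trials$trial_index, choices$trial_index)]
    drop_missing <- is.na(ch)
  }
  keep <- !(drop_wrap | drop_missing)
  out_choices <- NULL
  if (!is.null(choices)) {
    out_choices <- align_choices(trials[keep, , drop = FALSE], choices)
  }
  list(trials = trials[keep, , drop = FALSE],
       choices = out_choices,
       excluded_fraction = 1 - sum(keep) / n0,
       n_wraparound = sum(drop_wrap),
       n_missing_choice = sum(drop_missing & !drop_wrap))
}

# Bin edges from equally spaced centers: midpoints between centers, with the
# outermost edges pushed out to +/- edge_limit so the whole included feature
# range is covered.
bin_edges_from_centers <- function(centers, edge_limit = 0.79) {
  mid <- (centers[-1] + centers[-length(centers)]) / 2
  c(-edge_limit, mid, edge_limit)
}

#' Default decision-weight bin centers
#'
#' Eight equally spaced bin centers from -0.75 to 0.75 rad.
#' @export
weight_bin_centers <- function() seq(-0.75, 0.75, length.out = 8)

#' Binned feature predictors for the weighting regression
#'
#' For each trial, tallies the tilts into 8 equally spaced feature bins and
#' records the sum of tilt values falling in each bin (0 when empty). Only
#' meaningful after wraparound exclusion, when every tilt lies inside
#' `[-0.79, 0.79]` rad.
#'
#' @param trials trial table (post-exclusion).
#' @param centers bin centers (default [weight_bin_centers()]).
#' @param edge_limit outer edge of the first/last bin, radians.
#' @return n x 8 matrix of per-bin signed feature sums.
#' @export
bin_predictors <- function(trials, centers = weight_bin_centers(),
                           edge_limit = 0.79) {
  X <- feature_matrix(trials)
  if (any(abs(X) > edge_limit)) {
    stop("features outside [-", edge_limit, ", ", edge_limit,
         "] rad: exclude wraparound trials first")
  }
  edges <- bin_edges_from_centers(centers, edge_limit)
  idx <- matrix(findInterval(X, edges, rightmost.closed = TRUE),
                nrow(X), ncol(X))
  P <- matrix(0, nrow(X), length(centers))
  for (b in seq_along(centers)) {
    P[, b] <- rowSums(X * (idx == b))
  }
  colnames(P) <- sprintf("bin%d", seq_along(centers))
  P
}

#' Probit decision-weight profile
#'
#' Regresses the binary choice (CW = 1) on the 8 competitive binned feature
#' predictors (plus an intercept) with a probit GLM. The per-bin
#' coefficients form the psychophysical kernel: an inverted-U profile
#' (inliers weighted above outliers) is the signature of robust averaging.
#'
#' @param predictors matrix from [bin_predictors()].
#' @param choices choice table (or a `"CW"`/`"CCW"` character vector) aligned
#'   with the predictor rows.
#' @param centers bin centers used for labelling.
#' @return object of class `weighting_profile`: a list with
#'   `bin_centers_rad`, `coefficients`, `standard_errors`, `intercept`,
#'   `n_trials`, `inlier_mean`, `outlier_mean`, `converged`.
#' @export
probit_weights <- function(predictors, choices,
                           centers = weight_bin_centers()) {
  y <- if (is.data.frame(choices)) choices$choice else choices
  y <- as.numeric(y == "CW")
  stopifnot(length(y) == nrow(predictors))
  if (nrow(predictors) < ncol(predictors)) {
    stop("need at least as many trials as bins")
  }
  dat <- data.frame(y = y, predictors)
  fit <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial(link = "probit"), data = dat))
  sm <- summary(fit)
  co <- sm$coefficients
  beta <- co[-1, "Estimate"]
  se <- co[-1, "Std. Error"]
  nb <- length(centers)
  inl <- 3:6
  out <- c(1, 2, 7, 8)
  structure(
    list(bin_centers_rad = centers,
         coefficients = unname(beta),
         standard_errors = unname(se),
         intercept = unname(co[1, "Estimate"]),
         n_trials = nrow(predictors),
         inlier_mean = mean(beta[inl]),
         outlier_mean = mean(beta[out]),
         inlier_bins = inl, outlier_bins = out,
         converged = isTRUE(fit$converged) && !any(is.na(beta))),
    class = "weighting_profile")
}

#' @export
print.weighting_profile <- function(x, ...) {
  cat("<weighting_profile> ", x$n_trials, " trials\n", sep = "")
  print(data.frame(bin_center_rad = x$bin_centers_rad,
                   coefficient = x$coefficients,
                   se = x$standard_errors))
  cat(sprintf("inlier mean %.4f  outlier mean %.4f  contrast %.4f\n",
              x$inlier_mean, x$outlier_mean,
              x$inlier_mean - x$outlier_mean))
  invisible(x)
}

#' Inlier-minus-outlier weighting contrast
#'
#' Mean coefficient of the four inlying bins (3-6) minus that of the four
#' outlying bins (1, 2, 7, 8). Positive values indicate robust averaging.
#'
#' @param profile a [probit_weights()] result.
#' @export
inlier_outlier_contrast <- function(profile) {
  stopifnot(inherits(profile, "weighting_profile"))
  profile$inlier_mean - profile$outlier_mean
}

#' One-call weighting profile from trials and choices
#'
#' Convenience wrapper: applies the exclusion rules, bins the predictors and
#' fits the probit weighting regression.
#'
#' @inheritParams exclude_trials
#' @inheritParams bin_predictors
#' @export
weighting_profile <- function(trials, choices,
                              centers = weight_bin_centers(),
                              edge_limit = 0.79) {
  ex <- exclude_trials(trials, choices)
  P <- bin_predictors(ex$trials, centers, edge_limit)
  probit_weights(P, ex$choices, centers)
}
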
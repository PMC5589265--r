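#' Condition-wise accuracy summary
#'
#' Accuracy (and reaction-time means when present) per cell of the
#' |mu| x sigma design, after the standard exclusions, plus the low-low
#' (low |mu|, low sigma) versus high-high contrast - the two cells with an
#' identical |mu|/sigma ratio.
#'
#' @param trials,choices aligned tables.
#' @return list with `by_condition` (data.frame: mu_abs_deg, sigma_deg,
#'   n_trials, accuracy, mean_rt_ms) and `low_low_minus_high_high`.
#' @export
conditionwise_summary <- function(trials, choices) {
  ex <- exclude_trials(trials, choices)
  tr <- ex$trials
  ch <- ex$choices
  if (nrow(tr) == 0) stop("no included trials")
  cell <- interaction(abs(tr$mu_deg), tr$sigma_deg, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(tr)), cell), function(i) {
    data.frame(mu_abs_deg = abs(tr$mu_deg[i[1]]),
               sigma_deg = tr$sigma_deg[i[1]],
               n_trials = length(i),
               accuracy = mean(ch$correct[i]),
               mean_rt_ms = if (all(is.na(ch$rt_ms[i]))) NA_real_
                            else mean(ch$rt_ms[i], na.rm = TRUE))
  }))
  agg <- agg[order(agg$mu_abs_deg, agg$sigma_deg), ]
  rownames(agg) <- NULL
  mus <- sort(unique(agg$mu_abs_deg))
  sds <- sort(unique(agg$sigma_deg))
  ll <- agg$accuracy[agg$mu_abs_deg == mus[1] & agg$sigma_deg == sds[1]]
  hh <- agg$accuracy[agg$mu_abs_deg == mus[length(mus)] &
                       agg$sigma_deg == sds[length(sds)]]
  list(by_condition = agg,
       low_low_minus_high_high = if (length(ll) == 1 && length(hh) == 1)
         ll - hh else NA_real_)
}

#' Signal-detection sensitivity by condition
#'
#' d-prime per |mu| x sigma cell with clockwise as the signal class:
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)`. Extreme rates (0 or 1)
#' are corrected by the 1/(2N) rule before the quantile transform.
#'
#' @param trials,choices aligned tables.
#' @return data.frame: mu_abs_deg, sigma_deg, n_cw, n_ccw, hit_rate,
#'   fa_rate, dprime.
#' @export
dprime_by_condition <- function(trials, choices) {
  ex <- exclude_trials(trials, choices)
  tr <- ex$trials
  ch <- ex$choices
  cell <- interaction(abs(tr$mu_deg), tr$sigma_deg, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(tr)), cell), function(i) {
    cw <- tr$correct_category[i] == "CW"
    said_cw <- ch$choice[i] == "CW"
    n_cw <- sum(cw)
    n_ccw <- sum(!cw)
    if (n_cw == 0 || n_ccw == 0) {
      stop("condition cell lacks one ground-truth class; cannot form d'")
    }
    hit <- clamp(mean(said_cw[cw]), 1 / (2 * n_cw), 1 - 1 / (2 * n_cw))
    fa <- clamp(mean(said_cw[!cw]), 1 / (2 * n_ccw), 1 - 1 / (2 * n_ccw))
    data.frame(mu_abs_deg = abs(tr$mu_deg[i[1]]),
               sigma_deg = tr$sigma_deg[i[1]],
               n_cw = n_cw, n_ccw = n_ccw,
               hit_rate = hit, fa_rate = fa,
               dprime = stats::qnorm(hit) - stats::qnorm(fa))
  }))
  out <- out[order(out$mu_abs_deg, out$sigma_deg), ]
  rownames(out) <- NULL
  out
}

#' Standalone d-prime from hit and false-alarm rates
#'
#' @param hit_rate,fa_rate rates in `[0, 1]`.
#' @param n_signal,n_noise trial counts for the 1/(2N) extreme-rate
#'   correction; omit to use the raw rates.
#' @export
dprime <- function(hit_rate, fa_rate, n_signal = NULL, n_noise = NULL) {
  if (!is.null(n_signal)) {
    hit_rate <- clamp(hit_rate, 1 / (2 * n_signal), 1 - 1 / (2 * n_signal))
  }
  if (!is.null(n_noise)) {
    fa_rate <- clamp(fa_rate, 1 / (2 * n_noise), 1 - 1 / (2 * n_noise))
  }
  stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
}

#' Split-half regression linking decision policy to performance
#'
#' For each subject: apply the exclusion rules, split the included trials
#' into even and odd halves, fit (k, s) of the power model on the even half
#' by [grid_fit()], compute accuracy on the held-out odd half, then regress
#' accuracy on `[1, k, s, s*k]` across subjects by ordinary least squares.
#' A negative k coefficient means stronger robust averaging predicts better
#' held-out performance. Subjects below 60% overall accuracy are dropped
#' before fitting.
#'
#' @param subjects list; each element a list with `trials` and `choices`.
#' @param parity `"post_exclusion"` (default) splits by ordinal position
#'   among included trials; `"raw"` splits by the original trial index.
#' @param k_grid,s_grid fitting grids.
#' @param accuracy_threshold subject-exclusion floor (proportion correct).
#' @return object of class `link_regression`: `coefficients` (data.frame
#'   with estimate, se, t, 95% CI for intercept, k, s, s:k), `n_subjects`,
#'   `subjects` (per-subject k_hat, s_hat, accuracy_odd), `rank_deficient`.
#' @export
split_half_link_regression <- function(subjects,
                                       parity = c("post_exclusion", "raw"),
                                       k_grid = default_k_grid(),
                                       s_grid = default_s_grid(),
                                       accuracy_threshold = 0.6) {
  parity <- match.arg(parity)
  rows <- list()
  for (sid in seq_along(subjects)) {
    su <- subjects[[sid]]
    ex <- exclude_trials(su$trials, su$choices)
    if (mean(ex$choices$correct) < accuracy_threshold) next
    ord <- if (parity == "post_exclusion") seq_len(nrow(ex$trials)) - 1L
           else ex$trials$trial_index
    even <- ord %% 2L == 0L
    if (sum(even) == 0 || sum(!even) == 0) {
      stop("subject ", sid, ": one split half is empty")
    }
    fit <- grid_fit(ex$trials[even, ], ex$choices[even, ],
                    "power_late", k_grid, s_grid)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = sid,
      k_hat = fit$best_params$k, s_hat = fit$best_params$s,
      accuracy_odd = mean(ex$choices$correct[!even]))
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 8) {
    stop("need at least 8 included subjects for the link regression")
  }
  fit <- stats::lm(accuracy_odd ~ k_hat + s_hat + s_hat:k_hat, data = tab)
  beta <- stats::coef(fit)
  rank_deficient <- anyNA(beta)
  if (rank_deficient) {
    warning("link regression design is rank deficient (aliased coefficients)")
    co <- data.frame(term = names(beta), estimate = unname(beta),
                     se = NA_real_, t = NA_real_,
                     ci_lo = NA_real_, ci_hi = NA_real_)
  } else {
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit)
    co <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                     se = sm[, "Std. Error"], t = sm[, "t value"],
                     ci_lo = ci[, 1], ci_hi = ci[, 2])
  }
  rownames(co) <- NULL
  structure(list(coefficients = co, n_subjects = nrow(tab), subjects = tab,
                 rank_deficient = rank_deficient, parity = parity),
            class = "link_regression")
}

#' @export
print.link_regression <- function(x, ...) {
  cat(sprintf("<link_regression> %d subjects (%s parity)\n",
              x$n_subjects, x$parity))
  print(x$coefficients)
  invisible(x)
}
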
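#' Pipeline configuration
#'
#' Everything needed to run the whole analysis end to end on synthetic
#' observers: session design, the range the cohort's true (k, s) are drawn
#' from, fitting grids, and a master seed from which every stage's seed is
#' derived deterministically.
#'
#' @param n_subjects number of simulated observers (>= 1).
#' @param session session template (a [session_config()]); each subject and
#'   session kind gets a derived seed.
#' @param k_range,s_range ranges the subjects' true parameters are drawn
#'   uniformly from.
#' @param k_points,s_points fitting-grid resolutions.
#' @param surface_k_points,surface_s_points,surface_trials accuracy-surface
#'   settings.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 8L,
                            session = session_config(),
                            k_range = c(0.3, 1.2),
                            s_range = c(0.2, 2),
                            k_points = 100L, s_points = 100L,
                            surface_k_points = 25L, surface_s_points = 8L,
                            surface_trials = 4096L,
                            seed = 1L) {
  if (n_subjects < 1) stop("need at least one subject")
  stopifnot(inherits(session, "session_config"))
  structure(list(n_subjects = as.integer(n_subjects), session = session,
                 k_range = k_range, s_range = s_range,
                 k_points = as.integer(k_points),
                 s_points = as.integer(s_points),
                 surface_k_points = as.integer(surface_k_points),
                 surface_s_points = as.integer(surface_s_points),
                 surface_trials = as.integer(surface_trials),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' generate sessions -> simulate observers -> grid fits -> weighting
#' profiles -> accuracy / difference surfaces -> cohort link regression,
#' writing every artifact (CSV/JSON) plus a manifest with stage seeds and
#' file MD5 hashes to `out_dir`. Two runs with the same config produce
#' byte-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print one line per stage.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  master <- config$seed
  set.seed(derive_seed(master, 1L))
  k_true <- stats::runif(config$n_subjects, config$k_range[1], config$k_range[2])
  s_true <- stats::runif(config$n_subjects, config$s_range[1], config$s_range[2])
  k_grid <- default_k_grid(config$k_points)
  s_grid <- default_s_grid(config$s_points)
  files <- character(0)
  subjects <- list()
  fits <- list()
  for (i in seq_len(config$n_subjects)) {
    sess <- config$session
    sess$session_id <- sprintf("subj%02d", i)
    sess$seed <- derive_seed(master, 2L, i)
    trials <- generate_session(sess)
    truth <- observer_params("power_late", k = k_true[i], s = s_true[i])
    choices <- simulate_observer(trials, truth,
                                 seed = derive_seed(master, 3L, i))
    tf <- file.path(out_dir, sprintf("trials_subj%02d.csv", i))
    cf <- file.path(out_dir, sprintf("choices_subj%02d.csv", i))
    write_trials(trials, tf)
    write_choices(choices, cf)
    files <- c(files, tf, cf)
    fit <- grid_fit(trials, choices, "power_late", k_grid, s_grid)
    ff <- file.path(out_dir, sprintf("fit_subj%02d.json", i))
    write_fit(fit, ff)
    files <- c(files, ff)
    prof <- weighting_profile(trials, choices)
    pf <- file.path(out_dir, sprintf("profile_subj%02d.csv", i))
    write_profile(prof, pf)
    files <- c(files, pf)
    subjects[[i]] <- list(trials = trials, choices = choices)
    fits[[i]] <- fit
    say("subject %02d: true(k=%.3f,s=%.3f) fit(k=%.3f,s=%.3f)",
        i, k_true[i], s_true[i], fit$best_params$k, fit$best_params$s)
  }
  stim <- generate_session(session_config(
    n_blocks = max(1L, config$surface_trials %/% config$session$trials_per_block),
    trials_per_block = config$session$trials_per_block,
    session_id = "surface_stimuli", seed = derive_seed(master, 4L)))
  ps <- simulate_accuracy_surface(
    stim, "power", k_grid = seq(0.02, 2, length.out = config$surface_k_points),
    s_grid = exp(seq(log(0.05), log(5), length.out = config$surface_s_points)),
    seed = derive_seed(master, 5L))
  ls <- simulate_accuracy_surface(
    stim, "linear_equivalent",
    k_grid = ps$k_grid, s_grid = ps$s_grid, seed = derive_seed(master, 5L))
  sf <- file.path(out_dir, "surface_power.csv")
  lf <- file.path(out_dir, "surface_linear.csv")
  write_surface(ps, sf)
  write_surface(ls, lf)
  files <- c(files, sf, lf)
  say("surfaces: %d x %d grid on %d trials",
      length(ps$s_grid), length(ps$k_grid), ps$n_reps)
  link <- if (config$n_subjects >= 8) {
    split_half_link_regression(subjects, k_grid = k_grid, s_grid = s_grid)
  }
  if (!is.null(link)) {
    kf <- file.path(out_dir, "link_regression.json")
    jsonlite::write_json(list(coefficients = link$coefficients,
                              n_subjects = link$n_subjects,
                              subjects = link$subjects),
                         kf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, kf)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("robustavg")),
    seed = master,
    n_subjects = config$n_subjects,
    true_params = data.frame(subject = seq_len(config$n_subjects),
                             k_true = k_true, s_true = s_true),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline done in %.1fs (%d artifacts)", manifest$wall_time_s,
      length(files))
  invisible(manifest)
}
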
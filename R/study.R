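#' Configuration for a synthetic study
#'
#' Describes a complete synthetic experiment: subjects with a known
#' generative decision model and parameters, performing blocks of both
#' visibility conditions until each block reaches the correct-answer quota.
#' Defaults mirror the experimental design this package models: 15 subjects,
#' 12 blocks (6 per condition) of 70 correct answers each, the standard
#' trial-type mix, a mean baseline reaction time of 0.347 s, and UGM
#' generative parameters — the all-stay condition without working-memory
#' leak and the all-away condition with a positive leak.
#'
#' Per-subject parameters are jittered multiplicatively (mean-preserving
#' log-normal) around the configured means and clipped to the fitting
#' bounds. The default spread matches the between-subject dispersion implied
#' by the reported group SEMs of the fitted parameters (see
#' [preset_param_spread()]); the baseline reaction time is jittered normally
#' with the between-subject standard deviation implied by its reported SEM
#' (`0.009 * sqrt(15)` s).
#'
#' @param n_subjects Number of subjects.
#' @param model Generative model, `"eam"` or `"ugm"`.
#' @param params_all_stay,params_all_away [model_params()] used per
#'   condition (the all-stay parameters should have `leak = 0`).
#' @param blocks_per_condition Blocks per visibility condition.
#' @param correct_per_block Correct answers required to finish a block.
#' @param chunk_size Trials generated per batch while filling a block.
#' @param mix Trial-type proportions, see [default_mix()].
#' @param baseline_mean,baseline_sd Baseline reaction time distribution, s.
#' @param param_jitter_sd Log-scale SD of the per-subject parameter jitter:
#'   a scalar applied to all free parameters, a named vector over
#'   `nu`/`eta`/`theta`/`leak`, or `NULL` (default) for the SEM-matched
#'   spread of the chosen model, per condition.
#' @param trial_cap_factor Abort a block after
#'   `trial_cap_factor * correct_per_block / 0.5` trials (protects against
#'   near-chance parameter sets that cannot reach the quota).
#' @param config A [task_config()].
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_subjects = 15L, model = c("ugm", "eam"),
                         params_all_stay = NULL, params_all_away = NULL,
                         blocks_per_condition = 6L, correct_per_block = 70L,
                         chunk_size = 40L, mix = default_mix(),
                         baseline_mean = 0.347,
                         baseline_sd = 0.009 * sqrt(15),
                         param_jitter_sd = NULL, trial_cap_factor = 10,
                         config = task_config()) {
  model <- match.arg(model)
  if (is.null(params_all_stay))
    params_all_stay <- preset_params(model, "all_stay")
  if (is.null(params_all_away))
    params_all_away <- preset_params(model, "all_away_leak")
  if (is.null(param_jitter_sd))
    param_jitter_sd <- list(
      all_stay = preset_param_spread(model, "all_stay"),
      all_away = preset_param_spread(model, "all_away_leak"))
  if (!is.list(param_jitter_sd))
    param_jitter_sd <- list(all_stay = param_jitter_sd,
                            all_away = param_jitter_sd)
  if (n_subjects < 1) stop("`n_subjects` must be >= 1")
  structure(list(n_subjects = as.integer(n_subjects), model = model,
                 params_all_stay = params_all_stay,
                 params_all_away = params_all_away,
                 blocks_per_condition = as.integer(blocks_per_condition),
                 correct_per_block = as.integer(correct_per_block),
                 chunk_size = as.integer(chunk_size), mix = mix,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 param_jitter_sd = param_jitter_sd,
                 trial_cap_factor = trial_cap_factor, task = config),
            class = "study_config")
}

#' Between-subject spread of the reference parameters
#'
#' Per-parameter log-normal spread (`sdlog`) matched to the across-subject
#' dispersion implied by the reported group SEMs (SEM times `sqrt(15)` gives
#' the between-subject SD; the coefficient of variation `c` maps to
#' `sdlog = sqrt(log(1 + c^2))`). Used as the default subject-to-subject
#' jitter in [study_config()].
#'
#' @inheritParams preset_params
#' @return Named vector of `sdlog` values for `nu`, `eta`, `theta`, `leak`.
#' @export
preset_param_spread <- function(model = c("eam", "ugm"),
                                condition = c("all_stay", "all_away_noleak",
                                              "all_away_leak")) {
  model <- match.arg(model)
  condition <- match.arg(condition)
  sem <- switch(paste(model, condition, sep = "."),
    eam.all_stay       = c(0.00183, 0.00140, 0.01289, NA),
    ugm.all_stay       = c(0.61932, 3.35522, 1124.45466, NA),
    eam.all_away_noleak = c(0.01519, 0.01464, 0.06876, NA),
    ugm.all_away_noleak = c(2.55487, 20.17686, 6304.48655, NA),
    eam.all_away_leak  = c(0.00654, 0.00319, 0.01986, 0.04727),
    ugm.all_away_leak  = c(0.64309, 5.08468, 1736.69700, 0.04929))
  p <- preset_params(model, condition)
  means <- c(p$nu, p$eta, p$theta, if (p$leak > 0) p$leak else NA)
  cv <- sem * sqrt(15) / means
  out <- sqrt(log(1 + cv^2))
  out[is.na(out)] <- 0
  stats::setNames(out, c("nu", "eta", "theta", "leak"))
}

# Mean-preserving multiplicative log-normal jitter of the free parameters
# (meanlog offset -sdlog^2/2 so the across-subject mean matches the
# configured value), clipped to the fitting bounds so every synthetic
# subject stays inside the search box.
jitter_params <- function(params, sdlog) {
  if (length(sdlog) == 1)
    sdlog <- stats::setNames(rep(sdlog, 4), c("nu", "eta", "theta", "leak"))
  b <- default_bounds(params$model,
                      if (params$leak > 0) "free" else "fixed")
  jit <- function(x, name) {
    if (x == 0) return(0)
    s <- sdlog[[name]]
    min(max(x * rlnorm(1, -s^2 / 2, s), b$lower[[name]]), b$upper[[name]])
  }
  model_params(params$model,
               nu = jit(params$nu, "nu"), eta = jit(params$eta, "eta"),
               theta = jit(params$theta, "theta"),
               leak = if (params$leak > 0) jit(params$leak, "leak") else 0)
}

#' Generate one synthetic subject
#'
#' Simulates a subject's full session: for each condition, blocks of trials
#' are generated with the configured trial-type mix and played through the
#' generative decision model until the block accumulates the required number
#' of correct answers (the block ends at the trial achieving the quota). Raw
#' reaction times are emitted as `dt_ms / 1000 + baseline_rt`, so the
#' analysis stage must perform the baseline subtraction.
#'
#' @param config A [study_config()].
#' @param subject_index Subject number (used in the subject id).
#' @param seed Integer seed for this subject.
#' @return A list with `trials`, `decisions`, `baseline` (data frames) and
#'   `truth` (the subject's generative parameters per condition).
#' @export
generate_subject <- function(config, subject_index, seed = NULL) {
  stopifnot(inherits(config, "study_config"))
  with_seed(seed, function() {
    sid <- sprintf("S%02d", subject_index)
    baseline <- max(0.05, rnorm(1, config$baseline_mean, config$baseline_sd))
    truth <- list(
      all_stay = jitter_params(config$params_all_stay,
                               config$param_jitter_sd$all_stay),
      all_away = jitter_params(config$params_all_away,
                               config$param_jitter_sd$all_away))
    trials_all <- list()
    dec_all <- list()
    cap <- ceiling(config$trial_cap_factor * config$correct_per_block / 0.5)
    for (cond in c("all_stay", "all_away")) {
      pars <- truth[[cond]]
      for (blk in seq_len(config$blocks_per_condition)) {
        tri <- NULL
        dec <- NULL
        n_correct <- 0L
        while (n_correct < config$correct_per_block) {
          if (!is.null(tri) && nrow(tri) >= cap)
            stop("block cannot reach ", config$correct_per_block,
                 " correct answers within ", cap, " trials; generative ",
                 "parameters appear to perform near chance")
          chunk <- generate_block(config$chunk_size, config$mix, cond,
                                  config = config$task)
          sim <- simulate_dataset(chunk, config$model, pars, n_reps = 1L,
                                  compute_sp = FALSE, config = config$task)
          tri <- rbind(tri, chunk)
          dec <- rbind(dec, sim)
          n_correct <- sum(dec$correct)
        }
        keep <- seq_len(which(cumsum(dec$correct) ==
                                config$correct_per_block)[1])
        tri <- tri[keep, , drop = FALSE]
        dec <- dec[keep, , drop = FALSE]
        tri$trial_index <- dec$trial <- seq_along(keep)
        tri$subject_id <- dec$subject_id <- sid
        tri$block <- dec$block <- blk
        tri$condition <- dec$condition <- cond
        dec$trial_index <- dec$trial
        dec$raw_rt_s <- dec$dt_ms / 1000 + baseline
        trials_all[[paste(cond, blk)]] <- tri
        dec_all[[paste(cond, blk)]] <- dec
      }
    }
    trials <- do.call(rbind, trials_all)
    decisions <- do.call(rbind, dec_all)
    rownames(trials) <- rownames(decisions) <- NULL
    cols <- c("subject_id", "condition", "block", "trial_index",
              "trial_type", "choice", "raw_rt_s", "correct", "censored")
    list(trials = trials[, c("subject_id", "condition", "block",
                             "trial_index", "trial_type", "directions",
                             "reference_target", "correct_target")],
         decisions = decisions[, cols],
         baseline = data.frame(subject_id = sid, baseline_rt_s = baseline,
                               stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Generate a complete synthetic study
#'
#' Independent subjects generated under [generate_subject()], bundled with
#' the ground-truth generative parameters so downstream fitting and
#' statistics can be validated end to end.
#'
#' @param config A [study_config()].
#' @param seed Master integer seed; per-subject seeds are derived from it.
#' @return A list of class `token_study` with `trials`, `decisions`,
#'   `baseline` (row-bound data frames), `truth` (per-subject list) and
#'   `config`.
#' @export
generate_study <- function(config = study_config(), seed = NULL) {
  subject_seeds <- with_seed(seed, function()
    sample.int(.Machine$integer.max, config$n_subjects))
  subjects <- lapply(seq_len(config$n_subjects), function(i)
    generate_subject(config, i, seed = subject_seeds[i]))
  structure(list(
    trials = do.call(rbind, lapply(subjects, `[[`, "trials")),
    decisions = do.call(rbind, lapply(subjects, `[[`, "decisions")),
    baseline = do.call(rbind, lapply(subjects, `[[`, "baseline")),
    truth = stats::setNames(lapply(subjects, `[[`, "truth"),
                            vapply(subjects, function(s)
                              s$baseline$subject_id, character(1))),
    config = config), class = "token_study")
}

#' Write and read a study bundle directory
#'
#' The bundle layout is `trials.csv`, `decisions.csv`, `baseline.csv` and
#' `truth.json` inside `dir`.
#'
#' @param study A `token_study`.
#' @param dir Directory path (created if needed).
#' @return `read_study()` returns a `token_study` (without the original
#'   `config`).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trials_csv(study$trials, file.path(dir, "trials.csv"))
  write_decisions_csv(study$decisions, file.path(dir, "decisions.csv"))
  write.csv(study$baseline, file.path(dir, "baseline.csv"),
            row.names = FALSE)
  truth <- lapply(study$truth, function(tr)
    lapply(tr, function(p) p[c("model", "nu", "eta", "theta", "leak")]))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  truth_raw <- jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = FALSE)
  truth <- lapply(truth_raw, function(tr)
    lapply(tr, function(p)
      model_params(p$model, nu = p$nu, eta = p$eta, theta = p$theta,
                   leak = p$leak)))
  structure(list(
    trials = read_trials_csv(file.path(dir, "trials.csv")),
    decisions = read_decisions_csv(file.path(dir, "decisions.csv")),
    baseline = read.csv(file.path(dir, "baseline.csv"),
                        stringsAsFactors = FALSE),
    truth = truth), class = "token_study")
}
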
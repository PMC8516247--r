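#' Decision-model parameters
#'
#' Free parameters of the two decision models plus the fixed simulation
#' constants. `nu` is the mean drift rate, `eta` its between-trial standard
#' deviation (the drift used in a trial is a fresh draw from
#' `N(nu, eta)`), `theta` the decision boundary (boundary separation for the
#' EAM, urgency threshold for the UGM) and `leak` the per-jump working-memory
#' leak fraction applied to the evidence in the all-away condition. The
#' diffusion scale `s` (0.1), step size `dt` (10 ms) and UGM low-pass time
#' constant `tau` (100 ms) are fixed by convention.
#'
#' @param model `"eam"` or `"ugm"`.
#' @param nu Mean drift rate (> 0 in practice).
#' @param eta Drift-rate standard deviation, `>= 0`.
#' @param theta Boundary, `> 0`.
#' @param leak Working-memory leak fraction in `[0, 1]`.
#' @param s Diffusion scale (fixed, 0.1).
#' @param dt Simulation step, ms (fixed, 10).
#' @param tau UGM low-pass time constant, ms (fixed, 100).
#' @return A list of class `model_params`.
#' @export
model_params <- function(model = c("eam", "ugm"), nu, eta, theta, leak = 0,
                         s = 0.1, dt = 10, tau = 100) {
  model <- match.arg(model)
  if (theta <= 0) stop("`theta` must be > 0")
  if (eta < 0) stop("`eta` must be >= 0")
  if (leak < 0 || leak > 1) stop("`leak` must lie in [0, 1]")
  if (dt <= 0 || tau <= 0) stop("`dt` and `tau` must be > 0")
  structure(list(model = model, nu = nu, eta = eta, theta = theta,
                 leak = leak, s = s, dt = dt, tau = tau),
            class = "model_params")
}

#' Reference parameter sets
#'
#' Group-mean best-fit parameters for human performance on the tokens task,
#' used as generator defaults throughout the package. Three fitting regimes
#' exist per model: the all-stay condition (no working-memory leak), the
#' all-away condition modeled without leak, and the all-away condition with
#' the leak fraction as a free parameter.
#'
#' @param model `"eam"` or `"ugm"`.
#' @param condition `"all_stay"`, `"all_away_noleak"` or `"all_away_leak"`.
#' @return A [model_params()] object.
#' @export
preset_params <- function(model = c("eam", "ugm"),
                          condition = c("all_stay", "all_away_noleak",
                                        "all_away_leak")) {
  model <- match.arg(model)
  condition <- match.arg(condition)
  p <- switch(paste(model, condition, sep = "."),
    eam.all_stay       = c(0.04456, 0.00478, 0.29062, 0),
    ugm.all_stay       = c(3.76432, 7.65377, 23022.92488, 0),
    eam.all_away_noleak = c(0.03915, 0.01345, 0.25270, 0),
    ugm.all_away_noleak = c(4.12036, 12.84759, 18791.13380, 0),
    eam.all_away_leak  = c(0.06918, 0.01751, 0.26127, 0.12341),
    ugm.all_away_leak  = c(5.05699, 13.03403, 17660.64882, 0.21371))
  model_params(model, nu = p[1], eta = p[2], theta = p[3], leak = p[4])
}

#' Evidence trace of a trial
#'
#' The raw evidence `e` after jump `j` is the running count difference in
#' the trial's direction frame (`+1` per jump toward the reference target,
#' `-1` otherwise). The working-memory signal applies a fractional leak at
#' each jump onset and is frozen in between:
#' `e_leak[j] = (1 - leak) * e_leak[j-1] + d[j]`, with `e_leak[0] = 0`.
#' With `leak = 0` the two signals coincide; with `leak = 1` only the newest
#' jump is remembered.
#'
#' @param trial A `token_trial`.
#' @param leak Leak fraction in `[0, 1]`.
#' @param config A [task_config()] (sets the jump interval).
#' @return A list of class `evidence_trace` with fields `times` (jump onset
#'   times, ms), `e`, `e_leak`, and the originating trial as attribute
#'   `"trial"`.
#' @export
evidence_from_trial <- function(trial, leak = 0, config = task_config()) {
  stopifnot(inherits(trial, "token_trial"))
  if (leak < 0 || leak > 1) stop("`leak` must lie in [0, 1]")
  d <- trial$directions
  e_leak <- leaky_filter(matrix(d, nrow = 1), leak)[1, ]
  structure(list(times = config$jump_interval * seq_along(d),
                 e = cumsum(d), e_leak = e_leak),
            class = "evidence_trace", trial = trial)
}

# Leaky per-jump accumulation applied rowwise to a directions matrix.
leaky_filter <- function(dirmat, leak) {
  out <- dirmat * 0
  prev <- numeric(nrow(dirmat))
  for (j in seq_len(ncol(dirmat))) {
    prev <- (1 - leak) * prev + dirmat[, j]
    out[, j] <- prev
  }
  out
}

#' Construct an evidence trace directly
#'
#' Mainly for analytic tests: a piecewise-constant evidence signal with value
#' `values[j]` holding from `times[j]` until the next time point (0 before
#' `times[1]`).
#'
#' @param times Onset times, ms (nondecreasing).
#' @param values Evidence values after each onset.
#' @return An `evidence_trace` (with `e = e_leak = values`).
#' @export
evidence_trace <- function(times, values) {
  stopifnot(length(times) == length(values), !is.unsorted(times))
  structure(list(times = as.numeric(times), e = as.numeric(values),
                 e_leak = as.numeric(values)),
            class = "evidence_trace")
}

#' Simulate one decision from an evidence trace
#'
#' Runs the evidence accumulation model (EAM) or the urgency gating model
#' (UGM) on a piecewise-constant evidence signal until a boundary crossing
#' or the deadline.
#'
#' EAM: the accumulator starts at `theta/2` and each 10-ms step adds
#' `v * e(t) * 0.01 + s * xi * 0.1` (drift integrates evidence with the step
#' expressed in seconds; `xi` is standard normal, `v ~ N(nu, eta)` drawn once
#' per trial). A decision is made when `x > theta` (choice `+1`) or `x < 0`
#' (choice `-1`).
#'
#' UGM: the evidence drive `v * e(t) + s * xi` is low-pass filtered,
#' `x <- tau/(tau+dt) * x + dt/(tau+dt) * drive`, and multiplied by the
#' urgency signal `u = t` (elapsed time, ms); a decision is made when
#' `x * u` crosses `+theta` or `-theta`. With this convention the filter
#' state tracks `nu * e`, which is what gives fitted urgency thresholds their
#' characteristic 10^4 magnitude.
#'
#' In both models the decision time is `t - dt/2` for a crossing at step
#' time `t`. Decisions are only allowed strictly before `deadline` (the last
#' token jump); otherwise the trial is censored: the choice is forced from
#' the sign of the decision variable (ties broken at random) and `dt_ms` set
#' to the deadline.
#'
#' @param trace An `evidence_trace`; the model consumes its `e_leak` signal
#'   (equal to `e` when the leak is 0).
#' @param params A [model_params()].
#' @param seed Optional integer seed.
#' @param deadline Decision deadline, ms (default: time of the last token
#'   jump, 3000 ms for the standard task).
#' @return A list of class `simulated_decision`: `choice` (`+1`/`-1` in the
#'   trace's direction frame), `dt_ms`, `censored`, and — when the trace
#'   carries its originating trial — `correct` and `sp_at_dt`.
#' @export
simulate_eam <- function(trace, params, seed = NULL, deadline = NULL) {
  simulate_trace(trace, params, model_code = 0L, seed = seed,
                 deadline = deadline)
}

#' @rdname simulate_eam
#' @export
simulate_ugm <- function(trace, params, seed = NULL, deadline = NULL) {
  simulate_trace(trace, params, model_code = 1L, seed = seed,
                 deadline = deadline)
}

simulate_trace <- function(trace, params, model_code, seed, deadline) {
  stopifnot(inherits(trace, "evidence_trace"),
            inherits(params, "model_params"))
  if (is.null(deadline)) deadline <- default_deadline(trace)
  cseed <- with_seed(seed, draw_seed)
  res <- cpp_simulate_batch(matrix(trace$e_leak, nrow = 1), trace$times,
                            model_code, params$nu, params$eta, params$theta,
                            params$s, params$dt, params$tau, deadline,
                            1L, cseed)
  out <- list(choice = res$choice[1], dt_ms = res$dt_ms[1],
              censored = res$censored[1] == 1L)
  trial <- attr(trace, "trial")
  if (!is.null(trial)) {
    out$correct <- out$choice == winner_sign(trial)
    out$sp_at_dt <- sp_at_decision(trial, out$dt_ms,
                                   out$choice)[["sp"]]
  }
  structure(out, class = "simulated_decision")
}

# Deadline of a trace: the last token jump for trial-derived traces, and
# the standard 3000 ms trial span otherwise (custom analytic traces may
# start at t = 0, so max(times) is not a usable deadline).
default_deadline <- function(trace) {
  trial <- attr(trace, "trial")
  if (!is.null(trial)) return(max(trace$times))
  max(3000, trace$times)
}

# Success probability of the chosen target at the token state holding at the
# decision time (the state after the last jump with onset <= dt_ms).
sp_at_decision <- function(trial, dt_ms, choice,
                           jump_interval = 200) {
  n <- trial$n_tokens
  k <- min(floor(dt_ms / jump_interval), n)
  pos <- if (k > 0) sum(trial$directions[seq_len(k)] == 1L) else 0L
  neg <- k - pos
  sp <- if (choice == 1L) success_probability(pos, neg, n - k, n)
        else success_probability(neg, pos, n - k, n)
  list(sp = sp, jumps_seen = k)
}

#' Simulate a decision dataset
#'
#' Batch simulation of one decision model over a set of trials, with
#' `n_reps` independent replicates per trial. The working-memory leak in
#' `params` is applied to every trial's evidence (use `leak = 0` for the
#' all-stay condition). Correctness is scored against each trial's final
#' token majority, and `sp_at_dt` is the success probability of the chosen
#' target at the token state holding at the decision time.
#'
#' @param trials A `token_trials` data frame (or list of `token_trial`).
#' @param model `"eam"` or `"ugm"`.
#' @param params A [model_params()] (its `model` field is overridden by
#'   `model` if they disagree).
#' @param n_reps Replicates per trial, `>= 1`.
#' @param seed Optional integer seed.
#' @param compute_sp If `FALSE`, skip the success-probability column (used
#'   internally by the fitting loop, which only needs decision times and
#'   correctness).
#' @param config A [task_config()].
#' @return A data frame with one row per simulated decision: `trial`, `rep`,
#'   `trial_type`, `choice`, `dt_ms`, `correct`, `censored` and (optionally)
#'   `sp_at_dt`.
#' @export
simulate_dataset <- function(trials, model = c("eam", "ugm"), params,
                             n_reps = 1L, seed = NULL, compute_sp = TRUE,
                             config = task_config()) {
  model <- match.arg(model)
  if (!is.data.frame(trials)) trials <- trials_to_df(trials)
  if (nrow(trials) == 0) stop("empty trial set")
  if (n_reps < 1) stop("`n_reps` must be >= 1")
  dirmat <- directions_matrix(trials)
  cseed <- with_seed(seed, draw_seed)
  res <- simulate_directions(dirmat, model, params, n_reps, cseed, config)
  out <- data.frame(trial = res$trial, rep = res$rep,
                    trial_type = trials$trial_type[res$trial],
                    choice = res$choice, dt_ms = res$dt_ms,
                    correct = res$choice == res$winner,
                    censored = res$censored == 1L,
                    stringsAsFactors = FALSE)
  if (compute_sp) {
    out$sp_at_dt <- sp_for_rows(dirmat, res$trial, out$dt_ms, out$choice,
                                config)
  }
  out
}

# Low-level batch path shared by simulate_dataset() and the fitting loop:
# takes a directions matrix, applies the leak, runs the C++ core.
simulate_directions <- function(dirmat, model, params, n_reps, cseed,
                                config = task_config()) {
  evid <- leaky_filter(dirmat, params$leak)
  times <- config$jump_interval * seq_len(ncol(dirmat))
  deadline <- config$jump_interval * config$n_tokens
  res <- cpp_simulate_batch(evid, times,
                            if (model == "eam") 0L else 1L,
                            params$nu, params$eta, params$theta,
                            params$s, params$dt, params$tau, deadline,
                            as.integer(n_reps), cseed)
  res$winner <- ifelse(rowSums(dirmat) > 0, 1L, -1L)[res$trial]
  res
}

# Vectorized success probability of the chosen target at decision time.
sp_for_rows <- function(dirmat, trial_idx, dt_ms, choice, config) {
  n <- ncol(dirmat)
  cum_pos <- t(apply(dirmat == 1L, 1, cumsum))
  k <- pmin(floor(dt_ms / config$jump_interval), n)
  pos <- ifelse(k > 0, cum_pos[cbind(trial_idx, pmax(k, 1L))], 0L)
  neg <- k - pos
  n1 <- ifelse(choice == 1L, pos, neg)
  n2 <- k - n1
  success_probability(n1, n2, n - k, n_tokens = n)
}

#' Read and write decision-log CSV files
#'
#' @param decisions A decisions data frame.
#' @param path File path.
#' @return `read_decisions_csv()` returns the data frame.
#' @export
write_decisions_csv <- function(decisions, path) {
  write.csv(decisions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decisions_csv
#' @export
read_decisions_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
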
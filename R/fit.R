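#' Quantile maximum products statistic
#'
#' Goodness of fit of a simulated decision-time distribution to observed
#' decision times, computed separately for correct and error responses. The
#' observed decision times of each outcome define inter-quantile bins (outer
#' bins open-ended); the statistic is
#' \deqn{\sum_{\mathrm{bins}} n_{\mathrm{obs}} \log p_{\mathrm{pred}}}
#' where `p_pred` is the predicted probability of falling in that outcome
#' and bin (so outcomes are weighted by their predicted frequencies and the
#' observed counts), floored at `eps` to keep the statistic finite when a
#' bin receives no predicted mass. Larger is better; the maximum over
#' predicted distributions with the same binning is attained when predicted
#' proportions equal observed proportions.
#'
#' When an outcome has fewer than `min_error_count` observed trials its bins
#' collapse to a single open bin, keeping the statistic defined for subjects
#' with few errors.
#'
#' @param observed,predicted Data frames with numeric `dt_ms` and logical
#'   `correct` columns. The predicted set should be a large Monte-Carlo
#'   sample.
#' @param probs Quantile probabilities defining the bins (strictly
#'   increasing, in (0, 1)).
#' @param min_error_count Minimum observed count for an outcome to keep
#'   separate bins.
#' @param eps Floor for predicted bin probabilities.
#' @return The log-product statistic (a scalar, `<= 0`).
#' @export
qmpe_statistic <- function(observed, predicted,
                           probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                           min_error_count = 5L, eps = 1e-10) {
  check_qmpe_probs(probs)
  if (!nrow(observed)) stop("observed set is empty")
  if (!nrow(predicted)) stop("predicted set is empty")
  bins <- qmpe_bins(observed, probs, min_error_count)
  qmpe_eval(bins, predicted, eps)
}

check_qmpe_probs <- function(probs) {
  if (length(probs) < 1 || any(probs <= 0 | probs >= 1) ||
      is.unsorted(probs, strictly = TRUE))
    stop("`probs` must be strictly increasing and inside (0, 1)")
}

# Precompute the observed binning: per outcome, the quantile edges and the
# observed counts per bin. Outcomes absent from the observed data are
# dropped (their predicted mass still dilutes the other bins' proportions).
qmpe_bins <- function(observed, probs, min_error_count) {
  lapply(c(correct = TRUE, error = FALSE), function(oc) {
    dts <- observed$dt_ms[observed$correct == oc]
    if (!length(dts)) return(NULL)
    if (!oc && length(dts) < min_error_count) {
      list(edges = numeric(0), counts = length(dts))
    } else {
      q <- unname(quantile(dts, probs, type = 7))
      list(edges = q, counts = tabulate(findInterval(dts, q) + 1L,
                                        length(q) + 1L))
    }
  })
}

qmpe_eval <- function(bins, predicted, eps) {
  n_total <- nrow(predicted)
  stat <- 0
  for (oc in c(TRUE, FALSE)) {
    b <- bins[[if (oc) "correct" else "error"]]
    if (is.null(b)) next
    dts <- predicted$dt_ms[predicted$correct == oc]
    n_pred <- if (length(b$edges)) {
      tabulate(findInterval(dts, b$edges) + 1L, length(b$edges) + 1L)
    } else {
      length(dts)
    }
    p <- pmax(n_pred / n_total, eps)
    stat <- stat + sum(b$counts * log(p))
  }
  stat
}

#' Log-product statistic from counts and proportions
#'
#' The elementary form of the QMPE objective: observed bin counts against
#' predicted bin proportions, `sum(n_obs * log(pmax(p_pred, eps)))`.
#'
#' @param n_obs Observed counts per bin.
#' @param p_pred Predicted proportions per bin (same length).
#' @param eps Probability floor.
#' @return The log-product statistic.
#' @export
qmpe_from_counts <- function(n_obs, p_pred, eps = 1e-10) {
  stopifnot(length(n_obs) == length(p_pred))
  sum(n_obs * log(pmax(p_pred, eps)))
}

#' Default parameter bounds for fitting
#'
#' Wide boxes bracketing the reference parameter magnitudes by more than 5x
#' on each side: `nu` in (0, 20], `eta` in [0, 50], `theta` in (0, 5] for
#' the EAM and (0, 1e5] for the UGM, and the leak in [0, 1] when free.
#'
#' @param model `"eam"` or `"ugm"`.
#' @param leak `"fixed"` or `"free"`.
#' @return A list with `lower` and `upper` named vectors.
#' @export
default_bounds <- function(model = c("eam", "ugm"),
                           leak = c("fixed", "free")) {
  model <- match.arg(model)
  leak <- match.arg(leak)
  lower <- c(nu = 1e-6, eta = 0, theta = 1e-6)
  upper <- c(nu = 20, eta = 50, theta = if (model == "eam") 5 else 1e5)
  if (leak == "free") {
    lower <- c(lower, leak = 0)
    upper <- c(upper, leak = 1)
  }
  list(lower = lower, upper = upper)
}

#' Differential-evolution search settings
#'
#' Defaults follow the estimation procedure this package models: 100
#' particles, 500 iterations and 5 restarts, with canonical DE
#' hyperparameters (rand/1/bin, F = 0.8, CR = 0.9). `n_sim` is the number of
#' simulated trials used to evaluate each candidate during the search;
#' final predictions should use [model_predictions()] at 10,000 replicates.
#'
#' @param particles Population size.
#' @param iterations Number of DE generations.
#' @param restarts Independent restarts; the best result is kept.
#' @param n_sim Simulated trials per candidate evaluation.
#' @param f Differential weight.
#' @param cr Crossover probability.
#' @return A list of class `de_control`.
#' @export
de_control <- function(particles = 100L, iterations = 500L, restarts = 5L,
                       n_sim = 2000L, f = 0.8, cr = 0.9) {
  structure(list(particles = as.integer(particles),
                 iterations = as.integer(iterations),
                 restarts = as.integer(restarts),
                 n_sim = as.integer(n_sim), f = f, cr = cr),
            class = "de_control")
}

#' Fit a decision model to observed decision times
#'
#' Maximizes the QMPE statistic over model parameters with a
#' differential-evolution search. Each candidate parameter vector is scored
#' by simulating `control$n_sim` trials (the fitted trial set cycled to that
#' size), under common random numbers within a restart so the objective is a
#' deterministic function of the parameters. The search runs in log10
#' coordinates for the scale parameters `nu`, `theta` and `eta` (whose
#' plausible values span decades within the wide boxes; `eta` with a small
#' shift since 0 is allowed) and linear coordinates for the leak. Fitting
#' pools correct and error trials of the four
#' structured trial types; random trials should be excluded from
#' `trials`/`observed` by the caller (see [fitted_type_subset()]).
#'
#' @param trials Trials data frame (the fitted trial types).
#' @param observed Observed decisions: data frame with `dt_ms` and `correct`.
#' @param model `"eam"` or `"ugm"`.
#' @param leak `"fixed"` (leak held at `leak_value`, the all-stay regime) or
#'   `"free"` (leak fitted, the all-away regime).
#' @param leak_value Leak used when `leak = "fixed"`.
#' @param bounds Parameter box, as [default_bounds()].
#' @param control A [de_control()].
#' @param probs,min_error_count QMPE settings, see [qmpe_statistic()].
#' @param seed Integer seed for the whole search.
#' @param config A [task_config()].
#' @return A list of class `fit_result`: `params` (a [model_params()]),
#'   `objective`, `per_restart_objectives` and `search_config`.
#' @export
fit_model <- function(trials, observed, model = c("eam", "ugm"),
                      leak = c("fixed", "free"), leak_value = 0,
                      bounds = NULL, control = de_control(),
                      probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                      min_error_count = 5L, seed = NULL,
                      config = task_config()) {
  model <- match.arg(model)
  leak <- match.arg(leak)
  if (is.null(bounds)) bounds <- default_bounds(model, leak)
  if (any(bounds$lower >= bounds$upper))
    stop("inverted bounds: `lower` must be < `upper`")
  check_qmpe_probs(probs)
  if (!nrow(observed)) stop("observed set is empty")

  obs_bins <- qmpe_bins(observed, probs, min_error_count)
  dirmat <- directions_matrix(trials)
  dir_sim <- dirmat[rep_len(seq_len(nrow(dirmat)), control$n_sim), ,
                    drop = FALSE]

  # nu, theta and eta are scale parameters whose plausible values span
  # decades within the wide search boxes; DE operates on log10 coordinates
  # for them (eta with a small shift since 0 is allowed; the leak stays
  # linear) so a uniform initial population covers every magnitude.
  eta_shift <- 1e-4
  logpars <- intersect(c("nu", "theta"), names(bounds$lower))
  to_search <- function(p) {
    p[logpars] <- log10(p[logpars])
    p[["eta"]] <- log10(p[["eta"]] + eta_shift)
    p
  }
  from_search <- function(p) {
    p[logpars] <- 10^p[logpars]
    p[["eta"]] <- max(10^p[["eta"]] - eta_shift, 0)
    p
  }

  objective <- function(par, sim_seed) {
    lk <- if (leak == "free") par[["leak"]] else leak_value
    p <- model_params(model, nu = par[["nu"]], eta = par[["eta"]],
                      theta = par[["theta"]], leak = lk)
    res <- simulate_directions(dir_sim, model, p, n_reps = 1L,
                               cseed = sim_seed, config = config)
    pred <- data.frame(dt_ms = res$dt_ms, correct = res$choice == res$winner)
    qmpe_eval(obs_bins, pred, eps = 1e-10)
  }

  restart_seeds <- with_seed(seed, function()
    matrix(sample.int(.Machine$integer.max, 2L * control$restarts),
           ncol = 2L))
  restarts <- lapply(seq_len(control$restarts), function(r) {
    de_optimize(function(par) objective(from_search(par),
                                        restart_seeds[r, 2L]),
                to_search(bounds$lower), to_search(bounds$upper),
                particles = control$particles,
                iterations = control$iterations,
                f = control$f, cr = control$cr,
                seed = restart_seeds[r, 1L])
  })
  objs <- vapply(restarts, `[[`, numeric(1), "objective")
  best <- restarts[[which.max(objs)]]
  par <- from_search(best$par)
  lk <- if (leak == "free") par[["leak"]] else leak_value
  structure(list(
    params = model_params(model, nu = par[["nu"]], eta = par[["eta"]],
                          theta = par[["theta"]], leak = lk),
    objective = best$objective,
    per_restart_objectives = objs,
    search_config = list(model = model, leak = leak,
                         bounds = bounds, control = control,
                         probs = probs, min_error_count = min_error_count,
                         seed = seed)),
    class = "fit_result")
}

# Differential evolution (rand/1/bin), maximizing `obj` over a box.
de_optimize <- function(obj, lower, upper, particles, iterations,
                        f = 0.8, cr = 0.9, seed = NULL) {
  d <- length(lower)
  with_seed(seed, function() {
    pop <- t(replicate(particles, lower + runif(d) * (upper - lower)))
    colnames(pop) <- names(lower)
    fit <- apply(pop, 1, obj)
    for (gen in seq_len(iterations)) {
      for (i in seq_len(particles)) {
        rs <- sample(setdiff(seq_len(particles), i), 3L)
        mutant <- pop[rs[1L], ] + f * (pop[rs[2L], ] - pop[rs[3L], ])
        cross <- runif(d) < cr
        cross[sample.int(d, 1L)] <- TRUE
        cand <- pop[i, ]
        cand[cross] <- mutant[cross]
        cand <- pmin(pmax(cand, lower), upper)
        fc <- obj(cand)
        if (fc >= fit[i]) {
          pop[i, ] <- cand
          fit[i] <- fc
        }
      }
    }
    best_i <- which.max(fit)
    list(par = pop[best_i, ], objective = fit[best_i])
  })
}

#' Subset trials and decisions to the fitted trial types
#'
#' Fitting uses all (correct and error) easy, ambiguous, bias-for and
#' bias-against trials; random trials are excluded.
#'
#' @param trials Trials data frame.
#' @param decisions Optional decisions data frame with a `trial` column
#'   indexing rows of `trials`.
#' @return `trials` (and, if given, `decisions`) restricted to the four
#'   structured types, as a list with elements `trials` and `decisions`.
#' @export
fitted_type_subset <- function(trials, decisions = NULL) {
  keep <- trials$trial_type != "random"
  idx_map <- cumsum(keep)
  out <- list(trials = trials[keep, , drop = FALSE])
  if (!is.null(decisions)) {
    dk <- decisions[keep[decisions$trial], , drop = FALSE]
    dk$trial <- idx_map[dk$trial]
    out$decisions <- dk
  }
  out
}

#' Monte-Carlo predictions from a fitted model
#'
#' Simulates the fitted model over the trial set with enough replicates to
#' reach `n_total` decisions (10,000 per experimental condition by default),
#' and, when the observed decisions are supplied, also returns a
#' matched-size resample for side-by-side distribution comparison and the
#' absolute mean decision-time discrepancy per outcome (in ms) — the summary
#' used to compare models.
#'
#' @param fit A `fit_result` from [fit_model()].
#' @param trials Trials data frame to predict on.
#' @param observed Optional observed decisions (`dt_ms`, `correct`).
#' @param n_total Total predicted decisions to aim for.
#' @param seed Optional integer seed.
#' @param config A [task_config()].
#' @return A list with `predicted` (data frame), and when `observed` is
#'   given, `matched` (resample of size `nrow(observed)`) and `discrepancy`
#'   (named vector, ms, for `correct` and `error`).
#' @export
model_predictions <- function(fit, trials, observed = NULL, n_total = 10000L,
                              seed = NULL, config = task_config()) {
  stopifnot(inherits(fit, "fit_result"))
  n_reps <- max(1L, as.integer(ceiling(n_total / nrow(trials))))
  pred <- with_seed(seed, function() {
    sim <- simulate_dataset(trials, fit$params$model, fit$params,
                            n_reps = n_reps, compute_sp = TRUE,
                            config = config)
    out <- list(predicted = sim)
    if (!is.null(observed)) {
      out$matched <- sim[sample.int(nrow(sim), nrow(observed),
                                    replace = nrow(sim) < nrow(observed)), ]
      disc <- vapply(c(correct = TRUE, error = FALSE), function(oc) {
        o <- observed$dt_ms[observed$correct == oc]
        p <- sim$dt_ms[sim$correct == oc]
        if (!length(o) || !length(p)) return(NA_real_)
        abs(mean(o) - mean(p))
      }, numeric(1))
      out$discrepancy <- disc
    }
    out
  })
  pred
}

#' Read and write fit-result JSON files
#'
#' @param fit A `fit_result`.
#' @param path File path.
#' @return `read_fit_json()` returns a list mirroring the fit result.
#' @export
write_fit_json <- function(fit, path) {
  x <- list(model = fit$params$model,
            params = fit$params[c("nu", "eta", "theta", "leak", "s", "dt",
                                  "tau")],
            objective = fit$objective,
            per_restart_objectives = fit$per_restart_objectives,
            bounds = fit$search_config$bounds,
            control = unclass(fit$search_config$control),
            seed = fit$search_config$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
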
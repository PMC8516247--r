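#' Decision time from raw reaction time
#'
#' The decision time is the raw reaction time (cursor leaving the central
#' circle, measured from trial start) minus the subject's baseline reaction
#' time, estimated as the mean over dedicated single-token calibration
#' trials. Non-positive results mark invalid trials and are returned as `NA`
#' (with a warning) so they are excluded from summaries.
#'
#' @param raw_rt Raw reaction times, s.
#' @param baseline_rt Baseline reaction time(s), s (recycled).
#' @return Decision times, s, with invalid trials set to `NA`.
#' @export
decision_time <- function(raw_rt, baseline_rt) {
  dt <- raw_rt - baseline_rt
  bad <- !is.na(dt) & dt <= 0
  if (any(bad)) {
    warning(sum(bad), " trial(s) with non-positive decision time flagged ",
            "invalid and set to NA")
    dt[bad] <- NA_real_
  }
  dt
}

#' Paired comparison of per-subject means
#'
#' Standard paired-samples t test. Degenerate inputs are guarded: identical
#' vectors give `t = 0, p = 1`; a constant non-zero difference gives an
#' infinite t and `p = 0` rather than an error.
#'
#' @param values_a,values_b Paired numeric vectors (e.g. per-subject means),
#'   equal length, `n >= 2`.
#' @return A list with `t`, `p`, `df` and `mean_diff` (`a - b`).
#' @export
paired_comparison <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length")
  n <- length(values_a)
  if (n < 2) stop("need at least 2 pairs")
  d <- values_a - values_b
  if (sd(d) <= .Machine$double.eps^0.5 * max(abs(mean(d)), 1)) {
    if (abs(mean(d)) <= .Machine$double.eps^0.5)
      return(list(t = 0, p = 1, df = n - 1, mean_diff = 0))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1,
                mean_diff = mean(d)))
  }
  tt <- t.test(values_a, values_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate))
}

#' JZS Bayes factor for a paired comparison
#'
#' Bayes factor (BF10) for the mean of paired differences against the point
#' null, with a Cauchy prior of the given scale on the standardized effect
#' size (the Jeffreys-Zellner-Siow prior). Computed as the ratio of the
#' marginal likelihood of the observed t statistic under the alternative,
#' \deqn{m_1 = \int f_{t,\nu}(t \mid \delta\sqrt{n})\,
#'   \mathrm{Cauchy}(\delta; 0, r)\, d\delta,}
#' to its density under the null, using adaptive quadrature after the
#' substitution `delta = r * tan(phi)`. Scale 3 is used for decision times
#' (large effects expected) and 0.707 for success probabilities.
#'
#' @param differences Paired differences, `n >= 2`, non-constant.
#' @param scale Cauchy prior scale `r > 0`.
#' @return BF10 (positive scalar). Values above 3 indicate evidence for a
#'   difference; below 1/3, evidence for the null.
#' @export
bayes_factor_paired <- function(differences, scale = 0.707) {
  n <- length(differences)
  if (n < 2) stop("need at least 2 differences")
  if (scale <= 0) stop("`scale` must be > 0")
  if (sd(differences) == 0) stop("differences have zero variance")
  tstat <- mean(differences) / (sd(differences) / sqrt(n))
  df <- n - 1
  m0 <- stats::dt(tstat, df)
  integrand <- function(phi) {
    ncp <- scale * tan(phi) * sqrt(n)
    suppressWarnings(stats::dt(tstat, df, ncp = ncp)) / pi
  }
  m1 <- integrate(integrand, -pi / 2, pi / 2, rel.tol = 1e-9,
                  subdivisions = 400L)$value
  m1 / m0
}

#' Shapiro-Wilk normality check
#'
#' @param values Numeric vector, `3 <= n <= 5000`, non-constant.
#' @return A list with `W` and `p`.
#' @export
normality_check <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (sd(values) == 0) stop("values are constant")
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares two trial-level distributions (e.g. decision times of two trial
#' types within a subject). Ties from the discretized simulation grid are
#' tolerated (asymptotic p value).
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return A list with `D` and `p`.
#' @export
two_sample_distribution_test <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stop("empty input")
  ks <- suppressWarnings(ks.test(values_a, values_b, exact = FALSE))
  list(D = unname(ks$statistic), p = ks$p.value)
}

#' Summarize decisions by subject, condition and trial type
#'
#' Mean and SEM of decision time (s) and of the success probability at
#' decision time, over correct trials only by default (the convention for
#' behavioral summaries; set `correct_only = FALSE` for the pooled sets used
#' in fitting).
#'
#' @param decisions Data frame with columns `dt_s`, `sp_at_dt`, `correct`
#'   and the grouping columns in `by`.
#' @param by Grouping column names present in `decisions`.
#' @param correct_only Use only correct trials.
#' @return A data frame with one row per group: the grouping columns,
#'   `n_trials`, `mean_dt`, `sem_dt`, `mean_sp`, `sem_sp`.
#' @export
summarize_decisions <- function(decisions,
                                by = intersect(c("subject_id", "condition",
                                                 "trial_type"),
                                               names(decisions)),
                                correct_only = TRUE) {
  if (correct_only) decisions <- decisions[decisions$correct, , drop = FALSE]
  decisions <- decisions[!is.na(decisions$dt_s), , drop = FALSE]
  keys <- decisions[, by, drop = FALSE]
  groups <- split(decisions, keys, drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    n <- nrow(g)
    cbind(g[1, by, drop = FALSE],
          data.frame(n_trials = n,
                     mean_dt = mean(g$dt_s),
                     sem_dt = sd(g$dt_s) / sqrt(n),
                     mean_sp = mean(g$sp_at_dt),
                     sem_sp = sd(g$sp_at_dt) / sqrt(n)))
  }))
  rownames(out) <- NULL
  out[do.call(order, out[, by, drop = FALSE]), , drop = FALSE]
}

#' Group-level behavioral analysis of a study
#'
#' Reproduces the standard analysis chain on a study bundle: subtract each
#' subject's baseline reaction time from the raw reaction times, recompute
#' the success probability of the chosen target at the decision time,
#' summarize correct trials per subject, condition and trial type, and run
#' the paired contrasts of interest — easy vs ambiguous and bias-against vs
#' bias-for, within each condition, for both decision time and success
#' probability — with paired t tests and JZS Bayes factors (Cauchy scale 3
#' for decision times, 0.707 for success probabilities).
#'
#' @param study A `token_study` from [generate_study()], or a list with
#'   `trials`, `decisions` and `baseline` data frames in the study-bundle
#'   layout.
#' @param scale_dt,scale_sp Bayes-factor prior scales for decision times and
#'   success probabilities.
#' @return A list with `per_trial` (decisions with `dt_s` and `sp_at_dt`),
#'   `summary` (per subject x condition x trial type), and `tests` (one row
#'   per contrast: `condition`, `measure`, `contrast`, group means, `t`,
#'   `p`, `bf10`, `n_subjects`).
#' @export
analyze_study <- function(study, scale_dt = 3, scale_sp = 0.707) {
  dec <- merge(study$decisions, study$baseline, by = "subject_id")
  dec$dt_s <- decision_time(dec$raw_rt_s, dec$baseline_rt_s)
  key <- c("subject_id", "condition", "block", "trial_index")
  tri <- study$trials[, c(key, "trial_type", "directions")]
  dec$trial_type <- NULL  # retaken from the trial log on merge
  dec <- merge(dec, tri, by = key, sort = FALSE)
  dec$sp_at_dt <- sp_from_log(dec$directions, dec$dt_s * 1000, dec$choice)
  summ <- summarize_decisions(dec)
  tests <- rbind(
    study_contrasts(summ, "easy", "ambiguous", scale_dt, scale_sp),
    study_contrasts(summ, "bias_against", "bias_for", scale_dt, scale_sp))
  list(per_trial = dec, summary = summ, tests = tests)
}

# SP of the chosen target at decision time, from the trial-log directions
# string; vectorized over trials.
sp_from_log <- function(directions, dt_ms, choice, jump_interval = 200) {
  n <- nchar(directions[1])
  out <- rep(NA_real_, length(dt_ms))
  ok <- !is.na(dt_ms)
  if (!any(ok)) return(out)
  dirmat <- t(vapply(directions[ok], directions_from_string, integer(n),
                     USE.NAMES = FALSE))
  out[ok] <- sp_for_rows(dirmat, seq_len(sum(ok)),
                         pmin(dt_ms[ok], n * jump_interval), choice[ok],
                         config = task_config(n_tokens = n,
                                              jump_interval = jump_interval))
  out
}

study_contrasts <- function(summ, type_a, type_b, scale_dt, scale_sp) {
  do.call(rbind, lapply(unique(summ$condition), function(cond) {
    a <- summ[summ$condition == cond & summ$trial_type == type_a, ]
    b <- summ[summ$condition == cond & summ$trial_type == type_b, ]
    subj <- intersect(a$subject_id, b$subject_id)
    a <- a[match(subj, a$subject_id), ]
    b <- b[match(subj, b$subject_id), ]
    do.call(rbind, lapply(c("dt", "sp"), function(measure) {
      va <- a[[paste0("mean_", measure)]]
      vb <- b[[paste0("mean_", measure)]]
      pc <- if (length(subj) >= 2) paired_comparison(va, vb)
            else list(t = NA_real_, p = NA_real_)
      bf <- tryCatch(
        bayes_factor_paired(va - vb,
                            scale = if (measure == "dt") scale_dt
                                    else scale_sp),
        error = function(e) NA_real_)
      data.frame(condition = cond, measure = measure,
                 contrast = paste(type_a, "vs", type_b),
                 mean_a = mean(va), mean_b = mean(vb),
                 t = pc$t, p = pc$p, bf10 = bf,
                 n_subjects = length(subj), stringsAsFactors = FALSE)
    }))
  }))
}
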
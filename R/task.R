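#' Task configuration for the tokens task
#'
#' Bundles the design constants of the tokens task: 15 tokens jumping every
#' 200 ms, the post-decision fast-forward interval, how long a jumped token
#' stays visible in the all-away condition, the inter-trial interval, and the
#' block structure (a block ends when 70 correct answers have been achieved;
#' 12 blocks, half per visibility condition).
#'
#' @param n_tokens Number of tokens per trial. Must be odd so a strict
#'   majority always exists.
#' @param jump_interval Interval between token jumps, ms.
#' @param post_decision_interval Interval between the remaining jumps after a
#'   choice has been made, ms.
#' @param visibility_after_jump How long a token remains visible after its
#'   jump in the all-away condition, ms.
#' @param inter_trial_interval Pause between trials, ms.
#' @param correct_per_block Number of correct answers that completes a block.
#' @param n_blocks Total number of blocks (half all-stay, half all-away).
#' @return A list of class `task_config`.
#' @export
task_config <- function(n_tokens = 15L, jump_interval = 200,
                        post_decision_interval = 20,
                        visibility_after_jump = 200,
                        inter_trial_interval = 500,
                        correct_per_block = 70L, n_blocks = 12L) {
  n_tokens <- as.integer(n_tokens)
  if (n_tokens < 1L || n_tokens %% 2L == 0L)
    stop("`n_tokens` must be a positive odd integer")
  durs <- c(jump_interval, post_decision_interval, visibility_after_jump,
            inter_trial_interval)
  if (any(durs <= 0)) stop("all durations must be > 0")
  if (correct_per_block < 1L || n_blocks < 1L)
    stop("block counts must be positive")
  structure(list(n_tokens = n_tokens, jump_interval = jump_interval,
                 post_decision_interval = post_decision_interval,
                 visibility_after_jump = visibility_after_jump,
                 inter_trial_interval = inter_trial_interval,
                 correct_per_block = as.integer(correct_per_block),
                 n_blocks = as.integer(n_blocks)),
            class = "task_config")
}

#' Analytic success probability of a token split
#'
#' Probability that target one ends the trial with the token majority, given
#' `n1` tokens already in target one, `n2` in target two and `nr` still in
#' the central circle, each remaining token jumping to either side with
#' probability 1/2:
#' \deqn{P(C \mid N_1, N_2, N_r) = \frac{N_r!}{2^{N_r}}
#'   \sum_{k=0}^{\min(N_r,\, \lfloor n/2 \rfloor - N_2)} \frac{1}{k!\,(N_r-k)!}}
#' where the index `k` runs over the completions in which target two receives
#' few enough of the remaining tokens for target one to reach the strict
#' majority. With the standard 15 tokens the upper limit is
#' \eqn{\min(N_r, 7 - N_2)}.
#'
#' @param n1,n2,nr Token counts in target one, target two and the center.
#'   Vectors are recycled to a common length.
#' @param n_tokens Total token count; defaults to 15.
#' @return Success probabilities in `[0, 1]`.
#' @examples
#' success_probability(0, 0, 15)   # 0.5 at trial start
#' success_probability(8, 4, 3)    # 1: majority already secured
#' @export
success_probability <- function(n1, n2, nr, n_tokens = 15L) {
  k <- max(length(n1), length(n2), length(nr))
  n1 <- rep_len(as.integer(n1), k)
  n2 <- rep_len(as.integer(n2), k)
  nr <- rep_len(as.integer(nr), k)
  if (any(n1 < 0 | n2 < 0 | nr < 0))
    stop("invalid token state: negative counts")
  if (any(n1 + n2 + nr != n_tokens))
    stop("invalid token state: counts must sum to `n_tokens`")
  half <- n_tokens %/% 2L
  m <- pmin(nr, half - n2)
  vapply(seq_len(k), function(i) {
    if (m[i] < 0L) return(0)
    ks <- 0:m[i]
    sum(choose(nr[i], ks)) / 2^nr[i]
  }, numeric(1))
}

# Sign of the winning direction in the trial's stored frame (+1 if the
# reference target ends with the majority, -1 otherwise). Never 0: odd count.
winner_sign <- function(trial) {
  s <- sum(trial$directions)
  if (s > 0) 1L else -1L
}

#' Success-probability profile of a trial
#'
#' Success probability of the trial's correct (final-majority) target after
#' each token jump. The profile has one element per token; the last element
#' is always 1 because no tokens remain and the correct target, by
#' definition, holds the majority.
#'
#' @param trial A `token_trial`, from [generate_trial()].
#' @return Numeric vector of length `n_tokens`.
#' @export
sp_profile <- function(trial) {
  stopifnot(inherits(trial, "token_trial"))
  n <- trial$n_tokens
  dw <- trial$directions * winner_sign(trial)
  n1 <- cumsum(dw == 1L)
  j <- seq_len(n)
  success_probability(n1, j - n1, n - j, n_tokens = n)
}

# Rejection-sampling acceptance envelopes (see the methods vignette):
# easy trials must keep the correct target's SP at or above 0.60 from the
# third jump onward; ambiguous trials must stay inside [0.34, 0.66] through
# jump 10 (the exact band attainable under strict alternation).
.easy_sp_floor <- 0.60
.ambiguous_band <- c(0.34, 0.66)

#' Generate a single tokens-task trial
#'
#' Directions are stored relative to a uniformly drawn reference target
#' (`+1` = toward it). For the four structured types the reference target is
#' the correct (final-majority) target by construction; for `random` trials
#' every jump is an independent fair coin, so the reference target loses in
#' about half of them and `correct_target` records the actual winner.
#'
#' Easy and ambiguous trials are produced by rejection sampling. Easy: each
#' jump favors the correct target with probability 0.85 and the sequence is
#' accepted when the success probability stays at or above 0.60 from jump 3
#' on. Ambiguous: jumps 1-10 strictly alternate (random starting side), jumps
#' 11-15 favor the correct target with probability 0.85, and the sequence is
#' accepted when it ends with the correct target winning; alternation keeps
#' the success probability inside [0.34, 0.66] through jump 10. Bias trials
#' fix the first six jumps (`+1,+1,+1,-1,-1,-1` for bias-for, mirrored for
#' bias-against) and assign exactly 7 of the 9 tail jumps to the correct
#' target in random order, guaranteeing a 10-5 win.
#'
#' @param trial_type One of `"random"`, `"easy"`, `"ambiguous"`,
#'   `"bias_for"`, `"bias_against"`.
#' @param condition `"all_stay"` or `"all_away"`.
#' @param config A [task_config()].
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @return A list of class `token_trial` with fields `directions` (integer
#'   `+1`/`-1`), `trial_type`, `condition`, `reference_target`,
#'   `correct_target` and `n_tokens`.
#' @export
generate_trial <- function(trial_type = c("random", "easy", "ambiguous",
                                          "bias_for", "bias_against"),
                           condition = c("all_stay", "all_away"),
                           config = task_config(), seed = NULL) {
  trial_type <- match.arg(trial_type)
  condition <- match.arg(condition)
  with_seed(seed, function() {
    n <- config$n_tokens
    d <- switch(trial_type,
      random = sample(c(1L, -1L), n, replace = TRUE),
      easy = {
        repeat {
          cand <- sample(c(1L, -1L), n, replace = TRUE, prob = c(0.85, 0.15))
          if (sum(cand) <= 0L) next
          prof <- sp_profile_raw(cand, n)
          if (all(prof[3:n] >= .easy_sp_floor)) break
        }
        cand
      },
      ambiguous = {
        start <- sample(c(1L, -1L), 1L)
        repeat {
          head10 <- rep_len(c(start, -start), min(10L, n - 5L))
          tail5 <- sample(c(1L, -1L), n - length(head10), replace = TRUE,
                          prob = c(0.85, 0.15))
          cand <- c(head10, tail5)
          if (sum(cand) <= 0L) next
          prof <- sp_profile_raw(cand, n)
          h <- seq_along(head10)
          if (all(prof[h] >= .ambiguous_band[1] &
                  prof[h] <= .ambiguous_band[2])) break
        }
        cand
      },
      bias_for = c(1L, 1L, 1L, -1L, -1L, -1L, bias_tail(n - 6L)),
      bias_against = c(-1L, -1L, -1L, 1L, 1L, 1L, bias_tail(n - 6L))
    )
    ref <- sample(c("left", "right"), 1L)
    winner <- if (sum(d) > 0L) ref else setdiff(c("left", "right"), ref)
    structure(list(directions = d, trial_type = trial_type,
                   condition = condition, reference_target = ref,
                   correct_target = winner, n_tokens = n),
              class = "token_trial")
  })
}

# SP profile of a raw direction vector known to have a positive sum.
sp_profile_raw <- function(d, n) {
  n1 <- cumsum(d == 1L)
  j <- seq_len(n)
  success_probability(n1, j - n1, n - j, n_tokens = n)
}

# Tail of a bias trial: exactly ceil(3/4 * len) jumps toward the correct
# target in random order; with the standard 9-jump tail this is 7 vs 2,
# so the final count is 10-5 for the correct target.
bias_tail <- function(len) {
  n_pos <- ceiling(0.75 * len + 0.25)  # 7 when len = 9
  sample(c(rep(1L, n_pos), rep(-1L, len - n_pos)))
}

#' Default trial-type mix
#'
#' Half the trials in a block have random directions; the rest are split
#' among the four structured types: 15% easy, 15% ambiguous, 10% bias-for
#' and 10% bias-against.
#' @return Named numeric vector of proportions summing to 1.
#' @export
default_mix <- function() {
  c(random = 0.50, easy = 0.15, ambiguous = 0.15,
    bias_for = 0.10, bias_against = 0.10)
}

#' Generate a block of trials
#'
#' Trial-type counts follow `proportions` via the largest-remainder rounding
#' rule and the trial order is shuffled.
#'
#' @param n_trials Number of trials in the block.
#' @param proportions Named proportions over the five trial types; must sum
#'   to 1.
#' @param condition `"all_stay"` or `"all_away"`.
#' @param config A [task_config()].
#' @param seed Optional integer seed.
#' @return A data frame of class `token_trials` with one row per trial:
#'   `trial_index`, `trial_type`, `condition`, `directions` (a string of
#'   `+`/`-`), `reference_target`, `correct_target`.
#' @export
generate_block <- function(n_trials, proportions = default_mix(),
                           condition = c("all_stay", "all_away"),
                           config = task_config(), seed = NULL) {
  condition <- match.arg(condition)
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("`proportions` must sum to 1")
  if (is.null(names(proportions)) || any(!nzchar(names(proportions))))
    stop("`proportions` must be named by trial type")
  counts <- largest_remainder(proportions, n_trials)
  with_seed(seed, function() {
    types <- sample(rep(names(counts), counts))
    trials <- lapply(types, function(ty)
      generate_trial(ty, condition, config = config))
    df <- trials_to_df(trials)
    df$trial_index <- seq_len(nrow(df))
    class(df) <- c("token_trials", "data.frame")
    df
  })
}

# Largest-remainder apportionment of n among named proportions; ties broken
# by larger proportion, then by position, so the result is deterministic.
largest_remainder <- function(p, n) {
  raw <- p * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, p, -seq_along(p), decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(counts), names(p))
}

#' Convert trials between list and data-frame form
#'
#' `trials_to_df()` flattens a list of `token_trial` objects into the trial
#' log layout (directions as a `+`/`-` string); `df_to_trials()` rebuilds
#' the list, and `directions_matrix()` extracts the signed jump directions
#' as an integer matrix (one row per trial) for batch simulation.
#'
#' @param trials A list of `token_trial` objects or a `token_trials` data
#'   frame.
#' @return See each function's description.
#' @export
trials_to_df <- function(trials) {
  if (inherits(trials, "token_trial")) trials <- list(trials)
  data.frame(
    trial_index = seq_along(trials),
    trial_type = vapply(trials, `[[`, character(1), "trial_type"),
    condition = vapply(trials, `[[`, character(1), "condition"),
    directions = vapply(trials, function(tr)
      paste(ifelse(tr$directions == 1L, "+", "-"), collapse = ""),
      character(1)),
    reference_target = vapply(trials, `[[`, character(1), "reference_target"),
    correct_target = vapply(trials, `[[`, character(1), "correct_target"),
    stringsAsFactors = FALSE)
}

#' @rdname trials_to_df
#' @export
df_to_trials <- function(trials) {
  lapply(seq_len(nrow(trials)), function(i) {
    d <- directions_from_string(trials$directions[i])
    structure(list(directions = d,
                   trial_type = trials$trial_type[i],
                   condition = trials$condition[i],
                   reference_target = trials$reference_target[i],
                   correct_target = trials$correct_target[i],
                   n_tokens = length(d)),
              class = "token_trial")
  })
}

#' @rdname trials_to_df
#' @export
directions_matrix <- function(trials) {
  if (is.data.frame(trials)) {
    t(vapply(trials$directions, directions_from_string,
             integer(nchar(trials$directions[1])), USE.NAMES = FALSE))
  } else {
    if (inherits(trials, "token_trial")) trials <- list(trials)
    t(vapply(trials, `[[`, integer(trials[[1]]$n_tokens), "directions"))
  }
}

directions_from_string <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ifelse(ch == "+", 1L, -1L)
}

#' Read and write trial-log CSV files
#'
#' One row per trial with the columns produced by [trials_to_df()] plus any
#' identifiers (`subject_id`, `block`, ...) present in the data frame.
#'
#' @param trials A trials data frame.
#' @param path File path.
#' @return `read_trials_csv()` returns the trials data frame.
#' @export
write_trials_csv <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(directions = "character"))
  class(df) <- c("token_trials", "data.frame")
  df
}
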
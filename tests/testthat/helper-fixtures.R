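# Shared fixtures and independent oracles used across the test files.

# Exhaustive-enumeration oracle for the success probability: walk all 2^nr
# equiprobable completions and count those in which target one reaches the
# strict majority. Deliberately brute force and independent of the
# closed-form implementation.
sp_enum <- function(n1, n2, nr, n_tokens = 15, popcounts = NULL) {
  need <- n_tokens %/% 2 + 1 - n1  # remaining tokens target one still needs
  if (nr == 0) return(as.numeric(need <= 0))
  if (is.null(popcounts)) popcounts <- popcount_table(nr)
  mean(popcounts >= need)
}

# Number of set bits among the first `nr` bits of every integer in
# 0:(2^nr - 1): one row per completion, bit j = remaining token j goes to
# target one.
popcount_table <- function(nr) {
  ints <- 0:(2^nr - 1)
  vapply(ints, function(i) sum(as.integer(intToBits(i))[seq_len(nr)]),
         numeric(1))
}

# A homogeneous set of trials of one type as a trials data frame.
make_trial_set <- function(trial_type, n, condition = "all_stay",
                           seed = NULL) {
  tokensim:::with_seed(seed, function() {
    trs <- lapply(seq_len(n), function(i)
      generate_trial(trial_type, condition))
    df <- trials_to_df(trs)
    df$trial_index <- seq_len(n)
    df
  })
}

# Dense-grid quadrature oracle for the JZS paired Bayes factor, integrating
# the Cauchy prior over effect size through the substitution
# delta = scale * tan(phi) with a trapezoid rule.
bf_grid_oracle <- function(differences, scale, k = 200001L) {
  n <- length(differences)
  tstat <- mean(differences) / (sd(differences) / sqrt(n))
  df <- n - 1
  phi <- seq(-pi / 2 + 1e-8, pi / 2 - 1e-8, length.out = k)
  f <- suppressWarnings(
    stats::dt(tstat, df, ncp = scale * tan(phi) * sqrt(n)) / pi)
  m1 <- sum((f[-1] + f[-k]) / 2) * diff(phi[1:2])
  m1 / stats::dt(tstat, df)
}

# Brute-force ECDF sweep for the two-sample KS statistic.
ks_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# First-crossing step of the noise-free EAM under constant evidence, from
# the arithmetic of the update rule (not the simulation loop):
# x_n = theta/2 + n * nu * e * 0.01 crosses theta strictly.
eam_crossing_step <- function(nu, e, theta) {
  floor((theta / 2) / (nu * e * 0.01)) + 1
}

# First-crossing step of the noise-free UGM under constant evidence, using
# the geometric-series closed form of the low-pass filter:
# x_n = nu * e * (1 - a^n), decision when x_n * (n * dt) > theta.
ugm_crossing_step <- function(nu, e, theta, dt = 10, tau = 100,
                              n_max = 299) {
  a <- tau / (tau + dt)
  n <- seq_len(n_max)
  xu <- nu * e * (1 - a^n) * (n * dt)
  which(xu > theta)[1]
}
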
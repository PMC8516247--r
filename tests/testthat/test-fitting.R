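test_that("the log-product statistic matches direct arithmetic", {
  expect_equal(qmpe_from_counts(c(3, 1), c(0.75, 0.25)),
               3 * log(0.75) + log(0.25), tolerance = 1e-12)
  # floor rule keeps the statistic finite with unpredicted observed mass
  expect_equal(qmpe_from_counts(c(2, 1), c(1, 0)),
               log(1e-10), tolerance = 1e-12)
  set.seed(81)
  for (i in 1:10) {
    n <- rpois(4, 6) + 1
    p <- prop.table(runif(4))
    expect_equal(qmpe_from_counts(n, p), sum(n * log(p)), tolerance = 1e-10)
  }
})

test_that("the statistic is maximized at the observed proportions", {
  # grid-search oracle over the 3-bin probability simplex
  set.seed(82)
  grid <- expand.grid(p1 = seq(0.01, 0.98, by = 0.01),
                      p2 = seq(0.01, 0.98, by = 0.01))
  grid <- grid[grid$p1 + grid$p2 <= 0.99, ]
  grid$p3 <- 1 - grid$p1 - grid$p2
  for (i in 1:5) {
    n <- rpois(3, 8) + 1
    vals <- apply(grid, 1, function(p) qmpe_from_counts(n, p))
    expect_gte(qmpe_from_counts(n, n / sum(n)) + 1e-12, max(vals))
  }
})

test_that("quantile binning concentrates, floors and collapses as designed", {
  obs_one <- data.frame(dt_ms = rep(500, 8), correct = TRUE)
  expect_equal(qmpe_statistic(obs_one, obs_one), 0)  # n * log(1)

  obs <- data.frame(dt_ms = c(400, 500, 600, 800, 1200, 300),
                    correct = c(rep(TRUE, 5), FALSE))
  pred_correct_only <- data.frame(dt_ms = seq(100, 2000, by = 10),
                                  correct = TRUE)
  s <- qmpe_statistic(obs, pred_correct_only)
  expect_true(is.finite(s))  # the error bin hits the 1e-10 floor
  expect_lt(s, log(1e-10) + 1)

  # fewer than min_error_count errors -> a single error bin
  pred <- data.frame(dt_ms = rep(c(400, 350), c(95, 5)),
                     correct = rep(c(TRUE, FALSE), c(95, 5)))
  s2 <- qmpe_statistic(obs, pred, min_error_count = 5)
  expect_true(is.finite(s2))
  expect_error(qmpe_statistic(obs[0, ], pred), "empty")
  expect_error(qmpe_statistic(obs, pred[0, ]), "empty")
  expect_error(qmpe_statistic(obs, pred, probs = c(0.5, 0.1)), "increasing")
})

test_that("the QMPE objective is invariant to observed-data order", {
  set.seed(83)
  obs <- data.frame(dt_ms = sample(seq(200, 2800, by = 5), 60),
                    correct = runif(60) < 0.8)
  pred <- data.frame(dt_ms = sample(seq(200, 2800, by = 5), 500,
                                    replace = TRUE),
                     correct = runif(500) < 0.75)
  s1 <- qmpe_statistic(obs, pred)
  s2 <- qmpe_statistic(obs[sample.int(60), ], pred)
  expect_identical(s1, s2)
})

test_that("fitting is deterministic and order-invariant given the seed", {
  tri <- make_trial_set("easy", 30, seed = 84)
  truth <- preset_params("eam", "all_stay")
  obs <- simulate_dataset(tri, "eam", truth, n_reps = 2, seed = 85,
                          compute_sp = FALSE)
  ctrl <- de_control(particles = 6, iterations = 3, restarts = 2,
                     n_sim = 150)
  f1 <- fit_model(tri, obs, "eam", control = ctrl, seed = 86)
  f2 <- fit_model(tri, obs, "eam", control = ctrl, seed = 86)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$per_restart_objectives, f2$per_restart_objectives)
  f3 <- fit_model(tri, obs[sample.int(nrow(obs)), ], "eam", control = ctrl,
                  seed = 86)
  expect_identical(f1$params, f3$params)
  expect_error(fit_model(tri, obs, "eam", control = ctrl,
                         bounds = list(lower = c(nu = 1, eta = 0,
                                                 theta = 2),
                                       upper = c(nu = 0.5, eta = 50,
                                                 theta = 5))),
               "inverted")
})

test_that("the objective prefers the generating parameters to an inflated boundary", {
  # local-optimality probe: theta * 1.5 should fit worse in >= 80% of
  # synthetic datasets
  truth <- preset_params("eam", "all_stay")
  wrong <- model_params("eam", nu = truth$nu, eta = truth$eta,
                        theta = truth$theta * 1.5)
  tri <- make_trial_set("easy", 50, seed = 87)
  wins <- 0L
  for (k in 1:20) {
    obs <- simulate_dataset(tri, "eam", truth, n_reps = 2, seed = 1000 + k,
                            compute_sp = FALSE)
    pred_true <- simulate_dataset(tri, "eam", truth, n_reps = 40,
                                  seed = 5000 + k, compute_sp = FALSE)
    pred_wrong <- simulate_dataset(tri, "eam", wrong, n_reps = 40,
                                   seed = 5000 + k, compute_sp = FALSE)
    s_true <- qmpe_statistic(obs, pred_true)
    s_wrong <- qmpe_statistic(obs, pred_wrong)
    wins <- wins + (s_true >= s_wrong)
  }
  expect_gte(wins, 16L)
})

test_that("model predictions report per-outcome mean-DT discrepancies", {
  tri <- make_trial_set("ambiguous", 40, seed = 88)
  truth <- preset_params("ugm", "all_stay")
  obs <- simulate_dataset(tri, "ugm", truth, n_reps = 2, seed = 89,
                          compute_sp = FALSE)
  fit <- structure(list(params = truth), class = "fit_result")
  mp <- model_predictions(fit, tri, observed = obs, n_total = 4000,
                          seed = 90)
  expect_named(mp$discrepancy, c("correct", "error"))
  expect_identical(nrow(mp$matched), nrow(obs))
  # a perfect generative match keeps the discrepancy small (ms scale)
  expect_lt(mp$discrepancy[["correct"]], 150)
})

test_that("fitted-type subsetting drops random trials and reindexes", {
  tri <- generate_block(40, condition = "all_stay", seed = 91)
  dec <- simulate_dataset(tri, "eam", preset_params("eam", "all_stay"),
                          seed = 92, compute_sp = FALSE)
  sub <- fitted_type_subset(tri, dec)
  expect_false(any(sub$trials$trial_type == "random"))
  expect_identical(nrow(sub$decisions), nrow(sub$trials))
  expect_identical(sub$trials$directions[sub$decisions$trial],
                   sub$trials$directions)
})
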
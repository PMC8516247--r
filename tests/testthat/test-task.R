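test_that("success probability matches the printed-formula anchor cases", {
  expect_equal(success_probability(0, 0, 15), 0.5)
  expect_equal(success_probability(8, 4, 3), 1.0)
  # 4 equiprobable completions, exactly one of which rescues target one
  expect_equal(success_probability(6, 7, 2), 0.25)
  # exhaustive enumeration over all 2^7 completions
  expect_equal(success_probability(5, 3, 7), sp_enum(5, 3, 7),
               tolerance = 1e-12)
})

test_that("success probability validates token states", {
  expect_error(success_probability(-1, 2, 14), "negative")
  expect_error(success_probability(1, 2, 3), "sum")
})

test_that("success probability generalizes to other odd token counts", {
  for (st in list(c(2, 1, 2), c(0, 3, 2), c(4, 0, 1))) {
    expect_equal(success_probability(st[1], st[2], st[3], n_tokens = 5),
                 sp_enum(st[1], st[2], st[3], n_tokens = 5),
                 tolerance = 1e-12)
  }
})

test_that("sp profiles behave as the trial geometry dictates", {
  # monotone dominance: every jump toward the correct target
  tr <- structure(list(directions = rep(1L, 15), trial_type = "easy",
                       condition = "all_stay", reference_target = "left",
                       correct_target = "left", n_tokens = 15L),
                  class = "token_trial")
  prof <- sp_profile(tr)
  expect_true(all(diff(prof) >= 0))
  expect_equal(prof[15], 1)

  # the first six jumps of bias trials are exact mirrors around 0.5
  bf <- generate_trial("bias_for", seed = 21)
  ba <- generate_trial("bias_against", seed = 22)
  expect_equal(sp_profile(bf)[1:6], 1 - sp_profile(ba)[1:6],
               tolerance = 1e-12)
  expect_equal(sp_profile(bf)[6], 0.5)

  # the last profile element is degenerate for any trial
  rnd <- generate_trial("random", seed = 23)
  expect_true(sp_profile(rnd)[15] %in% c(0, 1))
})

test_that("structured trial types satisfy their construction constraints", {
  for (s in 1:25) {
    bf <- generate_trial("bias_for", seed = s)
    expect_identical(bf$directions[1:6], c(1L, 1L, 1L, -1L, -1L, -1L))
    expect_identical(sum(bf$directions[7:15] == 1L), 7L)
    ba <- generate_trial("bias_against", seed = s + 100)
    expect_identical(ba$directions[1:6], c(-1L, -1L, -1L, 1L, 1L, 1L))
    expect_gt(sum(ba$directions), 0)

    ez <- generate_trial("easy", seed = s + 200)
    expect_true(all(sp_profile(ez)[3:15] >= 0.60))

    am <- generate_trial("ambiguous", seed = s + 300)
    expect_identical(abs(diff(am$directions[1:10])), rep(2L, 9))
    pa <- sp_profile(am)[1:10]
    expect_true(all(pa >= 0.34 & pa <= 0.66))
    expect_gt(sum(am$directions), 0)
  }
})

test_that("random trials are unbiased coins and reproducible", {
  expect_identical(generate_trial("random", seed = 7)$directions,
                   generate_trial("random", seed = 7)$directions)
  sums <- vapply(1:4000, function(i) {
    sum(generate_trial("random", seed = i)$directions)
  }, numeric(1))
  # mean of direction sums ~ N(0, sqrt(15/4000))
  expect_lt(abs(mean(sums)), 3 * sqrt(15 / 4000))
})

test_that("block generation apportions the mix by largest remainder", {
  blk <- generate_block(100, condition = "all_stay", seed = 1)
  counts <- table(blk$trial_type)
  expect_identical(as.integer(counts[c("random", "easy", "ambiguous",
                                       "bias_for", "bias_against")]),
                   c(50L, 15L, 15L, 10L, 10L))

  one <- generate_block(1, condition = "all_stay", seed = 2)
  expect_identical(one$trial_type, "random")

  expect_identical(generate_block(40, condition = "all_away", seed = 3),
                   generate_block(40, condition = "all_away", seed = 3))
  expect_error(generate_block(10, c(random = 0.6, easy = 0.6)), "sum to 1")
})

test_that("trial logs round-trip through data frames and CSV", {
  blk <- generate_block(20, condition = "all_away", seed = 4)
  trs <- df_to_trials(blk)
  expect_identical(trials_to_df(trs)$directions, blk$directions)
  expect_identical(directions_matrix(blk), directions_matrix(trs))
  expect_true(all(rowSums(directions_matrix(blk)) %% 2 != 0))

  path <- tempfile(fileext = ".csv")
  write_trials_csv(blk, path)
  back <- read_trials_csv(path)
  expect_identical(back$directions, blk$directions)
  expect_identical(back$correct_target, blk$correct_target)
  unlink(path)
})

test_that("task config validates its invariants", {
  expect_error(task_config(n_tokens = 14), "odd")
  expect_error(task_config(jump_interval = 0), "> 0")
  expect_identical(task_config()$n_tokens, 15L)
})
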
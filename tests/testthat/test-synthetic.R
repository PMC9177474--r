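test_that("generator is reproducible and balanced", {
  d <- experiment_design(n_participants = 6)
  p <- generative_params(seed = 99, participant_sd = 3)
  t1 <- generate_choices(d, p)
  t2 <- generate_choices(d, p)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 6 * n_trials(d))
  # every participant contributes the same count to every cell
  counts <- table(t1$participant_id,
                  interaction(t1$bucket_weight_kg, t1$difficulty,
                              t1$duration_s, t1$bucket_side))
  expect_true(all(counts == d$trials_per_combination))
  # different seed, different draws
  t3 <- generate_choices(d, generative_params(seed = 100, participant_sd = 3))
  expect_false(identical(t1$choice, t3$choice))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(7)
  before <- .Random.seed
  invisible(generate_choices(experiment_design(n_participants = 2),
                             generative_params(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("flat curve yields Bernoulli(0.5) choices; degenerate bound yields all-bucket", {
  d <- experiment_design(n_participants = 420)  # 10,080 trials
  flat <- generative_params(true_k = 5, true_h = 3,
                            logistic = logistic_params(0.5, 0.5, 20, 1),
                            seed = 31)
  tr <- generate_choices(d, flat)
  phat <- mean(tr$choice == "bucket")
  se <- sqrt(0.25 / nrow(tr))
  expect_lt(abs(phat - 0.5), 3 * se)
  one <- generative_params(logistic = logistic_params(1, 1, 20, 1), seed = 5)
  tr1 <- generate_choices(experiment_design(n_participants = 5), one)
  expect_true(all(tr1$choice == "bucket"))
})

test_that("empirical cell probabilities follow the enumerated Phi ordering", {
  d <- experiment_design(n_participants = 48)
  tr <- generate_choices(d, recovery_params(seed = 77))
  ct <- aggregate_choices(tr)
  cells <- merge(ct$group, enumerate_cell_phis(24, 8))
  cells <- cells[order(cells$phi), ]
  # brute-force enumeration fixes the ordering; demand agreement for every
  # pair of cells whose expected probabilities are separated by more than
  # the binomial noise at 96 trials/cell (saturated tail cells differ by
  # less than that)
  expected <- logistic_value(cells$phi, logistic_params(0.05, 0.95, 30, 0.3))
  for (i in seq_len(nrow(cells) - 1)) for (j in seq(i + 1, nrow(cells))) {
    if (expected[j] - expected[i] >= 0.15)
      expect_lte(cells$p_bucket[i], cells$p_bucket[j])
  }
})

test_that("noiseless cell means equal the logistic of the enumerated Phi", {
  d <- experiment_design()
  cm <- generate_noiseless_cell_means(d, recovery_params(seed = 1))
  ref <- enumerate_cell_phis(24, 8)
  m <- merge(cm, ref)
  expect_equal(m$p_bucket,
               logistic_value(m$phi, logistic_params(0.05, 0.95, 30, 0.3)))
  expect_equal(length(unique(cm$p_bucket)), 12)
  top <- cm[which.max(cm$p_bucket), ]
  expect_equal(top$duration_s, 27)
  expect_equal(top$bucket_weight_kg, 0)   # empty bucket
  expect_equal(top$difficulty, "hard")
  expect_true(all(cm$p_bucket >= 0.05 & cm$p_bucket <= 0.95))
})

test_that("zero shifts make cells sharing a duration identical", {
  cm <- generate_noiseless_cell_means(experiment_design(),
                                      recovery_params(seed = 1, true_k = 0,
                                                      true_h = 0))
  sp <- split(cm$p_bucket, cm$duration_s)
  for (g in sp) expect_equal(length(unique(g)), 1L)
})

test_that("generator rejects invalid parameters by field name", {
  expect_error(generative_params(true_k = Inf), "'true_k'")
  expect_error(generative_params(true_h = NA), "'true_h'")
  expect_error(generative_params(participant_sd = -1), "participant_sd")
  d <- experiment_design()
  expect_error(generate_noiseless_cell_means(d,
                 generative_params(participant_sd = 2)), "participant_sd")
})

test_that("exposure-performance generator matches its specification", {
  fx <- list(easy = c(error_rate = 0, mean_rt = 1800, rt_sd = 500),
             hard = c(error_rate = 0.3, mean_rt = 5700, rt_sd = 1500))
  perf <- generate_exposure_performance(10, fx, trials_per_level = 40, seed = 3)
  expect_equal(nrow(perf), 10 * 2 * 40)
  expect_true(all(perf$correct[perf$difficulty == "easy"] == 1))
  expect_true(all(perf$rt > 0))
  # identical parameters: paired t on per-participant means is null
  fx0 <- list(a = c(error_rate = 0.1, mean_rt = 2000, rt_sd = 600),
              b = c(error_rate = 0.1, mean_rt = 2000, rt_sd = 600))
  p0 <- generate_exposure_performance(40, fx0, 40, seed = 8)
  m <- aggregate(rt ~ participant_id + difficulty, p0, mean)
  tt <- paired_t(m$rt[m$difficulty == "a"], m$rt[m$difficulty == "b"])
  expect_gt(tt$p, 0.01)
  expect_error(generate_exposure_performance(5, fx, trials_per_level = 0),
               "trials_per_level")
  expect_error(generate_exposure_performance(5,
                 list(a = c(error_rate = 2, mean_rt = 1, rt_sd = 1))),
               "error_rate")
})

test_that("exposure generator reproduces the difficulty contrast it encodes", {
  fx <- list(`2digit` = c(error_rate = 0.0568, mean_rt = 1851, rt_sd = 600),
             `4digit` = c(error_rate = 0.1161, mean_rt = 5774, rt_sd = 2000))
  perf <- generate_exposure_performance(48, fx, trials_per_level = 40, seed = 21)
  agg <- aggregate(cbind(err = 1 - correct, rt) ~ participant_id + difficulty,
                   perf, mean)
  e2 <- agg[agg$difficulty == "2digit", ]
  e4 <- agg[agg$difficulty == "4digit", ]
  tt <- paired_t(e4$err, e2$err)
  expect_gt(tt$mean_diff, 0)     # harder level makes more errors
  expect_lt(tt$p, 0.05)
  rt <- paired_t(e4$rt, e2$rt)
  expect_gt(rt$mean_diff, 0)
  expect_lt(rt$p, 1e-6)
})

test_that("empirical cell means converge to the generative logistic", {
  # 10,000 trials in one cell via many participants, sd = 0
  d <- experiment_design(weights = c(0, 3.2), durations = c(9, 18, 27),
                         n_participants = 420)
  p <- recovery_params(seed = 55)
  tr <- generate_choices(d, p)
  ct <- aggregate_choices(tr)
  expected <- generate_noiseless_cell_means(d, p)
  m <- merge(ct$group, expected, by = c("bucket_weight_kg", "difficulty",
                                        "duration_s"))
  ntr <- 420 * 2  # trials per collapsed cell
  se <- sqrt(pmax(m$p_bucket.y * (1 - m$p_bucket.y), 1e-4) / ntr)
  expect_true(all(abs(m$p_bucket.x - m$p_bucket.y) < 4 * se))
})
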
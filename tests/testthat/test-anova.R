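test_that("2x2 within fixture matches hand-worked sums of squares", {
  df <- anova_fixture_2x2()
  res <- rm_anova(df, dv = "y", id = "participant_id", within = c("A", "B"))
  # frozen values from explicit marginal-means arithmetic:
  # SS_A = 14.0833..., SS_AxP = 0.1666... -> F_A = 169
  # SS_B = 10.0833..., SS_BxP = 2.1666... -> F_B = 121/13
  # SS_AB = 0.75, SS_ABxP = 0.5 -> F_AB = 3
  expect_equal(res$F[res$effect == "A"], 169, tolerance = 1e-9)
  expect_equal(res$F[res$effect == "B"], 121 / 13, tolerance = 1e-9)
  expect_equal(res$F[res$effect == "A:B"], 3, tolerance = 1e-9)
  expect_equal(res$df_effect, c(1L, 1L, 1L))
  expect_equal(res$df_error, c(2L, 2L, 2L))
  expect_equal(res$partial_eta_sq[res$effect == "A"], 169 / 171,
               tolerance = 1e-9)
  expect_equal(res$partial_eta_sq[res$effect == "A:B"], 0.6, tolerance = 1e-9)
  expect_equal(res$p[res$effect == "A"], pf(169, 1, 2, lower.tail = FALSE),
               tolerance = 1e-9)
  # agreement with the independent Moebius-decomposition oracle
  orc <- oracle_rm_anova(df, "y", "participant_id", c("A", "B"))
  for (e in res$effect)
    expect_equal(res$F[res$effect == e], orc[[e]]$F, tolerance = 1e-9)
})

test_that("three-way ANOVA agrees with the independent oracle on random data", {
  set.seed(11)
  for (rep in 1:3) {
    g <- expand.grid(participant_id = paste0("P", 1:7),
                     dur = c("9", "18", "27"), dif = c("lo", "hi"),
                     wt = c("w0", "w1"), stringsAsFactors = FALSE)
    g$y <- rnorm(nrow(g))
    res <- rm_anova(g, dv = "y", id = "participant_id",
                    within = c("dur", "dif", "wt"))
    orc <- oracle_rm_anova(g, "y", "participant_id", c("dur", "dif", "wt"))
    for (e in res$effect) {
      expect_equal(res$F[res$effect == e], orc[[e]]$F, tolerance = 1e-9)
      expect_equal(res$partial_eta_sq[res$effect == e], orc[[e]]$pes,
                   tolerance = 1e-9)
      expect_equal(res$df_error[res$effect == e], orc[[e]]$df_error)
    }
    # exact decomposition: total SS = participant + sum effect + sum error SS
    ss <- attr(res, "ss")
    expect_equal(attr(res, "ss_participant") + sum(ss),
                 attr(res, "ss_total"), tolerance = 1e-9)
  }
})

test_that("F is invariant under affine transformation of the data", {
  set.seed(23)
  g <- expand.grid(participant_id = paste0("P", 1:6),
                   a = c("a1", "a2"), b = c("b1", "b2", "b3"),
                   stringsAsFactors = FALSE)
  g$y <- rnorm(nrow(g))
  f0 <- rm_anova(g, "y", "participant_id", c("a", "b"))$F
  g$y2 <- 3.7 * g$y + 11
  f1 <- rm_anova(g, "y2", "participant_id", c("a", "b"))$F
  expect_equal(f0, f1, tolerance = 1e-9)
})

test_that("degrees of freedom follow the design arithmetic", {
  d <- experiment_design(n_participants = 30)
  tr <- generate_choices(d, generative_params(seed = 14, participant_sd = 4))
  res <- rm_anova(aggregate_choices(tr))
  expect_equal(res$df_effect[res$effect == "duration_s"], 2L)
  expect_equal(res$df_error[res$effect == "duration_s"], 58L)
  expect_equal(res$df_effect[res$effect == "difficulty"], 1L)
  expect_equal(res$df_error[res$effect == "difficulty"], 29L)
  expect_equal(res$df_error[res$effect == "duration_s:difficulty:bucket_weight_kg"],
               58L)
  # df_error = df_effect * (n - 1) throughout
  expect_equal(res$df_error, res$df_effect * 29L)
})

test_that("a factor with no within-participant effect gets F = 0, p = 1", {
  g <- expand.grid(participant_id = paste0("P", 1:5),
                   a = c("a1", "a2"), b = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  base <- rnorm(5); names(base) <- paste0("P", 1:5)
  g$y <- base[g$participant_id] + ifelse(g$b == "b2", 0.5, 0) +
    rnorm(nrow(g), 0, 0.1) * (g$b == "b2")
  g$y <- ave(g$y, g$participant_id, g$b)  # identical across levels of a
  res <- rm_anova(g, "y", "participant_id", c("a", "b"))
  expect_equal(res$F[res$effect == "a"], 0)
  expect_equal(res$p[res$effect == "a"], 1)
})

test_that("invalid designs are rejected", {
  g <- expand.grid(participant_id = "P1", a = c("a1", "a2"),
                   stringsAsFactors = FALSE)
  g$y <- 1:2
  expect_error(rm_anova(g, "y", "participant_id", "a"), "2 participants")
  g2 <- expand.grid(participant_id = paste0("P", 1:3),
                    a = c("a1", "a2"), stringsAsFactors = FALSE)
  g2$y <- rnorm(6)
  expect_error(rm_anova(g2[-1, ], "y", "participant_id", "a"), "balanced")
  expect_error(rm_anova(g2, "z", "participant_id", "a"), "lacks")
})

test_that("Greenhouse-Geisser epsilon is 1 for two-level factors and <= 1 otherwise", {
  set.seed(31)
  g <- expand.grid(participant_id = paste0("P", 1:8),
                   a = c("a1", "a2"), b = c("b1", "b2", "b3"),
                   stringsAsFactors = FALSE)
  g$y <- rnorm(nrow(g))
  res <- rm_anova(g, "y", "participant_id", c("a", "b"),
                  correction = "greenhouse-geisser")
  expect_equal(res$epsilon[res$effect == "a"], 1, tolerance = 1e-9)
  expect_lte(res$epsilon[res$effect == "b"], 1 + 1e-12)
  expect_gte(res$epsilon[res$effect == "b"], 0.5)  # lower bound 1/(L-1)
  # F unchanged; only p adjusted
  res0 <- rm_anova(g, "y", "participant_id", c("a", "b"))
  expect_equal(res$F, res0$F, tolerance = 1e-12)
  expect_gte(res$p_gg[res$effect == "b"], res$p[res$effect == "b"])
})

test_that("duration power shrinks when the generative effect is halved", {
  nsim <- 60
  rej <- c(full = 0, half = 0)
  for (s in seq_len(nsim)) {
    for (v in c("full", "half")) {
      steep <- if (v == "full") 0.3 else 0.075
      p <- generative_params(true_k = 24, true_h = 8,
                             logistic = logistic_params(0.35, 0.65, 30, steep),
                             seed = 5000 + s)
      tr <- generate_choices(experiment_design(n_participants = 10), p)
      res <- rm_anova(aggregate_choices(tr))
      if (res$p[res$effect == "duration_s"] < 0.05)
        rej[v] <- rej[v] + 1
    }
  }
  expect_gt(rej["full"], rej["half"])
})
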
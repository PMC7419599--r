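test_that("partial eta squared identity and edge cases", {
  expect_equal(round(partial_eta_squared(11.06, 1, 18), 3), 0.381)
  expect_equal(round(partial_eta_squared(31.343, 3, 48), 3), 0.662)
  expect_equal(partial_eta_squared(0, 3, 48), 0)
  expect_error(partial_eta_squared(-1, 1, 10), "f >= 0")
  # recomputing eta from a fitted table's own F/df reproduces the stored value
  d <- random_mixed_scores(n_per_group = 5, effect = 0.8, seed = 3)
  res <- mixed_rm_anova(d)
  expect_equal(res$eta_p2,
               partial_eta_squared(res$F, res$df1, res$df2), tolerance = 1e-12)
})

test_that("mixed ANOVA matches the aov() oracle on random small designs", {
  for (s in 1:50) {
    n <- 3 + s %% 4
    k <- 3 + s %% 2
    d <- random_mixed_scores(n_per_group = n, k = k, effect = (s %% 3) * 0.5,
                             seed = 200 + s)
    mine <- mixed_rm_anova(d, gg = "never")
    fit <- summary(aov(value ~ group * condition + Error(participant / condition),
                       data = d))
    between <- fit[["Error: participant"]][[1]]
    within <- fit[["Error: participant:condition"]][[1]]
    expect_equal(mine$F[mine$effect == "group"], between["group", "F value"],
                 tolerance = 1e-10, label = sprintf("group F case %d", s))
    expect_equal(mine$F[mine$effect == "condition"],
                 within["condition", "F value"], tolerance = 1e-10,
                 label = sprintf("condition F case %d", s))
    expect_equal(mine$F[mine$effect == "condition:group"],
                 within["group:condition", "F value"], tolerance = 1e-10,
                 label = sprintf("interaction F case %d", s))
    expect_equal(mine$p[mine$effect == "condition"],
                 within["condition", "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("ANOVA input validation: flat data, missing cells, tiny groups", {
  d <- random_mixed_scores(seed = 1)
  d$value <- 1
  expect_error(mixed_rm_anova(d), "zero variance")
  d2 <- random_mixed_scores(seed = 2)
  expect_error(mixed_rm_anova(d2[-1, ]), "unbalanced")
  d3 <- random_mixed_scores(n_per_group = 2, seed = 3)
  d3 <- d3[d3$participant != "g1p1", ]
  expect_error(mixed_rm_anova(d3), "at least 2 participants")
  # all-identical-within-cells but varying between: F defined, runs
  d4 <- random_mixed_scores(seed = 4, sd_trial = 1e-6)
  expect_s3_class(mixed_rm_anova(d4), "tbl_df")
})

test_that("Greenhouse-Geisser epsilon: bounds, sphericity, eigen oracle", {
  # compound symmetry -> epsilon = 1
  S_cs <- matrix(0.3, 4, 4); diag(S_cs) <- 1
  expect_equal(gg_epsilon(cov_matrix = S_cs), 1)
  # rank-1 contrast covariance -> lower bound 1/(k-1)
  v <- c(3, 1, -1, -3)
  S_r1 <- tcrossprod(v) + diag(1e-10, 4)
  expect_equal(gg_epsilon(cov_matrix = S_r1), 1 / 3, tolerance = 1e-6)
  # random instances match the eigenvalue form of the same quantity
  for (s in 1:20) {
    withr::with_seed(300 + s, {
      A <- matrix(rnorm(40), 10, 4)
      S <- cov(A)
    })
    C <- postprime:::orthonormal_contrasts(4)
    lam <- eigen(C %*% S %*% t(C), symmetric = TRUE, only.values = TRUE)$values
    eps_eigen <- sum(lam)^2 / (3 * sum(lam^2))
    expect_equal(gg_epsilon(cov_matrix = S), min(1, max(1 / 3, eps_eigen)),
                 tolerance = 1e-12)
  }
})

test_that("GG correction shrinks dfs and inflates p when sphericity fails", {
  withr::with_seed(8, {
    d <- random_mixed_scores(n_per_group = 8, seed = 8)
    # induce strong non-sphericity: one condition much noisier
    d$value[d$condition == "c4"] <- d$value[d$condition == "c4"] +
      rnorm(sum(d$condition == "c4"), 0, 6)
  })
  raw <- mixed_rm_anova(d, gg = "never")
  cor <- mixed_rm_anova(d, gg = "always")
  wi <- cor$effect %in% c("condition", "condition:group")
  expect_true(all(cor$df1[wi] <= raw$df1[wi]))
  expect_true(all(cor$df2[wi] <= raw$df2[wi]))
  expect_true(all(cor$p[wi] >= raw$p[wi]))
  expect_true(all(cor$gg_epsilon[wi] >= 1 / 3 & cor$gg_epsilon[wi] <= 1))
})

test_that("family alpha rule and sequential Holm", {
  expect_equal(holm_family_alpha(5), 0.005)
  expect_equal(holm_family_alpha(2), 0.0125)
  expect_equal(holm_family_alpha(1), 0.025)
  expect_equal(holm_sequential(c(0.01, 0.04, 0.03)),
               p.adjust(c(0.01, 0.04, 0.03), method = "holm"))
})

test_that("post hocs require a significant omnibus and cap adjusted p at 1", {
  d <- aggregate_trials(random_mixed_scores(n_per_group = 6, effect = 2,
                                            sd_trial = 0.5, seed = 12))
  expect_error(posthoc_pairwise(d, omnibus_p = 0.2, alpha = 0.05), "refused")
  ph <- posthoc_pairwise(d, omnibus_p = 1e-5, alpha = 0.05, between = TRUE)
  expect_equal(sum(ph$scope == "within"), 2 * choose(4, 2))
  expect_equal(unique(ph$multiplier[ph$scope == "within"]), 6)
  expect_true(all(ph$p_adj <= 1))
  expect_true(all(ph$p_adj >= ph$p_raw - 1e-15))
  # identical samples -> adjusted p = 1
  d2 <- d
  d2$value <- ave(seq_len(nrow(d2)), d2$participant)  # constant per participant
  ph2 <- posthoc_pairwise(d2, omnibus_p = 1e-5, alpha = 0.05)
  expect_true(all(ph2$p_adj == 1))
})

test_that("trial aggregation averages to one score per participant x condition", {
  d <- random_mixed_scores(n_per_group = 3, trials = 3, seed = 15)
  agg <- aggregate_trials(d)
  expect_equal(nrow(agg), 3 * 2 * 4)
  one <- d[d$participant == "g1p1" & d$condition == "c1", "value"]
  expect_equal(agg$value[agg$participant == "g1p1" & agg$condition == "c1"],
               mean(one))
})

test_that("injected within-subject effects are detected with high power", {
  # 1 trial-level SD condition effect, 3 trials averaged, n = 10/group
  alpha <- holm_family_alpha(5)
  hits <- vapply(1:300, function(s) {
    d <- random_mixed_scores(n_per_group = 10, trials = 3, effect = 1,
                             sd_subj = 1, sd_trial = 1, seed = 5000 + s)
    res <- mixed_rm_anova(aggregate_trials(d))
    res$p[res$effect == "condition"] < alpha
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})
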
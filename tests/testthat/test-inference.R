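make_cohort_df <- function(cells) {
  # cells: data.frame age_group, condition, n, k (allocentric count)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    with(cells[i, ], data.frame(
      subject_id = paste0(age_group, condition, seq_len(n)),
      age_group = age_group, condition = condition,
      allocentric_majority = c(rep(1L, k), rep(0L, n - k)),
      stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

test_that("saturated logistic model reproduces observed cell proportions", {
  cells <- expand.grid(age_group = c("children", "young", "older"),
                       condition = c("landmark", "geometry"),
                       stringsAsFactors = FALSE)
  cells$n <- c(10, 12, 11, 9, 10, 13)
  cells$k <- c(3, 8, 4, 7, 10, 11)
  fit <- fit_strategy_glm(make_cohort_df(cells))
  for (i in seq_len(nrow(cells))) {
    row <- fit$cell_probabilities
    p <- row$p[row$age_group == cells$age_group[i] &
                 row$condition == cells$condition[i]]
    expect_equal(p, cells$k[i] / cells$n[i], tolerance = 1e-12)
  }
  # the GLM itself agrees where it converges
  pr <- predict(fit$model, cells, type = "response")
  expect_equal(unname(pr), cells$k / cells$n, tolerance = 1e-6)

  # separation: an all-allocentric cell still reports probability 1
  cells$k[1] <- cells$n[1]
  fit2 <- fit_strategy_glm(make_cohort_df(cells))
  row <- fit2$cell_probabilities
  expect_equal(row$p[row$age_group == "children" & row$condition == "landmark"], 1)

  expect_error(fit_strategy_glm(make_cohort_df(cells)[1:25, ]), "non-empty")
})

test_that("second differences match the hand-computed probability contrast", {
  # rounded cell probabilities 0.88 -> 0.99 (young) and 0.32 -> 0.82
  # (children) give (0.82 - 0.32) - (0.99 - 0.88) = 0.39
  cells <- expand.grid(age_group = c("children", "young", "older"),
                       condition = c("landmark", "geometry"),
                       stringsAsFactors = FALSE)
  cells$n <- 100L
  cells$k <- round(c(0.32, 0.88, 0.31, 0.82, 0.99, 0.82) * 100)
  fit <- fit_strategy_glm(make_cohort_df(cells))
  sd_cy <- second_difference(fit, c("children", "young"))
  expect_equal(sd_cy$delta, 0.39, tolerance = 1e-12)
  # delta-method SE equals the binomial form on the four cells
  se_hand <- sqrt(sum(c(0.32 * 0.68, 0.82 * 0.18, 0.88 * 0.12, 0.99 * 0.01) / 100))
  expect_equal(sd_cy$se, se_hand, tolerance = 1e-12)
  expect_lt(sd_cy$p_value, 0.001)

  # antisymmetry under swapping the pair
  sd_yc <- second_difference(fit, c("young", "children"))
  expect_equal(sd_yc$delta, -sd_cy$delta)

  # equal condition effects in both groups: delta = 0
  cells0 <- cells
  cells0$k <- round(c(0.3, 0.5, 0.4, 0.6, 0.8, 0.7) * 100)
  fit0 <- fit_strategy_glm(make_cohort_df(cells0))
  expect_equal(second_difference(fit0, c("children", "young"))$delta, 0,
               tolerance = 1e-12)

  # bootstrap SE agrees with the delta method within Monte-Carlo error
  set.seed(2)
  sd_b <- second_difference(fit, c("children", "young"),
                            se_method = "bootstrap", boot_reps = 4000)
  expect_equal(sd_b$se, se_hand, tolerance = 0.1)

  expect_error(second_difference(fit, c("children", "adults")), "unknown")
})

test_that("Fisher test matches full hypergeometric enumeration", {
  # enumeration oracle: P(X = x) over all tables with the observed margins
  fisher_oracle <- function(tab) {
    m <- rowSums(tab); k <- colSums(tab)
    xs <- max(0, k[1] - m[2]):min(m[1], k[1])
    probs <- vapply(xs, function(x) {
      choose(m[1], x) * choose(m[2], k[1] - x) / choose(sum(m), k[1])
    }, 0)
    p_obs <- probs[xs == tab[1, 1]]
    sum(probs[probs <= p_obs + 1e-12])
  }
  set.seed(4)
  for (rep in 1:40) {
    tab <- matrix(rpois(4, 4) + 1, 2)
    expect_equal(fisher_2x2(tab)$p_value, fisher_oracle(tab),
                 tolerance = 1e-9)
  }
  # diagonal table: p = 2 / choose(20, 10)
  diag_tab <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_2x2(diag_tab)$p_value, 2 / choose(20, 10),
               tolerance = 1e-12)
  # null table
  null_tab <- matrix(c(5, 5, 5, 5), 2)
  ft <- fisher_2x2(null_tab)
  expect_equal(ft$p_value, 1)
  expect_equal(ft$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(ft$phi, 0)
  # one-sided CI has an infinite upper bound
  g <- fisher_2x2(matrix(c(9, 2, 3, 8), 2), alternative = "greater")
  expect_equal(g$conf_int[2], Inf)
  expect_gt(g$conf_int[1], 1)

  # phi equals the Pearson correlation of the two binary indicators
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 5) + 1, 2)
    x <- rep(c(1, 1, 0, 0), as.vector(t(tab)))
    y <- rep(c(1, 0, 1, 0), as.vector(t(tab)))
    expect_equal(fisher_2x2(tab)$phi, cor(x, y), tolerance = 1e-12)
  }
  expect_error(fisher_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
})

test_that("chi-square power analysis inverts the noncentral distribution", {
  expect_identical(chisq_power_n(w = 0.356, df = 2), 77L)
  # numeric-inversion oracle at w = 0.5, df = 1: lambda* ~ 7.849 -> N = 32
  expect_identical(chisq_power_n(w = 0.5, df = 1), 32L)
  crit <- qchisq(0.95, 1)
  expect_gte(pchisq(crit, 1, ncp = 32 * 0.25, lower.tail = FALSE), 0.8)
  expect_lt(pchisq(crit, 1, ncp = 31 * 0.25, lower.tail = FALSE), 0.8)
  # N non-increasing in w
  ws <- c(0.1, 0.2, 0.3, 0.5, 0.8)
  ns <- vapply(ws, chisq_power_n, 0L, df = 2)
  expect_true(all(diff(ns) <= 0))
  expect_error(chisq_power_n(0, 2), "w > 0")
})

test_that("Mann-Whitney p-values match exact permutation enumeration", {
  mw_perm_oracle <- function(x, y) {
    n1 <- length(x); N <- n1 + length(y)
    pooled <- c(x, y)
    U_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combs <- combn(N, n1)
    Us <- apply(combs, 2, function(idx) {
      sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
    })
    mu <- n1 * (N - n1) / 2
    mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
  }
  set.seed(8)
  for (rep in 1:10) {
    x <- round(rnorm(sample(4:7, 1)), 2)
    y <- round(rnorm(sample(4:7, 1), 0.5), 2)
    res <- compare_distributions(x, y, test = "mann_whitney")
    expect_equal(res$p_value, mw_perm_oracle(x, y), tolerance = 1e-9)
  }
  # fully separated 5 vs 5: U maximal (25), exact p = 2 / choose(10, 5)
  res <- compare_distributions(6:10, 1:5, test = "mann_whitney")
  expect_equal(unname(res$statistic), 25)
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  # identical samples: p ~ 1, r ~ 0
  res0 <- compare_distributions(c(1, 2, 3, 4), c(1, 2, 3, 4),
                                test = "mann_whitney")
  expect_gt(res0$p_value, 0.9)
  expect_lt(abs(res0$effect_size), 0.1)
  # r = z / sqrt(N)
  x <- rnorm(20); y <- rnorm(20, 1)
  r <- compare_distributions(x, y, test = "mann_whitney")
  expect_equal(r$effect_size, r$z / sqrt(40))
})

test_that("Wilcoxon signed rank handles shifts and degenerate input", {
  set.seed(10)
  x <- rnorm(25, 1)
  res <- compare_distributions(x, test = "wilcoxon")
  expect_lt(res$p_value, 0.01)
  expect_gt(res$effect_size, 0)
  # all differences zero: degenerate, flagged
  deg <- compare_distributions(rep(2, 6), test = "wilcoxon", mu = 2)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
})

test_that("two-factor ANOVA reports interaction and Bonferroni simple effects", {
  set.seed(12)
  d <- expand.grid(age = c("young", "older"), cond = c("landmark", "geometry"),
                   rep = 1:15)
  d$y <- rnorm(nrow(d)) + ifelse(d$age == "older" & d$cond == "landmark", 2, 0)
  res <- compare_distributions(test = "anova2", data = d, response = "y",
                               factors = c("age", "cond"))
  expect_s3_class(res, "anova2_result")
  expect_true("age:cond" %in% rownames(res$table))
  expect_lt(res$table["age:cond", "Pr(>F)"], 0.01)
  expect_equal(nrow(res$simple_effects), 2L)
  expect_equal(res$simple_effects$p_bonferroni,
               pmin(1, res$simple_effects$p * 2))
  # the age effect is confined to the landmark condition
  expect_lt(res$simple_effects$p_bonferroni[res$simple_effects$level == "landmark"],
            0.01)
})

test_that("altitude classifier reaches the Gaussian Bayes rate", {
  set.seed(14)
  n <- 500
  d <- 2
  feats <- c(rnorm(n, -d / 2), rnorm(n, d / 2))
  labs <- rep(c("ego", "allo"), each = n)
  clf <- train_altitude_classifier(feats, labs)
  acc <- mean(predict(clf, feats) == labs)
  expect_equal(acc, pnorm(d / 2), tolerance = 0.03)
  # perfectly separated features: training accuracy 1
  sep <- train_altitude_classifier(c(1:5, 11:15), rep(c("a", "b"), each = 5))
  expect_equal(mean(predict(sep, c(1:5, 11:15)) == rep(c("a", "b"), each = 5)), 1)
  # identical feature for both classes: accuracy equals majority-class rate
  same <- train_altitude_classifier(rep(1, 12), rep(c("a", "b"), c(8, 4)))
  expect_equal(mean(predict(same, rep(1, 12)) == rep(c("a", "b"), c(8, 4))),
               8 / 12)
  expect_error(train_altitude_classifier(1:5, rep("a", 5)), "two classes")
})

test_that("hold-out validation: separability, chance level, determinism", {
  set.seed(16)
  # perfectly separable: every repetition 100% correct, p = 0
  f <- c(rnorm(26, -4), rnorm(26, 4))
  l <- rep(c("e", "a"), each = 26)
  hv <- holdout_validate(f, l, reps = 200, seed = 42)
  expect_equal(hv$overall_correct, 1)
  expect_equal(hv$p_value, 0)
  expect_length(hv$accuracies, 200)
  # determinism under a fixed seed
  hv2 <- holdout_validate(f, l, reps = 200, seed = 42)
  expect_identical(hv$accuracies, hv2$accuracies)

  # chance-level features: on any single dataset, repeated hold-out tracks
  # that dataset's accidental feature-label correlation, so chance behavior
  # (accuracy 0.5, p ~ 0.5) holds on average over replicate datasets
  set.seed(19)
  reps <- replicate(30, {
    f0 <- rnorm(105)
    l0 <- rep(c("e", "a"), c(52, 53))
    hv0 <- holdout_validate(f0, l0, reps = 60)
    c(acc = hv0$overall_correct, p = hv0$p_value)
  })
  expect_equal(mean(reps["acc", ]), 0.5, tolerance = 0.03)
  expect_gt(mean(reps["p", ]), 0.3)
  expect_lt(mean(reps["p", ]), 0.7)
})

test_that("leave-one-out validation enumerates folds correctly", {
  # n = 4, features {0, 0, 1, 1}: labels matching the feature split
  # classify perfectly; alternating labels fail every fold (hand-enumerated:
  # after removal, the held-out case's feature value is represented in
  # training only by the opposite class, so each prediction flips)
  f <- c(0, 0, 1, 1)
  lv <- loo_validate(f, c("a", "a", "b", "b"))
  expect_equal(lv$overall_correct, 1)
  lva <- loo_validate(f, c("a", "b", "a", "b"))
  expect_equal(lva$overall_correct, 0)
  # permutation invariance
  set.seed(18)
  ff <- rnorm(20); ll <- rep(c("a", "b"), 10)
  perm <- sample(20)
  r1 <- loo_validate(ff, ll)
  r2 <- loo_validate(ff[perm], ll[perm])
  expect_equal(r1$overall_correct, r2$overall_correct)
  # separable data: 100%
  expect_equal(loo_validate(c(rnorm(10, -3), rnorm(10, 3)),
                            rep(c("a", "b"), each = 10))$overall_correct, 1)
})
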
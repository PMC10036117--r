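# Statistical layer: logistic age-by-condition model with probability-scale
# second differences, contingency statistics with effect sizes, rank tests
# with r = z/sqrt(N), factorial ANOVA with simple effects, chi-square power
# analysis, and the gaze-altitude strategy classifier with repeated hold-out
# and leave-one-out validation.

#' Fit the logistic age-by-condition strategy model
#'
#' Fits a binomial GLM with logit link of the binary majority-allocentric
#' outcome on age group, condition and their interaction. The design is
#' saturated (six cells, six parameters), so the fitted cell probabilities
#' equal the observed cell proportions; they are reported directly from the
#' cell counts, which also keeps them exact under complete separation (a
#' cell with all-allocentric or all-egocentric subjects), where the
#' maximum-likelihood coefficients diverge.
#'
#' @param cohort A `cohort_table` (or data frame) with columns `age_group`,
#'   `condition` and `allocentric_majority` (0/1); all six cells must be
#'   non-empty.
#' @return An object of class `strategy_glm`: list with the fitted `model`,
#'   `cell_probabilities` (data frame: age_group, condition, p, n, k) and
#'   the input data.
#' @export
fit_strategy_glm <- function(cohort) {
  d <- as.data.frame(cohort)
  stopifnot(all(c("age_group", "condition", "allocentric_majority") %in% names(d)))
  cells <- stats::aggregate(allocentric_majority ~ age_group + condition,
                            data = d, FUN = function(x) c(k = sum(x), n = length(x)))
  cells <- cbind(cells[1:2], as.data.frame(cells$allocentric_majority))
  if (length(unique(d$age_group)) < 2L || length(unique(d$condition)) < 2L ||
      nrow(cells) < length(unique(d$age_group)) * length(unique(d$condition))) {
    stop("all age-group x condition cells must be non-empty ",
         "(full two-factor design required)")
  }
  cells$p <- cells$k / cells$n
  model <- suppressWarnings(
    stats::glm(allocentric_majority ~ age_group * condition,
               family = stats::binomial(), data = d))
  structure(list(model = model, cell_probabilities = cells, data = d),
            class = "strategy_glm")
}

#' @export
print.strategy_glm <- function(x, ...) {
  cat("Logistic age x condition strategy model (saturated)\n")
  print(x$cell_probabilities[, c("age_group", "condition", "n", "p")])
  invisible(x)
}

cell_p <- function(fit, age_group, condition) {
  c <- fit$cell_probabilities
  row <- c[c$age_group == age_group & c$condition == condition, ]
  if (nrow(row) != 1L) stop("unknown cell: ", age_group, " x ", condition)
  row
}

#' Probability-scale second difference (interaction contrast)
#'
#' The second difference Delta for a pair of age groups (g1, g2) is the
#' change, from the landmark to the geometry condition, of the between-group
#' difference in allocentric-response probability:
#' `Delta = [P(g1, geometry) - P(g1, landmark)] - [P(g2, geometry) - P(g2,
#' landmark)]`. It is computed on the probability scale from the fitted
#' (= observed, saturated design) cell probabilities. The standard error uses
#' the delta method, which for the saturated binomial model reduces to
#' `sqrt(sum p(1-p)/n)` over the four cells; cells at 0 or 1 contribute zero
#' variance. A nonparametric bootstrap (resampling subjects within cells) is
#' available as an alternative.
#'
#' @param fit A `strategy_glm`.
#' @param group_pair Character vector `c(g1, g2)`; Delta is the condition
#'   effect of `g1` minus that of `g2` (swapping the pair flips the sign).
#' @param conditions Character vector naming the reference and comparison
#'   condition (default landmark to geometry).
#' @param se_method `"delta"` (default) or `"bootstrap"`.
#' @param boot_reps Bootstrap repetitions (when `se_method = "bootstrap"`).
#' @return An object of class `interaction_estimate`: list with `delta`,
#'   `se`, `p_value`, and `cell_probabilities`.
#' @export
second_difference <- function(fit, group_pair,
                              conditions = c("landmark", "geometry"),
                              se_method = c("delta", "bootstrap"),
                              boot_reps = 2000L) {
  stopifnot(inherits(fit, "strategy_glm"), length(group_pair) == 2L)
  se_method <- match.arg(se_method)
  cells <- lapply(group_pair, function(g) {
    lapply(conditions, function(cd) cell_p(fit, g, cd))
  })
  eff <- vapply(cells, function(cc) cc[[2]]$p - cc[[1]]$p, 0)
  delta <- eff[1] - eff[2]
  if (se_method == "delta") {
    v <- sum(vapply(unlist(cells, recursive = FALSE),
                    function(r) r$p * (1 - r$p) / r$n, 0))
    se <- sqrt(v)
  } else {
    d <- fit$data
    reps <- vapply(seq_len(boot_reps), function(i) {
      effs <- vapply(group_pair, function(g) {
        ps <- vapply(conditions, function(cd) {
          y <- d$allocentric_majority[d$age_group == g & d$condition == cd]
          mean(sample(y, replace = TRUE))
        }, 0)
        ps[2] - ps[1]
      }, 0)
      effs[1] - effs[2]
    }, 0)
    se <- stats::sd(reps)
  }
  z <- if (se > 0) delta / se else Inf * sign(delta)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(delta = delta, se = se, p_value = p,
                 group_pair = group_pair,
                 cell_probabilities = fit$cell_probabilities),
            class = "interaction_estimate")
}

#' @export
print.interaction_estimate <- function(x, ...) {
  cat(sprintf("Second difference (%s vs %s): Delta = %.3f, SE = %.3f, p = %.3g\n",
              x$group_pair[1], x$group_pair[2], x$delta, x$se, x$p_value))
  invisible(x)
}

#' Fisher's exact test with odds ratio and effect sizes
#'
#' Exact hypergeometric test of a 2x2 contingency table, returning the
#' conditional maximum-likelihood odds ratio with its confidence interval
#' (one-sided of the form `[L, Inf)` under a `"greater"` alternative), the
#' phi coefficient, and Cohen's w (equal to `|phi|` for a 2x2 table).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`; the direction
#'   of a one-sided test must be chosen by the caller.
#' @param conf_level Confidence level for the odds-ratio interval.
#' @return An object of class `test_result` with fields `statistic`
#'   (named `Fisher-p`), `p_value`, `odds_ratio`, `conf_int`, `phi`,
#'   `cohens_w`, `n`.
#' @export
fisher_2x2 <- function(table, alternative = c("two.sided", "greater", "less"),
                       conf_level = 0.95) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0),
            all(abs(table - round(table)) < 1e-8))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("a margin of the table is zero")
  }
  ft <- stats::fisher.test(table, alternative = alternative,
                           conf.level = conf_level)
  x11 <- table[1, 1]; x12 <- table[1, 2]
  x21 <- table[2, 1]; x22 <- table[2, 2]
  n <- sum(table)
  phi <- (x11 * x22 - x12 * x21) /
    sqrt(prod(c(x11 + x12, x21 + x22, x11 + x21, x12 + x22)))
  structure(list(statistic = c("Fisher-p" = unname(ft$p.value)),
                 p_value = ft$p.value,
                 odds_ratio = unname(ft$estimate),
                 conf_int = as.numeric(ft$conf.int),
                 phi = phi, cohens_w = abs(phi), n = n,
                 alternative = alternative),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(names(x$statistic)[1], "=", signif(unname(x$statistic)[1], 4),
      " p =", signif(x$p_value, 3), " N =", x$n, "\n")
  if (!is.null(x$effect_size)) {
    cat("  effect size r =", signif(x$effect_size, 3), "\n")
  }
  if (!is.null(x$odds_ratio)) {
    cat("  odds ratio =", signif(x$odds_ratio, 4), " CI = [",
        signif(x$conf_int[1], 3), ",", signif(x$conf_int[2], 3), "]",
        " w =", signif(x$cohens_w, 3), "\n")
  }
  invisible(x)
}

#' Minimal sample size for a chi-square test
#'
#' Smallest integer N for which the noncentral chi-square test with
#' noncentrality `lambda = N w^2` and the given degrees of freedom reaches
#' the target power at level alpha.
#'
#' @param w Cohen's w effect size (> 0).
#' @param df Degrees of freedom of the test (e.g. 2 for a 3-group by
#'   2-outcome contingency design).
#' @param alpha Significance level.
#' @param power Target power.
#' @return Integer minimal N.
#' @examples
#' chisq_power_n(w = 0.356, df = 2)  # 77
#' @export
chisq_power_n <- function(w, df, alpha = 0.05, power = 0.8) {
  stopifnot(w > 0, df >= 1, alpha > 0, alpha < 1, power > alpha, power < 1)
  crit <- stats::qchisq(1 - alpha, df)
  pow <- function(lambda) stats::pchisq(crit, df, ncp = lambda, lower.tail = FALSE)
  lam <- stats::uniroot(function(l) pow(l) - power, c(1e-6, 1e4),
                        tol = 1e-10)$root
  n <- ceiling(lam / w^2 - 1e-9)
  while (n > 1 && pow((n - 1) * w^2) >= power) n <- n - 1
  while (pow(n * w^2) < power) n <- n + 1
  as.integer(n)
}

# z statistic of the Mann-Whitney U via the normal approximation with tie
# correction and continuity correction (the approximation behind r = z/sqrt(N))
mw_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - sum(ties^3 - ties) /
                            ((n1 + n2) * (n1 + n2 - 1)))
  if (sig2 <= 0) return(list(U = U, z = 0))
  cc <- sign(U - mu) * 0.5
  list(U = U, z = (U - mu - cc) / sqrt(sig2))
}

#' Nonparametric and factorial comparisons with effect sizes
#'
#' One entry point for the distribution comparisons used in the analyses:
#' Mann-Whitney U for independent groups and Wilcoxon signed rank for paired
#' differences against a null median, both reporting the rank effect size
#' `r = z / sqrt(N)` from the normal approximation (N the total sample
#' size); and a two-factor ANOVA reporting main effects, the interaction,
#' and optionally Bonferroni-corrected simple effects of the first factor
#' within each level of the second.
#'
#' @param x Numeric sample (or paired differences for `wilcoxon`).
#' @param y Second sample (`mann_whitney` only).
#' @param test `"mann_whitney"`, `"wilcoxon"` or `"anova2"`.
#' @param mu Null median for `wilcoxon` (default 0).
#' @param data,response,factors For `anova2`: a data frame, the response
#'   column name, and the two factor column names.
#' @param simple_effects Whether to add simple-effects tests (`anova2`).
#' @param exact Use the exact rank-test distribution where available
#'   (default: exact for small samples without ties, as in
#'   [stats::wilcox.test()]).
#' @return A `test_result` (rank tests) or a list of class `anova2_result`
#'   with the ANOVA table and simple-effects data frame.
#' @export
compare_distributions <- function(x = NULL, y = NULL,
                                  test = c("mann_whitney", "wilcoxon", "anova2"),
                                  mu = 0, data = NULL, response = NULL,
                                  factors = NULL, simple_effects = TRUE,
                                  exact = NULL) {
  test <- match.arg(test)
  if (test == "mann_whitney") {
    stopifnot(length(x) >= 1, length(y) >= 1)
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
    z <- mw_z(x, y)
    N <- length(x) + length(y)
    return(structure(list(statistic = c(U = unname(wt$statistic)),
                          p_value = wt$p.value,
                          effect_size = z$z / sqrt(N), z = z$z, n = N),
                     class = "test_result"))
  }
  if (test == "wilcoxon") {
    stopifnot(length(x) >= 1)
    if (all(x == mu)) {
      return(structure(list(statistic = c(W = NA_real_), p_value = NA_real_,
                            effect_size = NA_real_, n = length(x),
                            degenerate = TRUE),
                       class = "test_result"))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, mu = mu, exact = exact))
    d <- x[x != mu] - mu
    n <- length(d)
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    mu_v <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- if (sig2 > 0) (V - mu_v - sign(V - mu_v) * 0.5) / sqrt(sig2) else 0
    return(structure(list(statistic = c(W = unname(wt$statistic)),
                          p_value = wt$p.value,
                          effect_size = z / sqrt(length(x)), z = z,
                          n = length(x)),
                     class = "test_result"))
  }
  # two-factor ANOVA
  stopifnot(is.data.frame(data), length(factors) == 2L,
            all(c(response, factors) %in% names(data)))
  d <- data
  d[[factors[1]]] <- factor(d[[factors[1]]])
  d[[factors[2]]] <- factor(d[[factors[2]]])
  fml <- stats::as.formula(paste(response, "~", factors[1], "*", factors[2]))
  fit <- stats::aov(fml, data = d)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  simple <- NULL
  if (simple_effects) {
    lv <- levels(d[[factors[2]]])
    rows <- lapply(lv, function(l) {
      sub <- d[d[[factors[2]]] == l, ]
      f1 <- stats::aov(stats::as.formula(paste(response, "~", factors[1])),
                       data = sub)
      s <- summary(f1)[[1]]
      data.frame(level = l, F = s$`F value`[1], df1 = s$Df[1], df2 = s$Df[2],
                 p = s$`Pr(>F)`[1], stringsAsFactors = FALSE)
    })
    simple <- do.call(rbind, rows)
    simple$p_bonferroni <- pmin(1, simple$p * length(lv))
  }
  structure(list(table = tab, simple_effects = simple, model = fit),
            class = "anova2_result")
}

#' Train the gaze-altitude logistic classifier
#'
#' Single-predictor logistic regression of a binary label (navigation
#' strategy, or experimental condition) on the mean orientation-period gaze
#' altitude, with a 0.5 decision threshold on the predicted probability.
#' Under complete separation the maximum-likelihood coefficients diverge but
#' the decision rule (a threshold on the feature) is still well defined and
#' is used as-is.
#'
#' @param features Numeric vector (one value per case, e.g. mean gaze
#'   altitude in degrees).
#' @param labels Factor or vector coercible to a 2-level factor with both
#'   classes present.
#' @return Object of class `altitude_classifier` with the fitted `model`,
#'   class `levels`, and `threshold`.
#' @export
train_altitude_classifier <- function(features, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L || any(table(labels) == 0L)) {
    stop("exactly two classes (both present) are required")
  }
  d <- data.frame(y = labels, x = as.numeric(features))
  model <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial(), data = d))
  structure(list(model = model, levels = levels(labels), threshold = 0.5),
            class = "altitude_classifier")
}

#' @rdname train_altitude_classifier
#' @param object An `altitude_classifier`.
#' @param newdata Numeric vector of feature values.
#' @param ... Unused.
#' @return `predict()`: factor of predicted class labels.
#' @export
predict.altitude_classifier <- function(object, newdata, ...) {
  p <- stats::predict(object$model, data.frame(x = as.numeric(newdata)),
                      type = "response")
  factor(object$levels[1L + (p > object$threshold)], levels = object$levels)
}

#' Repeated 25% hold-out validation
#'
#' Repeatedly trains the gaze-altitude classifier on 75% of the cases and
#' tests it on the remaining 25%, accumulating the distribution of the
#' per-repetition correctly-classified proportion. The reported p-value is
#' the fraction of repetitions in which fewer than half of the held-out
#' cases were classified correctly. Splits are stratified by class by
#' default; in unstratified mode a split that leaves a class absent from
#' training is re-drawn (and counted).
#'
#' @param features Numeric feature vector.
#' @param labels 2-level labels.
#' @param fraction Held-out fraction (default 0.25).
#' @param reps Repetitions (default 1000).
#' @param stratified Stratify splits by class (default `TRUE`).
#' @param seed Optional integer seed for reproducible splits.
#' @return Object of class `validation_report`: scheme, per-repetition
#'   accuracies, mean accuracy, per-class correct rates (averaged over
#'   repetitions), `p_value`, and the number of re-drawn splits.
#' @export
holdout_validate <- function(features, labels, fraction = 0.25, reps = 1000L,
                             stratified = TRUE, seed = NULL) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2L, length(features) == length(labels),
            all(table(labels) >= 3L))
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  acc <- numeric(reps)
  class_correct <- matrix(NA_real_, reps, 2L,
                          dimnames = list(NULL, levels(labels)))
  redraws <- 0L
  for (r in seq_len(reps)) {
    repeat {
      if (stratified) {
        train_idx <- unlist(lapply(levels(labels), function(l) {
          idx <- which(labels == l)
          k <- max(2L, round((1 - fraction) * length(idx)))
          k <- min(k, length(idx) - 1L)
          sample(idx, k)
        }))
      } else {
        k <- max(2L, round((1 - fraction) * n))
        train_idx <- sample.int(n, min(k, n - 1L))
      }
      if (nlevels(droplevels(labels[train_idx])) == 2L &&
          all(table(labels[train_idx]) >= 2L)) break
      redraws <- redraws + 1L
    }
    test_idx <- setdiff(seq_len(n), train_idx)
    clf <- train_altitude_classifier(features[train_idx], labels[train_idx])
    pred <- predict(clf, features[test_idx])
    truth <- labels[test_idx]
    acc[r] <- mean(pred == truth)
    for (l in levels(labels)) {
      sel <- truth == l
      class_correct[r, l] <- if (any(sel)) mean(pred[sel] == truth[sel]) else NA
    }
  }
  structure(list(scheme = "holdout25", fraction = fraction, reps = reps,
                 accuracies = acc, overall_correct = mean(acc),
                 class_correct = colMeans(class_correct, na.rm = TRUE),
                 p_value = mean(acc < 0.5), redraws = redraws),
            class = "validation_report")
}

#' Leave-one-out validation
#'
#' Trains on all but one case and tests on the held-out case, over every
#' case in turn. Folds in which removing the case leaves a class absent from
#' the training set are flagged and excluded from the rate.
#'
#' @param features Numeric feature vector.
#' @param labels 2-level labels (at least 3 cases).
#' @return Object of class `validation_report` with per-fold correctness and
#'   the overall proportion of held-out cases classified correctly.
#' @export
loo_validate <- function(features, labels) {
  labels <- factor(labels)
  n <- length(labels)
  stopifnot(n >= 3L, nlevels(labels) == 2L)
  correct <- rep(NA, n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (nlevels(droplevels(labels[tr])) < 2L) next  # class absent: flagged
    clf <- train_altitude_classifier(features[tr], labels[tr])
    correct[i] <- predict(clf, features[i]) == labels[i]
  }
  cc <- vapply(levels(labels), function(l) {
    mean(correct[labels == l], na.rm = TRUE)
  }, 0)
  structure(list(scheme = "leave_one_out", fold_correct = correct,
                 overall_correct = mean(correct, na.rm = TRUE),
                 class_correct = cc, flagged_folds = sum(is.na(correct))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation (", x$scheme, "): ",
      sprintf("%.1f%%", 100 * x$overall_correct), " correct", sep = "")
  if (!is.null(x$p_value)) cat(", p =", signif(x$p_value, 3))
  cat("\n  per class: ",
      paste(names(x$class_correct),
            sprintf("%.1f%%", 100 * x$class_correct),
            sep = " ", collapse = ", "), "\n", sep = "")
  invisible(x)
}
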
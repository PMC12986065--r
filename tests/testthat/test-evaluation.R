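# helper: a one-rater matrix with k of n items answered correctly
one_rater_matrix <- function(k, n, group = "g") {
  key <- data.frame(item_id = sprintf("q%02d", 1:n), key = "A",
                    stringsAsFactors = FALSE)
  sel <- c(rep("A", k), rep("B", n - k))
  resp <- data.frame(respondent_id = "r1", group = group,
                     item_id = key$item_id, selection = sel,
                     stringsAsFactors = FALSE)
  response_matrix(resp, key)
}

test_that("scoring reproduces the print-convention percentages", {
  s <- score_responses(one_rater_matrix(29, 30))
  expect_equal(s$correct, 29)
  expect_equal(s$accuracy, 96.7)
  expect_equal(score_responses(one_rater_matrix(0, 30))$accuracy, 0.0)
  # pooled error rates
  expect_equal(accuracy_pct(172, 900), 19.1)
  expect_equal(accuracy_pct(87, 300), 29.0)
  expect_equal(round_half_up(96.65, 1), 96.7)  # half rounds up, not to even
  bad <- data.frame(respondent_id = "r1", group = "g", item_id = "q01",
                    selection = "F", stringsAsFactors = FALSE)
  expect_error(response_matrix(bad, data.frame(item_id = "q01", key = "A")),
               class = "tg18_validation_error")
})

test_that("Clopper-Pearson interval matches the exact binomial bounds", {
  ci <- binomial_ci(29, 30, 0.95)
  expect_equal(round_half_up(ci, 1), c(82.8, 99.9))
  expect_equal(binomial_ci(0, 10)[1], 0.0)
  expect_equal(binomial_ci(30, 30)[2], 100.0)
  expect_true(ci[1] <= 100 * 29 / 30 && 100 * 29 / 30 <= ci[2])
  expect_error(binomial_ci(0, 0), class = "tg18_validation_error")
})

test_that("Clopper-Pearson coverage is conservative at p = 0.8, n = 30", {
  set.seed(20260924)
  k <- rbinom(2000, 30, 0.8)
  covered <- vapply(k, function(ki) {
    ci <- binomial_ci(ki, 30)
    ci[1] <= 80 && 80 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("AUC equals exhaustive pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 0, 1)), 0.5)
  expect_equal(roc_auc(rep(0.7, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)),
               class = "tg18_validation_error")
  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), 2)  # rounding induces ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(scores, labels), auc_paircount(scores, labels))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.5)
  if (length(unique(labels)) == 2) {
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("DeLong comparison: identities, antisymmetry, jackknife variance", {
  set.seed(9)
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  a <- c(0.9, 0.8, 0.7, 0.35, 0.6, 0.3, 0.2, 0.1)
  b <- c(0.85, 0.4, 0.75, 0.45, 0.55, 0.5, 0.25, 0.15)
  same <- delong_compare(a, a, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  d1 <- delong_compare(a, b, labels)
  d2 <- delong_compare(b, a, labels)
  expect_equal(d1$z, -d2$z)
  expect_equal(d1$p, d2$p)
  # single-curve DeLong variance equals the grouped jackknife, brute force
  va <- stats::var(placements_for_test(a, labels)$v10) / 4 +
    stats::var(placements_for_test(a, labels)$v01) / 4
  expect_equal(va, delong_var_jackknife(a, labels), tolerance = 1e-9)
  vb <- stats::var(placements_for_test(b, labels)$v10) / 4 +
    stats::var(placements_for_test(b, labels)$v01) / 4
  expect_equal(vb, delong_var_jackknife(b, labels), tolerance = 1e-9)
})

test_that("DeLong z and p agree with pROC's implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  labels <- rep(c(1, 0), each = 20)
  a <- labels * 0.4 + runif(40)
  b <- labels * 0.2 + runif(40)
  mine <- delong_compare(a, b, labels)
  ra <- pROC::roc(labels, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(labels, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(abs(mine$z), abs(as.numeric(ref$statistic)),
               tolerance = 1e-8)
  expect_equal(mine$p, as.numeric(ref$p.value), tolerance = 1e-8)
})

test_that("Fleiss' kappa matches pair-counting and is relabel invariant", {
  # unanimous raters over heterogeneous items
  R1 <- rbind(c(3, 0), c(0, 3), c(3, 0))
  expect_equal(fleiss_kappa(R1)$kappa, 1.0)
  # small fixture against the independent pair-counting oracle
  R2 <- rbind(c(2, 1, 0), c(0, 3, 0), c(1, 1, 1), c(0, 0, 3))
  expect_equal(fleiss_kappa(R2)$kappa, fleiss_kappa_pairs(R2))
  expect_equal(fleiss_kappa(R2[, c(3, 1, 2)])$kappa,
               fleiss_kappa(R2)$kappa)
  expect_error(fleiss_kappa(rbind(c(2, 1), c(3, 1))),
               class = "tg18_validation_error")
  expect_error(fleiss_kappa(rbind(c(3, 0), c(3, 0))),
               class = "tg18_degenerate_agreement")
  # bootstrap CI brackets the point estimate, reproducibly
  k1 <- fleiss_kappa(R2, ci = TRUE, n_boot = 200, seed = 5)
  k2 <- fleiss_kappa(R2, ci = TRUE, n_boot = 200, seed = 5)
  expect_identical(k1$ci, k2$ci)
})

test_that("Cohen's kappa: perfect, independent and symmetric cases", {
  a <- rep(c("A", "B", "C"), 10)
  expect_equal(cohen_kappa(a, a)$kappa, 1.0)
  # independent-by-construction marginals give kappa 0 exactly
  x <- rep(c("A", "B"), each = 50)
  y <- rep(c("A", "B"), times = 50)
  expect_equal(cohen_kappa(x, y)$kappa, 0.0)
  b <- rep(c("B", "C", "A"), 10)
  expect_equal(cohen_kappa(a, b)$kappa, cohen_kappa(b, a)$kappa)
  expect_error(cohen_kappa(character(0), character(0)),
               class = "tg18_validation_error")
})

test_that("McNemar statistic and monotonicity", {
  expect_equal(mcnemar_test(5, 5)$statistic, 0)
  m <- mcnemar_test(8, 2)
  expect_equal(m$statistic, 3.6)
  expect_equal(m$p, stats::pchisq(3.6, 1, lower.tail = FALSE))
  # cross-check against the stock implementation, uncorrected
  ref <- stats::mcnemar.test(matrix(c(10, 2, 8, 10), 2), correct = FALSE)
  expect_equal(m$statistic, unname(ref$statistic))
  expect_equal(m$p, ref$p.value)
  p_prev <- 1
  for (b in 5:9) {
    p <- mcnemar_test(b, 10 - b)$p
    expect_lte(p, p_prev + 1e-12)
    p_prev <- p
  }
  expect_error(mcnemar_test(0, 0), class = "tg18_degenerate_table")
})

test_that("group tests: ANOVA F against the sum-of-squares oracle", {
  groups <- list(a = c(81, 83, 85, 80), b = c(72, 74, 70, 75),
                 c = c(78, 79, 77, 81))
  gt <- group_tests(groups)
  expect_equal(gt$anova$F, anova_F_ss(groups), tolerance = 1e-10)
  expect_equal(gt$anova$df, c(2, 9))
  # identical means with spread -> F = 0
  flat <- list(a = c(79, 81), b = c(78, 82), c = c(80.5, 79.5))
  expect_equal(group_tests(flat)$anova$F, 0)
  # Bonferroni is min(1, m * p)
  m <- nrow(gt$pairwise_t)
  expect_equal(gt$pairwise_t$p_bonferroni,
               pmin(1, gt$pairwise_t$p * m))
  expect_equal(nrow(gt$tukey), 3)
  expect_error(group_tests(list(a = c(1, 1), b = c(2, 2))),
               class = "tg18_validation_error")
})

test_that("categorical test switches to Fisher on small expected counts", {
  even <- categorical_test(matrix(c(5, 5, 5, 5), 2))
  expect_identical(even$method, "chi-square")
  expect_equal(even$statistic, 0)
  small <- categorical_test(matrix(c(1, 2, 9, 8), 2))
  expect_identical(small$method, "fisher")
  expect_true(any(small$expected < 5))
  # Fisher p equals exhaustive hypergeometric enumeration
  set.seed(3)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 3), 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- categorical_test(tab)
    if (res$method == "fisher") {
      expect_equal(res$p, fisher_p_enum(tab), tolerance = 1e-12)
    }
  }
  expect_error(categorical_test(matrix(0, 2, 2)),
               class = "tg18_validation_error")
})

test_that("stratified accuracies aggregate to the overall accuracy", {
  bank <- generate_question_bank(generation_spec(seed = 2024))
  rm <- simulate_expert_cohort(bank, c(g1 = 0.8, g2 = 0.7), 5, seed = 6)
  rep <- evaluate_matrix(rm)
  agg <- stats::aggregate(cbind(correct, total) ~ group, data = rep$by_domain,
                          FUN = sum)
  for (i in seq_len(nrow(agg))) {
    grp <- rep$respondents[rep$respondents$group == agg$group[i], ]
    expect_equal(agg$correct[i], sum(grp$correct))
    expect_equal(agg$total[i], sum(grp$total))
  }
  # report-level invariants: CIs contain their point estimates
  expect_true(all(rep$groups$ci_lo <= rep$groups$mean_accuracy))
  expect_true(all(rep$groups$ci_hi >= rep$groups$mean_accuracy))
  expect_true(all(rep$respondents$accuracy >= 0 &
                    rep$respondents$accuracy <= 100))
})
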
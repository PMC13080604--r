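test_that("confusion metrics match the screening-study values and conventions", {
  m <- binary_metrics(tp = 70, fp = 24, fn = 3, tn = 1)
  expect_equal(round(m$sensitivity, 3), 0.959)
  expect_equal(round(m$specificity, 3), 0.040)
  expect_equal(round(m$precision, 3), 0.745)
  expect_equal(round(m$f1, 3), 0.838)
  m2 <- binary_metrics(tp = 61, fp = 14, fn = 12, tn = 11)
  expect_equal(round(m2$sensitivity, 3), 0.836)
  expect_equal(round(m2$specificity, 3), 0.440)
  # all-correct: every defined metric is 1
  m3 <- binary_metrics(tp = 10, fp = 0, fn = 0, tn = 5)
  expect_equal(c(m3$sensitivity, m3$specificity, m3$precision, m3$f1),
               rep(1, 4))
  # zero denominators are undefined (NA), never silently 0
  m4 <- binary_metrics(tp = 0, fp = 0, fn = 3, tn = 5)
  expect_true(is.na(m4$precision))
  expect_equal(m4$sensitivity, 0)
  expect_error(binary_metrics(tp = 0, fp = 0, fn = 0, tn = 0), "empty")
  # F1 is the harmonic mean of its own precision and recall
  withr::with_seed(1, {
    for (i in 1:20) {
      cm <- as.list(rmultinom(1, 100, c(0.3, 0.2, 0.2, 0.3))[, 1] + 1)
      names(cm) <- c("tp", "fp", "fn", "tn")
      mm <- binary_metrics(tibble::as_tibble(cm))
      expect_equal(mm$f1,
                   2 * mm$precision * mm$sensitivity /
                     (mm$precision + mm$sensitivity),
                   tolerance = 1e-12)
    }
  })
})

test_that("logical-OR combination reproduces the joint-screen arithmetic", {
  # 73 positives: scale finds 61, AI adds 11 unique -> 72/73 combined
  truth <- rep(c(TRUE, FALSE), c(73, 25))
  scale_pred <- c(rep(TRUE, 61), rep(FALSE, 12), rep(FALSE, 25))
  ai_pred <- c(rep(TRUE, 59), rep(FALSE, 2), rep(TRUE, 11), rep(FALSE, 1),
               rep(TRUE, 24), FALSE)
  comb <- combine_or(ai_pred, scale_pred)
  cm <- binary_metrics(confusion_counts(truth, comb))
  expect_equal(cm$tp, 72)
  expect_equal(round(cm$sensitivity, 3), 0.986)

  # the all-negative screen is the identity element
  expect_equal(combine_or(scale_pred, rep(FALSE, 98)), scale_pred)
  expect_error(combine_or(c(TRUE, FALSE), c(TRUE, FALSE),
                          id_a = 1:2, id_b = 2:3), "misaligned")
  expect_error(combine_or(c(TRUE), c(TRUE, FALSE)), "length")
})

test_that("OR-combination dominates on sensitivity and concedes specificity", {
  withr::with_seed(2, {
    for (i in 1:100) {
      n <- sample(30:120, 1)
      truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
      if (length(unique(truth)) < 2) truth[1:2] <- c(0, 1)
      a <- rbinom(n, 1, 0.4) == 1
      b <- rbinom(n, 1, 0.4) == 1
      mc <- binary_metrics(confusion_counts(truth, combine_or(a, b)))
      ma <- binary_metrics(confusion_counts(truth, a))
      mb <- binary_metrics(confusion_counts(truth, b))
      expect_gte(mc$sensitivity, max(ma$sensitivity, mb$sensitivity))
      expect_lte(mc$specificity, min(ma$specificity, mb$specificity))
    }
  })
})

test_that("macro F1 averages one-vs-rest F1s with the absent-class rule", {
  perf <- diag(c(10, 8, 6))
  expect_equal(macro_f1(perf)$macro_f1, 1)
  withr::with_seed(3, {
    for (i in 1:25) {
      cm <- matrix(rpois(9, 4), 3, 3)
      if (sum(cm) == 0) cm[1, 1] <- 1
      expect_equal(macro_f1(cm)$macro_f1, brute_macro_f1(cm))
    }
  })
  absent <- matrix(c(5, 0, 0, 0, 3, 0, 0, 0, 0), 3, 3)
  expect_warning(res <- macro_f1(absent), "absent")
  expect_equal(res$per_class$f1[3], 0)
  expect_error(macro_f1(matrix(0, 3, 3)), "empty")
})

test_that("rank-based AUC equals pair counting and survives monotone maps", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  withr::with_seed(4, {
    for (i in 1:30) {
      n <- sample(20:100, 1)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      sc <- rnorm(n, 0.5 * y)
      if (i %% 4 == 0) sc <- round(sc)        # heavy ties
      auc <- roc_auc(sc, y)$auc
      expect_equal(auc, pairwise_auc(sc, y))
      # strictly monotone transforms leave the AUC unchanged
      expect_equal(roc_auc(exp(sc / 2), y)$auc, auc)
    }
  })
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(5, {
    y <- rbinom(300, 1, 0.4)
    sc <- rnorm(300, 0.8 * y)
  })
  ours <- roc_auc(sc, y)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("AUC under independent labels sits at chance", {
  withr::with_seed(6, {
    aucs <- vapply(1:20, function(i) {
      y <- rbinom(500, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      roc_auc(rnorm(500), y)$auc
    }, numeric(1))
  })
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("bootstrap intervals are seeded, degenerate-safe, and calibrated", {
  dd <- tibble::tibble(x = rep(2.5, 40))
  ci <- bootstrap_ci(dd, function(d) mean(d$x), B = 200, seed = 1)
  expect_equal(ci$ci_low, 2.5)
  expect_equal(ci$ci_high, 2.5)

  withr::with_seed(7, {
    d2 <- tibble::tibble(score = rnorm(60), y = rbinom(60, 1, 0.5))
  })
  stat <- function(d) tryCatch(roc_auc(d$score, d$y)$auc,
                               error = function(e) NA_real_)
  c1 <- bootstrap_ci(d2, stat, B = 200, seed = 9, stratify_by = "y")
  c2 <- bootstrap_ci(d2, stat, B = 200, seed = 9, stratify_by = "y")
  expect_identical(c1, c2)
  expect_lte(c1$ci_low, c1$estimate)
  expect_gte(c1$ci_high, c1$estimate)
  expect_error(bootstrap_ci(d2, stat, B = 50, seed = 1), "at least 100")
})

test_that("bootstrap coverage of a known AUC is near nominal", {
  # nested simulation at reduced size: true AUC for N(delta,1) vs N(0,1)
  delta <- 1
  true_auc <- pnorm(delta / sqrt(2))
  withr::with_seed(8, { sim_seeds <- sample.int(1e6, 200) })
  covered <- vapply(sim_seeds, function(s) {
    withr::with_seed(s, {
      y <- rep(c(0, 1), each = 40)
      sc <- rnorm(80) + delta * y
    })
    ci <- bootstrap_ci(tibble::tibble(score = sc, y = y),
                       function(d) tryCatch(roc_auc(d$score, d$y)$auc,
                                            error = function(e) NA_real_),
                       B = 300, seed = s, stratify_by = "y")
    ci$ci_low <= true_auc && true_auc <= ci$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("decision curves satisfy their closed forms", {
  withr::with_seed(9, {
    y <- rbinom(100, 1, 0.4)
    p <- runif(100)
  })
  grid <- seq(0.1, 0.9, by = 0.1)
  dc <- decision_curve(p, y, grid)
  prev <- mean(y)
  expect_true(all(dc$nb_treat_none == 0))
  expect_equal(dc$nb_treat_all, prev - (1 - prev) * grid / (1 - grid))
  # perfect classifier: no false positives, net benefit = prevalence
  dcp <- decision_curve(as.numeric(y), y, grid)
  expect_true(all(abs(dcp$net_benefit - prev) < 1e-12))
  expect_error(decision_curve(p, y, numeric(0)), "empty")
  expect_error(decision_curve(p, y, c(0, 0.5)), "strictly")
})

test_that("gain reports compute relative improvements in percent", {
  single <- binary_metrics(tp = 24, fp = 26, fn = 28, tn = 20)
  comb <- binary_metrics(tp = 36, fp = 34, fn = 16, tn = 12)
  g <- gain_report(single, comb)
  expect_equal(g$gain_pct[g$metric == "sensitivity"], 50)
  gd <- gain_report(binary_metrics(tp = 61, fp = 14, fn = 12, tn = 11),
                    binary_metrics(tp = 72, fp = 25, fn = 1, tn = 0))
  expect_equal(gd$gain_pct[gd$metric == "sensitivity"], 11 / 61 * 100)
  same <- gain_report(single, single)
  expect_true(all(same$gain_pct == 0))
  zero <- binary_metrics(tp = 0, fp = 5, fn = 10, tn = 10)
  gz <- gain_report(zero, comb)
  expect_true(is.na(gz$gain_pct[gz$metric == "sensitivity"]))
})
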
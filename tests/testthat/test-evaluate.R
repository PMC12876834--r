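test_that("confusion metrics reproduce the screening 2x2 arithmetic", {
  # the case-level screening table: 13 true positives, 10 false positives,
  # 6 true negatives, no false negatives
  pred <- c(rep("FN", 13), rep("FN", 10), rep("control", 6))
  truth <- c(rep("FN", 13), rep("control", 16))
  cm <- confusion_metrics(pred, truth, positive = "FN", level = "case")
  expect_equal(round(cm$ppv, 2), 0.57)
  expect_equal(round(cm$specificity, 2), 0.38)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$npv, 1)
  expect_equal(cm$precision, cm$ppv)
  expect_equal(cm$recall, cm$sensitivity)

  perfect <- confusion_metrics(truth, truth, positive = "FN", level = "case")
  for (m in c("accuracy", "precision", "recall", "f1", "sensitivity",
              "specificity", "ppv", "npv"))
    expect_equal(perfect[[m]], 1)

  expect_error(confusion_metrics("FN", c("FN", "FN")), "length")

  set.seed(20)
  for (i in 1:50) {
    p <- runif(30) < 0.5; t <- runif(30) < 0.5
    cm <- confusion_metrics(p, t, level = "tile")
    o <- oracle_confusion(p, t)
    expect_equal(cm$accuracy, o$accuracy)
    expect_equal(cm$sensitivity, o$sens)
    expect_equal(cm$specificity, o$spec)
    expect_equal(cm$ppv, o$ppv)
    expect_equal(cm$npv, o$npv)
    if (!is.na(cm$f1))
      expect_equal(cm$f1, 2 * o$ppv * o$sens / (o$ppv + o$sens))
  }
  # undefined ratios propagate as NA, never 0
  nd <- confusion_metrics(rep(FALSE, 4), rep(FALSE, 4))
  expect_true(is.na(nd$precision) && is.na(nd$recall) && is.na(nd$f1))
})

test_that("auc_roc equals pair counting with ties at one half", {
  expect_equal(auc_roc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc_roc(rep(2, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(auc_roc(1:3, rep(TRUE, 3)), "both classes")
  set.seed(21)
  for (i in 1:50) {
    n <- sample(5:25, 1)
    s <- sample(1:6, n, replace = TRUE)  # heavy ties
    y <- runif(n) < 0.5
    if (all(y) || !any(y)) next
    expect_equal(auc_roc(s, y), oracle_auc(s, y))
    # trapezoidal integration of the empirical ROC agrees
    thr <- sort(unique(s))
    sens <- vapply(c(-Inf, thr), function(t) mean(s[y] >= t), numeric(1))
    fpr <- vapply(c(-Inf, thr), function(t) mean(s[!y] >= t), numeric(1))
    sens <- c(sens, 0); fpr <- c(fpr, 0)
    trap <- sum((fpr[-length(fpr)] - fpr[-1]) *
                  (sens[-length(sens)] + sens[-1]) / 2)
    expect_equal(auc_roc(s, y), trap, tolerance = 1e-9)
  }
})

test_that("bootstrap CIs are percentile-based, seeded and NA-aware", {
  acc <- function(p, t) mean(p == t)
  ci <- bootstrap_ci(acc, rep(1, 20), rep(1, 20), n_resamples = 200, seed = 1)
  expect_equal(ci$point, 1)
  expect_equal(ci$lo95, 1)
  expect_equal(ci$hi95, 1)

  set.seed(22)
  p <- runif(50) < 0.5; t <- runif(50) < 0.5
  c1 <- bootstrap_ci(acc, p, t, n_resamples = 300, seed = 9)
  c2 <- bootstrap_ci(acc, p, t, n_resamples = 300, seed = 9)
  expect_identical(c1$lo95, c2$lo95)
  expect_identical(c1$hi95, c2$hi95)
  expect_lte(c1$lo95, c1$point)
  expect_gte(c1$hi95, c1$point)

  # metric undefined in most resamples -> error; in a few -> counted
  sens <- function(p, t) if (sum(t) == 0) NA_real_ else sum(p & t) / sum(t)
  expect_error(bootstrap_ci(sens, c(TRUE, FALSE), c(FALSE, FALSE),
                            n_resamples = 100, seed = 2), "undefined")
  ci3 <- bootstrap_ci(sens, runif(40) < 0.5, c(TRUE, runif(39) < 0.1),
                      n_resamples = 200, seed = 3)
  expect_gte(ci3$n_undefined, 0)
})

test_that("youden_cutoff matches a brute-force sweep and favours sensitivity", {
  r <- youden_cutoff(c(1, 2, 3, 10, 11, 12),
                     c("control", "control", "control", "FN", "FN", "FN"))
  expect_equal(r$J, 1)
  expect_equal(r$youden_sens, 1)
  expect_equal(r$youden_spec, 1)
  expect_equal(r$auc, 1)
  expect_error(youden_cutoff(1:3, rep("FN", 3)), "both classes")

  set.seed(23)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    s <- round(runif(n, 0, 5), 1)
    y <- runif(n) < 0.5
    if (all(y) || !any(y)) next
    r <- youden_cutoff(s, y, positive = TRUE)
    # brute force over all midpoints
    u <- sort(unique(s))
    thr <- if (length(u) == 1) u else (u[-length(u)] + u[-1]) / 2
    J <- vapply(thr, function(t)
      mean(s[y] >= t) + mean(s[!y] < t) - 1, numeric(1))
    expect_equal(r$J, max(J), tolerance = 1e-12)
    expect_equal(r$youden_cutoff, thr[which.max(J)])  # lowest on ties
    expect_true(all(diff(r$thresholds$sens) <= 1e-12))
    expect_true(all(diff(r$thresholds$spec) >= -1e-12))
  }
})

test_that("spearman_cor is mid-rank Pearson and transform-invariant", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(spearman_cor(x, x)$r_s, 1)
  expect_equal(spearman_cor(x, -x)$r_s, -1)
  expect_error(spearman_cor(1:3, 1:4), "length")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
  expect_warning(r0 <- spearman_cor(rep(1, 5), 1:5), "zero rank variance")
  expect_true(is.na(r0$r_s))

  set.seed(24)
  for (i in 1:50) {
    n <- sample(4:15, 1)
    a <- sample(1:5, n, replace = TRUE)  # ties
    b <- sample(1:5, n, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    r <- spearman_cor(a, b)$r_s
    expect_equal(r, cor(a, b, method = "spearman"))  # base-R cross-check
    # explicit mid-rank Pearson formula as independent oracle
    ra <- rank(a); rb <- rank(b)
    num <- sum((ra - mean(ra)) * (rb - mean(rb)))
    den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
    expect_equal(r, num / den)
    # invariance under strictly monotone transforms
    expect_equal(spearman_cor(exp(a), b)$r_s, r)
    expect_equal(spearman_cor(a, 2 * b + 1)$r_s, r)
  }
})

test_that("mann_whitney matches exact enumeration and its identities", {
  mw <- mann_whitney(1, 1)
  expect_equal(mw$U, 0.5)
  expect_equal(mw$p, 1)

  sep <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$p, 0.1)  # 2/20 assignments as extreme

  set.seed(25)
  for (i in 1:30) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- sample(1:8, na, replace = TRUE); b <- sample(1:8, nb, replace = TRUE)
    ra <- mann_whitney(a, b); rb <- mann_whitney(b, a)
    expect_equal(ra$U + rb$U, na * nb)
    expect_equal(ra$p, rb$p)
    # cross-check against base R where its exact method applies (no ties)
    if (!any(duplicated(c(a, b)))) {
      w <- wilcox.test(a, b, exact = TRUE)
      expect_equal(ra$U, unname(w$statistic))
    }
  }
  # large samples switch to the tie-corrected normal approximation
  set.seed(26)
  big <- mann_whitney(rnorm(20), rnorm(20) + 1)
  expect_match(big$method, "normal")
  expect_lt(big$p, 0.05)
})

test_that("chi_square is Pearson's statistic on 2x2 tables", {
  prop <- matrix(c(10, 20, 5, 10), 2)  # proportional rows
  r <- chi_square(prop)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_equal(chi_square(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  tab <- matrix(c(12, 5, 3, 9), 2)
  expect_equal(chi_square(tab)$statistic, chi_square(t(tab))$statistic)
  expect_equal(chi_square(tab)$statistic, chi_square(tab[2:1, ])$statistic)
  expect_equal(chi_square(tab)$statistic,
               unname(suppressWarnings(
                 chisq.test(tab, correct = FALSE))$statistic))
  expect_equal(chi_square(tab, correct = TRUE)$statistic,
               unname(suppressWarnings(
                 chisq.test(tab, correct = TRUE))$statistic))
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
})

test_that("evaluate_run assembles a complete, recomputable report", {
  set.seed(27)
  n <- 60
  p_scores <- runif(n)
  tile_preds <- data.frame(
    p_foamy = p_scores,
    predicted_label = ifelse(p_scores >= 0.5, "foamy", "not_foamy"),
    label = sample(c("foamy", "not_foamy"), n, replace = TRUE))
  case_ids <- paste0("c", 1:10)
  case_preds <- data.frame(case_id = case_ids,
                           predicted = rep(c("FN", "control"), 5),
                           disease = rep(c("FN", "control"), each = 5))
  case_scores <- data.frame(case_id = case_ids,
                            mean_zs = c(runif(5, 0.3, 0.8),
                                        runif(5, 0, 0.2)))
  case_records <- data.frame(case_id = case_ids,
                             disease = rep(c("FN", "control"), each = 5),
                             mpvs = c(runif(5, 1, 3), rep(0, 5)),
                             stain = rep(c("HE", "PAS"), 5),
                             sex = sample(c("F", "M"), 10, replace = TRUE))
  rep <- evaluate_run(tile_preds, case_preds = case_preds,
                      case_scores = case_scores,
                      case_records = case_records,
                      n_resamples = 100, seed = 4)
  expect_s3_class(rep, "zebra_report")
  expect_equal(rep$tile$metrics$accuracy,
               mean(tile_preds$predicted_label == tile_preds$label))
  expect_equal(rep$case$metrics$sensitivity,
               mean(case_preds$predicted[case_preds$disease == "FN"] == "FN"))
  expect_false(is.null(rep$roc))
  expect_false(is.null(rep$zs_comparison))
  expect_equal(rep$zs_comparison$mean_fn, mean(case_scores$mean_zs[1:5]))
  expect_true("overall" %in% names(rep$correlation))
  # report values equal independently recomputed ones
  expect_equal(rep$roc$auc, oracle_auc(case_scores$mean_zs,
                                       case_records$disease == "FN"))

  # controls only: ROC absent with an explanatory note
  ctrl <- case_records$disease == "control"
  rep2 <- evaluate_run(tile_preds, case_preds = case_preds[ctrl, ],
                       case_scores = case_scores[ctrl, ],
                       case_records = case_records[ctrl, ],
                       n_resamples = 50, seed = 4)
  expect_null(rep2$roc)
  expect_true(any(grepl("one disease class", rep2$notes)))
})
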
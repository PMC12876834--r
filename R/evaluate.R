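# The statistical protocol: 2x2 classification metrics with percentile
# bootstrap CIs (1,000 resamples), rank-based AUC, ROC/Youden cutoff
# selection, Spearman correlation on mid-ranks, Mann-Whitney U (exact by
# enumeration for small samples) and Pearson chi-square. Undefined ratios
# (zero denominators) propagate as NA, never as 0.

as_binary <- function(x, positive) {
  if (is.logical(x)) return(x)
  x == positive
}

#' Classification metrics from predicted and true labels
#'
#' Computes accuracy, precision, recall, F1, sensitivity, specificity, PPV
#' and NPV from the 2x2 table. Ratios with zero denominator are `NA`.
#'
#' @param predicted,truth aligned label vectors (logical, or character with
#'   `positive` naming the positive class).
#' @param positive positive class label (default `"foamy"`; case-level
#'   vectors typically use `"FN"`).
#' @param level evaluation level tag: `"tile"`, `"glomerulus"` or `"case"`.
#' @return object of class `classification_metrics`.
#' @export
confusion_metrics <- function(predicted, truth, positive = "foamy",
                              level = c("tile", "glomerulus", "case")) {
  level <- match.arg(level)
  if (length(predicted) != length(truth))
    stop("predicted and truth differ in length")
  if (length(predicted) == 0) stop("empty input")
  p <- as_binary(predicted, positive)
  t <- as_binary(truth, positive)
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- rat(tp, tp + fp)
  recall <- rat(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  structure(list(
    accuracy = rat(tp + tn, tp + fp + fn + tn),
    precision = precision, recall = recall, f1 = f1,
    auc_roc = NA_real_,
    sensitivity = recall, specificity = rat(tn, tn + fp),
    ppv = precision, npv = rat(tn, tn + fn),
    tp = tp, fp = fp, fn = fn, tn = tn, level = level),
    class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("Classification metrics (%s level; TP %d FP %d FN %d TN %d)\n",
              x$level, x$tp, x$fp, x$fn, x$tn))
  for (m in c("accuracy", "precision", "recall", "f1", "auc_roc",
              "sensitivity", "specificity", "ppv", "npv"))
    if (!is.na(x[[m]]))
      cat(sprintf("  %-12s %.*f\n", m, digits, x[[m]]))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimate: the probability that a random positive
#' outranks a random negative, ties counted one half.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels logical (or character with `positive`) true labels; both
#'   classes must be present.
#' @param positive positive class label when `labels` is character.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(scores, labels, positive = "foamy") {
  y <- as_binary(labels, positive)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute AUC")
  r <- rank(scores)  # mid-ranks for ties
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for a classification metric
#'
#' Resamples (prediction, label) pairs with replacement `n_resamples` times
#' (default 1,000), recomputes the metric, and returns the empirical 2.5/97.5
#' percentiles. Resamples where the metric is undefined (`NA`) are skipped
#' and counted; more than 50% undefined is an error.
#'
#' @param metric_fn `function(predictions, labels) -> scalar`.
#' @param predictions,labels aligned vectors.
#' @param n_resamples bootstrap resamples (>= 1).
#' @param seed RNG seed for the resampling.
#' @param conf confidence level (default 0.95).
#' @return object of class `bootstrap_ci`: `point`, `lo95`, `hi95`,
#'   `n_resamples`, `n_undefined`, `seed`.
#' @export
bootstrap_ci <- function(metric_fn, predictions, labels,
                         n_resamples = 1000L, seed = 1L, conf = 0.95) {
  n <- length(predictions)
  if (n == 0) stop("empty sample")
  if (length(labels) != n) stop("predictions and labels differ in length")
  point <- metric_fn(predictions, labels)
  vals <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      v <- suppressWarnings(tryCatch(metric_fn(predictions[idx], labels[idx]),
                                     error = function(e) NA_real_))
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  })
  bad <- sum(is.na(vals))
  if (bad > n_resamples / 2)
    stop("metric undefined in ", bad, " of ", n_resamples,
         " bootstrap resamples")
  q <- quantile(vals[!is.na(vals)], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                names = FALSE, type = 7)
  structure(list(point = point, lo95 = q[1], hi95 = q[2],
                 n_resamples = as.integer(n_resamples),
                 n_undefined = bad, seed = as.integer(seed)),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("%.3f [%.3f, %.3f] (%d resamples, %d undefined)\n",
              x$point, x$lo95, x$hi95, x$n_resamples, x$n_undefined))
  invisible(x)
}

#' ROC analysis with Youden-J optimal cutoff
#'
#' Evaluates sensitivity/specificity with the decision rule `score >= t` at
#' every midpoint between adjacent sorted unique scores, picks the cutoff
#' maximizing Youden's J = sensitivity + specificity - 1, ties broken toward
#' the lower cutoff (favouring sensitivity).
#'
#' @inheritParams auc_roc
#' @param positive positive class label (default `"FN"` for case screening).
#' @return object of class `roc_result`: `auc`, `thresholds` (data frame of
#'   threshold/sens/spec), `youden_cutoff`, `youden_sens`, `youden_spec`, `J`.
#' @export
youden_cutoff <- function(scores, labels, positive = "FN") {
  y <- as_binary(labels, positive)
  if (all(y) || !any(y)) stop("both classes must be present")
  u <- sort(unique(scores))
  thr <- if (length(u) == 1) u else (u[-length(u)] + u[-1]) / 2
  sens <- vapply(thr, function(t) mean(scores[y] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!y] < t), numeric(1))
  J <- sens + spec - 1
  best <- which.max(J)  # first maximum = lowest cutoff on ties
  structure(list(auc = auc_roc(scores, y),
                 thresholds = data.frame(threshold = thr, sens = sens,
                                         spec = spec),
                 youden_cutoff = thr[best], youden_sens = sens[best],
                 youden_spec = spec[best], J = J[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f | Youden cutoff %.4g (J %.3f, sens %.3f, spec %.3f)\n",
    x$auc, x$youden_cutoff, x$J, x$youden_sens, x$youden_spec))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties). Zero rank
#' variance in either input yields `NA` with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param stratum optional label carried in the result (e.g. `"H&E"`,
#'   `"female"`).
#' @return object of class `correlation_result`: `r_s`, `n`, `stratum`.
#' @export
spearman_cor <- function(x, y, stratum = NA_character_) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warning("zero rank variance; Spearman correlation undefined")
    rs <- NA_real_
  } else rs <- cor(rx, ry)
  structure(list(r_s = rs, n = length(x), stratum = stratum),
            class = "correlation_result")
}

mw_u_stat <- function(ranks_a, n_a, n_b) {
  sum(ranks_a) - n_a * (n_a + 1) / 2
}

#' Mann-Whitney U test
#'
#' U from rank sums with mid-ranks on ties. Two-sided p-value by exhaustive
#' enumeration of group assignments when `n_a + n_b <= 12` (valid under
#' ties), otherwise by normal approximation with tie correction.
#'
#' @param group_a,group_b numeric vectors (both nonempty).
#' @return list with `U` (statistic of `group_a`), `p` (two-sided) and
#'   `method`.
#' @export
mann_whitney <- function(group_a, group_b) {
  n_a <- length(group_a); n_b <- length(group_b)
  if (n_a == 0 || n_b == 0) stop("both groups must be nonempty")
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  U <- mw_u_stat(r[seq_len(n_a)], n_a, n_b)
  mu <- n_a * n_b / 2
  if (n_a + n_b <= 12) {
    idx <- combn(n_a + n_b, n_a)
    us <- apply(idx, 2, function(ii) mw_u_stat(r[ii], n_a, n_b))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    n <- n_a + n_b
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * (n + 1 - tie_term)
    z <- (U - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(U = U, p = p, method = method)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default (set `correct = TRUE` for Yates).
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @param correct apply Yates continuity correction.
#' @return list with `statistic`, `df` (1) and `p`.
#' @export
chi_square <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal total: chi-square undefined")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  d <- abs(table - E)
  if (correct) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / E)
  list(statistic = stat, df = 1L, p = pchisq(stat, 1, lower.tail = FALSE))
}

# Bootstrap CIs for every defined metric of a prediction/label pair.
metrics_with_cis <- function(predicted, truth, p_scores = NULL,
                             positive = "foamy", level = "tile",
                             n_resamples = 1000L, seed = 1L) {
  cm <- confusion_metrics(predicted, truth, positive = positive,
                          level = level)
  if (!is.null(p_scores))
    cm$auc_roc <- tryCatch(auc_roc(p_scores, truth, positive = positive),
                           error = function(e) NA_real_)
  fns <- list(
    accuracy = function(p, t) confusion_metrics(p, t, positive, level)$accuracy,
    precision = function(p, t) confusion_metrics(p, t, positive, level)$precision,
    recall = function(p, t) confusion_metrics(p, t, positive, level)$recall,
    f1 = function(p, t) confusion_metrics(p, t, positive, level)$f1,
    sensitivity = function(p, t) confusion_metrics(p, t, positive, level)$sensitivity,
    specificity = function(p, t) confusion_metrics(p, t, positive, level)$specificity,
    ppv = function(p, t) confusion_metrics(p, t, positive, level)$ppv,
    npv = function(p, t) confusion_metrics(p, t, positive, level)$npv)
  cis <- list()
  for (m in names(fns)) {
    if (is.na(cm[[m]])) next
    cis[[m]] <- tryCatch(
      bootstrap_ci(fns[[m]], predicted, truth, n_resamples = n_resamples,
                   seed = derive_seed(seed, m)),
      error = function(e) NULL)
  }
  if (!is.na(cm$auc_roc) && !is.null(p_scores)) {
    cis$auc_roc <- tryCatch(
      bootstrap_ci(function(s, t) auc_roc(s, t, positive = positive),
                   p_scores, truth, n_resamples = n_resamples,
                   seed = derive_seed(seed, "auc")),
      error = function(e) NULL)
  }
  list(metrics = cm, cis = cis)
}

#' Full evaluation report
#'
#' Assembles the statistical protocol into one report: classification metrics
#' with bootstrap CIs at tile, glomerulus and case level; ROC/Youden analysis
#' of the case-level mean ZEBRA score; Mann-Whitney comparison of case ZS
#' between disease groups; and Spearman correlation of case ZS with the
#' manual vacuolization score (MPVS), overall and stratified by stain and
#' sex where metadata allow. Strata or sections that cannot be computed are
#' skipped with an explanatory note.
#'
#' @param tile_preds data frame with `predicted_label`, `label`, `p_foamy`.
#' @param region_preds data frame with `predicted_label`, `label` per
#'   glomerulus (optional).
#' @param case_preds data frame with `predicted`, `disease` per case
#'   (optional).
#' @param case_scores data frame with `case_id`, `mean_zs` (optional).
#' @param case_records data frame with `case_id`, `disease` and optionally
#'   `mpvs`, `stain`, `sex` (optional).
#' @param n_resamples bootstrap resamples.
#' @param seed evaluation seed.
#' @return object of class `zebra_report` (JSON-serializable list).
#' @export
evaluate_run <- function(tile_preds, region_preds = NULL, case_preds = NULL,
                         case_scores = NULL, case_records = NULL,
                         n_resamples = 1000L, seed = 1L) {
  notes <- character(0)
  rep <- list()
  rep$counts <- list(n_tiles = NROW(tile_preds),
                     n_regions = NROW(region_preds),
                     n_cases = NROW(case_preds))
  rep$tile <- metrics_with_cis(tile_preds$predicted_label, tile_preds$label,
                               tile_preds$p_foamy, positive = "foamy",
                               level = "tile", n_resamples = n_resamples,
                               seed = derive_seed(seed, "tile"))
  if (!is.null(region_preds))
    rep$glomerulus <- metrics_with_cis(
      region_preds$predicted_label, region_preds$label,
      region_preds$score %||% NULL, positive = "foamy",
      level = "glomerulus", n_resamples = n_resamples,
      seed = derive_seed(seed, "glom"))
  if (!is.null(case_preds))
    rep$case <- metrics_with_cis(
      case_preds$predicted, case_preds$disease, NULL, positive = "FN",
      level = "case", n_resamples = n_resamples,
      seed = derive_seed(seed, "case"))

  if (!is.null(case_scores) && !is.null(case_records)) {
    df <- merge(case_scores, case_records, by = "case_id")
    if (length(unique(df$disease)) < 2) {
      notes <- c(notes, paste(
        "ROC/Youden and group comparison skipped: only one disease class",
        "present among scored cases"))
    } else {
      rep$roc <- youden_cutoff(df$mean_zs, df$disease, positive = "FN")
      mwt <- mann_whitney(df$mean_zs[df$disease == "FN"],
                          df$mean_zs[df$disease == "control"])
      rep$zs_comparison <- list(
        mean_fn = mean(df$mean_zs[df$disease == "FN"]),
        sd_fn = sd(df$mean_zs[df$disease == "FN"]),
        mean_control = mean(df$mean_zs[df$disease == "control"]),
        sd_control = sd(df$mean_zs[df$disease == "control"]),
        mann_whitney = mwt)
    }
    if (!is.null(df$mpvs)) {
      strata <- list(overall = rep(TRUE, nrow(df)))
      if (!is.null(df$stain))
        for (s in unique(df$stain)) strata[[s]] <- df$stain == s
      if (!is.null(df$sex))
        for (s in unique(df$sex)) strata[[s]] <- df$sex == s
      rep$correlation <- list()
      for (nm in names(strata)) {
        sel <- strata[[nm]] & !is.na(df$mpvs)
        if (sum(sel) < 3) {
          notes <- c(notes, paste0("Spearman stratum '", nm,
                                   "' skipped: fewer than 3 cases"))
          next
        }
        rep$correlation[[nm]] <- tryCatch(
          spearman_cor(df$mean_zs[sel], df$mpvs[sel], stratum = nm),
          warning = function(w) {
            structure(list(r_s = NA_real_, n = sum(sel), stratum = nm),
                      class = "correlation_result")
          })
      }
    }
  } else {
    notes <- c(notes,
               "ROC section absent: case scores or case records missing")
  }
  rep$notes <- notes
  structure(rep, class = "zebra_report")
}

#' @export
print.zebra_report <- function(x, ...) {
  cat("== Evaluation report ==\n")
  cat(sprintf("tiles %d | regions %s | cases %s\n", x$counts$n_tiles,
              x$counts$n_regions, x$counts$n_cases))
  for (lev in c("tile", "glomerulus", "case"))
    if (!is.null(x[[lev]])) print(x[[lev]]$metrics)
  if (!is.null(x$roc)) print(x$roc)
  if (!is.null(x$zs_comparison))
    cat(sprintf("case ZS: FN %.3f +/- %.3f vs control %.3f +/- %.3f (MW p=%.3g)\n",
                x$zs_comparison$mean_fn, x$zs_comparison$sd_fn,
                x$zs_comparison$mean_control, x$zs_comparison$sd_control,
                x$zs_comparison$mann_whitney$p))
  if (!is.null(x$correlation))
    for (cc in x$correlation)
      cat(sprintf("Spearman ZS~MPVS [%s]: r_s=%.3f (n=%d)\n",
                  cc$stratum, cc$r_s, cc$n))
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}
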
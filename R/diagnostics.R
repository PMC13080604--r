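#' Screening metrics from binary confusion counts
#'
#' Sensitivity (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)` and F1 `2TP/(2TP+FP+FN)` from confusion-matrix counts.
#' Ratios with a zero denominator are undefined and reported as `NA`, never
#' silently as 0. Vectorized over rows, so a table of confusion matrices
#' (e.g. [study_fixtures()]) pipes straight through.
#'
#' @param data data frame with columns `tp`, `fp`, `fn`, `tn` (one row per
#'   screener), or `NULL` when counts are given directly
#' @param tp,fp,fn,tn counts, used when `data` is `NULL`
#' @return the input tibble with `sensitivity`, `specificity`, `precision`,
#'   `f1`, `accuracy`, `n` appended
#' @export
binary_metrics <- function(data = NULL, tp = NULL, fp = NULL, fn = NULL, tn = NULL) {
  if (is.null(data)) data <- tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn)
  out <- tibble::as_tibble(data)
  stop_if_not(all(c("tp", "fp", "fn", "tn") %in% names(out)),
              "`data` needs tp/fp/fn/tn columns")
  with_counts <- out[c("tp", "fp", "fn", "tn")]
  stop_if_not(all(as.matrix(with_counts) >= 0, na.rm = FALSE),
              "confusion counts must be non-negative")
  n <- out$tp + out$fp + out$fn + out$tn
  stop_if_not(all(n > 0), "empty confusion matrix")
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  dplyr::mutate(out,
                sensitivity = safe_div(.data$tp, .data$tp + .data$fn),
                specificity = safe_div(.data$tn, .data$tn + .data$fp),
                precision   = safe_div(.data$tp, .data$tp + .data$fp),
                f1          = safe_div(2 * .data$tp, 2 * .data$tp + .data$fp + .data$fn),
                accuracy    = (.data$tp + .data$tn) / n,
                n = n)
}

#' Confusion counts from per-subject truth and prediction
#'
#' @param truth,estimate logical (or 0/1) vectors of gold labels and screen
#'   decisions
#' @return one-row tibble of `tp`, `fp`, `fn`, `tn`
#' @export
confusion_counts <- function(truth, estimate) {
  stop_if_not(length(truth) == length(estimate), "truth/estimate lengths differ")
  stop_if_not(is_binary01(truth) && is_binary01(estimate),
              "truth and estimate must be binary (logical or 0/1)")
  truth <- as.logical(truth); estimate <- as.logical(estimate)
  tibble::tibble(tp = sum(truth & estimate), fp = sum(!truth & estimate),
                 fn = sum(truth & !estimate), tn = sum(!truth & !estimate))
}

#' Logical-OR combination of two screeners
#'
#' The combined screen is positive if either component is positive. When
#' subject ids are supplied they must agree element-wise (misaligned subject
#' sets are an error, not silently recycled).
#'
#' @param pred_a,pred_b logical (or 0/1) per-subject decisions
#' @param id_a,id_b optional subject identifiers for alignment checking
#' @return logical vector of combined decisions
#' @export
combine_or <- function(pred_a, pred_b, id_a = NULL, id_b = NULL) {
  stop_if_not(length(pred_a) == length(pred_b), "prediction vectors differ in length")
  if (!is.null(id_a) || !is.null(id_b)) {
    stop_if_not(!is.null(id_a) && !is.null(id_b) && identical(id_a, id_b),
                "subject ids of the two screeners are misaligned")
  }
  stop_if_not(is_binary01(pred_a) && is_binary01(pred_b),
              "predictions must be binary (logical or 0/1)")
  as.logical(pred_a) | as.logical(pred_b)
}

#' Macro-averaged F1 for a K-class confusion matrix
#'
#' Unweighted mean of per-class one-vs-rest F1 scores. A class absent from
#' both the truth margin and the prediction margin contributes F1 = 0 with a
#' warning (the convention keeps the average comparable across runs).
#'
#' @param confusion K x K count matrix, rows = truth, columns = predicted
#' @return list with `macro_f1` and a `per_class` tibble
#' @export
macro_f1 <- function(confusion) {
  stop_if_not(is.matrix(confusion) && nrow(confusion) == ncol(confusion) &&
                nrow(confusion) >= 2, "`confusion` must be a square K x K matrix, K >= 2")
  stop_if_not(sum(confusion) > 0, "empty confusion matrix")
  k <- nrow(confusion)
  per <- purrr::map_dfr(seq_len(k), function(i) {
    tp <- confusion[i, i]
    fn <- sum(confusion[i, ]) - tp
    fp <- sum(confusion[, i]) - tp
    absent <- (tp + fn + fp) == 0
    if (absent)
      warning(sprintf("class %d absent from truth and predictions; F1 set to 0", i),
              call. = FALSE)
    f1 <- if (absent || (2 * tp + fp + fn) == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    tibble::tibble(class = i, tp = tp, fp = fp, fn = fn, f1 = f1, absent = absent)
  })
  list(macro_f1 = mean(per$f1), per_class = per)
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation with ties counted 1/2, plus
#' the full ROC curve evaluated at every observed score cutpoint (decision
#' rule: positive if `score >= cut`).
#'
#' @param scores continuous scores, higher = more case-like
#' @param labels binary gold labels (logical or 0/1)
#' @return a `roc_curve` object: list with `auc`, `n_pos`, `n_neg` and a
#'   `curve` tibble (`threshold`, `sensitivity`, `specificity`)
#' @export
roc_auc <- function(scores, labels) {
  stop_if_not(length(scores) == length(labels), "scores/labels lengths differ")
  stop_if_not(is_binary01(labels), "labels must be binary")
  y <- as.logical(labels)
  stop_if_not(any(y) && any(!y), "both classes must be present")
  stop_if_not(all(is.finite(scores)), "scores must be finite")
  n1 <- sum(y); n0 <- sum(!y)
  r <- rank(scores)                       # midranks handle ties as 1/2
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # operating points at every distinct cutpoint ("positive if score >= cut"),
  # built from cumulative counts over the descending sort
  ord <- order(scores, decreasing = TRUE)
  ss <- scores[ord]; ys <- y[ord]
  last <- cumsum(rle(ss)$lengths)
  curve <- tibble::tibble(
    threshold = c(Inf, ss[last]),
    sensitivity = c(0, cumsum(ys)[last] / n1),
    specificity = c(1, 1 - cumsum(!ys)[last] / n0))
  structure(list(auc = auc, n_pos = n1, n_neg = n0, curve = curve),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.3f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Percentile bootstrap confidence interval
#'
#' 95% (by default) percentile interval from `B` seeded resamples of the
#' rows of `data`, optionally stratified (resampling within the levels of a
#' column -- use the class label for AUC, sensitivity or specificity so both
#' classes survive every resample). A resample on which the statistic is
#' undefined (`NA`) is redrawn; redraws are capped at `10 * B` total draws
#' and reported via the `n_redrawn` attribute.
#'
#' @param data data frame of per-subject rows
#' @param statistic function `data -> numeric scalar`
#' @param B number of bootstrap repetitions (>= 100; studies conventionally
#'   use 1000)
#' @param seed integer seed
#' @param stratify_by optional column name to stratify resampling on
#' @param conf confidence level
#' @return tibble `estimate`, `ci_low`, `ci_high`, `B`; attribute
#'   `n_redrawn`
#' @export
bootstrap_ci <- function(data, statistic, B = 1000, seed = 1,
                         stratify_by = NULL, conf = 0.95) {
  stop_if_not(B >= 100, "`B` must be at least 100")
  stop_if_not(nrow(data) > 0, "`data` is empty")
  withr::local_seed(as.integer(seed))
  groups <- if (is.null(stratify_by)) list(seq_len(nrow(data)))
            else split(seq_len(nrow(data)), data[[stratify_by]])
  draw <- function() {
    idx <- unlist(lapply(groups, function(g) g[sample.int(length(g), length(g),
                                                          replace = TRUE)]))
    statistic(data[idx, , drop = FALSE])
  }
  stats_out <- numeric(B)
  n_draws <- 0L; n_redrawn <- 0L; i <- 1L
  while (i <= B && n_draws < 10L * B) {
    v <- draw(); n_draws <- n_draws + 1L
    if (is.na(v)) { n_redrawn <- n_redrawn + 1L; next }
    stats_out[i] <- v; i <- i + 1L
  }
  stop_if_not(i > B, "statistic undefined on too many resamples (cap reached)")
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(stats_out, c(alpha, 1 - alpha), names = FALSE, type = 7)
  out <- tibble::tibble(estimate = statistic(data), ci_low = qs[1],
                        ci_high = qs[2], B = B)
  attr(out, "n_redrawn") <- n_redrawn
  out
}

#' Decision curve analysis
#'
#' Net benefit of acting on `probs >= pt` across a grid of threshold
#' probabilities: `NB(pt) = TP/n - FP/n * pt/(1-pt)`, with the treat-all and
#' treat-none reference policies. Treat-none is identically 0; treat-all is
#' `prevalence - (1-prevalence) * pt/(1-pt)`.
#'
#' @param probs risk probabilities in [0, 1]
#' @param labels binary outcomes
#' @param pt_grid threshold probabilities, strictly inside (0, 1)
#' @return a `decision_curve` object: tibble `threshold`, `net_benefit`,
#'   `nb_treat_all`, `nb_treat_none`
#' @export
decision_curve <- function(probs, labels, pt_grid = seq(0.05, 0.95, by = 0.05)) {
  stop_if_not(length(pt_grid) > 0, "`pt_grid` is empty")
  stop_if_not(all(pt_grid > 0 & pt_grid < 1), "`pt_grid` must lie strictly in (0, 1)")
  stop_if_not(all(probs >= 0 & probs <= 1), "`probs` must be probabilities")
  stop_if_not(is_binary01(labels), "labels must be binary")
  y <- as.logical(labels); n <- length(y); prev <- mean(y)
  out <- purrr::map_dfr(pt_grid, function(pt) {
    pos <- probs >= pt
    w <- pt / (1 - pt)
    tibble::tibble(threshold = pt,
                   net_benefit = sum(pos & y) / n - sum(pos & !y) / n * w,
                   nb_treat_all = prev - (1 - prev) * w,
                   nb_treat_none = 0)
  })
  class(out) <- c("decision_curve", class(out))
  out
}

#' Relative gain of a combined screener over a single screener
#'
#' Per-metric relative improvement in percent,
#' `(combined - single) / single * 100`. Metrics with an undefined or zero
#' baseline yield `NA` (undefined), never 0.
#'
#' @param metrics_single,metrics_combined one-row tibbles as returned by
#'   [binary_metrics()] (or any one-row data frames sharing metric columns)
#' @param metrics which columns to compare
#' @return tibble `metric`, `single`, `combined`, `gain_pct`
#' @export
gain_report <- function(metrics_single, metrics_combined,
                        metrics = c("f1", "precision", "sensitivity", "specificity")) {
  stop_if_not(nrow(metrics_single) == 1 && nrow(metrics_combined) == 1,
              "gain_report compares one screener against one combination")
  metrics <- intersect(metrics, intersect(names(metrics_single),
                                          names(metrics_combined)))
  stop_if_not(length(metrics) > 0, "no shared metric columns")
  purrr::map_dfr(metrics, function(m) {
    s <- metrics_single[[m]][1]; cmb <- metrics_combined[[m]][1]
    gain <- if (is.na(s) || is.na(cmb) || s == 0) NA_real_ else (cmb - s) / s * 100
    tibble::tibble(metric = m, single = s, combined = cmb, gain_pct = gain)
  })
}
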
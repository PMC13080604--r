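#' Fit a temperature-scaling calibration model
#'
#' Temperature scaling divides the logits by a single positive scalar T and
#' re-applies the sigmoid: `p' = sigmoid(logit(p) / T)`. T is chosen to
#' minimize the negative log-likelihood on the supplied set (1-d bounded
#' optimization of log T). Because the map is strictly monotone for any
#' T > 0, score rankings -- and hence ROC curves and AUC -- are unchanged;
#' only the probability scale moves.
#'
#' @param probs uncalibrated probabilities, clipped to `[1e-6, 1 - 1e-6]`
#'   before the logit transform
#' @param labels binary outcomes; both classes must be present
#' @param interval search interval for T
#' @return a `calibration_model`: list with `temperature`, `nll`
#'   (at the fitted T) and `nll_identity` (at T = 1)
#' @export
fit_temperature <- function(probs, labels, interval = c(0.05, 20)) {
  stop_if_not(length(probs) == length(labels), "probs/labels lengths differ")
  stop_if_not(all(probs > 0 & probs < 1), "`probs` must lie strictly in (0, 1)")
  stop_if_not(is_binary01(labels), "labels must be binary")
  y <- as.numeric(labels)
  stop_if_not(any(y == 1) && any(y == 0),
              "degenerate labels: both classes are required to fit a temperature")
  lg <- stats::qlogis(clip_prob(probs))
  nll <- function(log_t) {
    p <- clip_prob(stats::plogis(lg / exp(log_t)))
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  opt <- stats::optimize(nll, interval = log(interval))
  structure(list(temperature = exp(opt$minimum), nll = opt$objective,
                 nll_identity = nll(0)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> T = %.3f (NLL %.4f, identity NLL %.4f)\n",
              x$temperature, x$nll, x$nll_identity))
  invisible(x)
}

#' Apply temperature scaling to probabilities
#'
#' @param probs probabilities in (0, 1)
#' @param model a [fit_temperature()] result, or a positive scalar T
#' @return calibrated probabilities
#' @export
apply_temperature <- function(probs, model) {
  t_val <- if (inherits(model, "calibration_model")) model$temperature else model
  stop_if_not(is.numeric(t_val) && t_val > 0, "temperature must be a positive scalar")
  stats::plogis(stats::qlogis(clip_prob(probs)) / t_val)
}

#' Youden-index optimal threshold
#'
#' Scans the midpoints between adjacent sorted unique scores and returns the
#' cutpoint maximizing `J = sensitivity + specificity - 1` under the rule
#' "positive if score >= cut". Ties in J break toward the lowest cutpoint.
#'
#' @param scores continuous scores; at least two distinct values
#' @param labels binary gold labels, both classes present
#' @return tibble `threshold`, `j`, `sensitivity`, `specificity`
#' @export
youden_threshold <- function(scores, labels) {
  stop_if_not(length(scores) == length(labels), "scores/labels lengths differ")
  stop_if_not(is_binary01(labels), "labels must be binary")
  y <- as.logical(labels)
  stop_if_not(any(y) && any(!y), "both classes must be present")
  u <- sort(unique(scores))
  stop_if_not(length(u) >= 2, "constant scores: no threshold can be selected")
  cand <- (u[-1] + u[-length(u)]) / 2
  n1 <- sum(y); n0 <- sum(!y)
  j <- vapply(cand, function(ct) {
    pos <- scores >= ct
    sum(pos & y) / n1 + sum(!pos & !y) / n0 - 1
  }, numeric(1))
  # ties (within float tolerance) break toward the lowest cutpoint
  best <- which(j >= max(j) - 1e-12)[1]
  ct <- cand[best]
  pos <- scores >= ct
  tibble::tibble(threshold = ct, j = j[best],
                 sensitivity = sum(pos & y) / n1,
                 specificity = sum(!pos & !y) / n0)
}

#' Tier thresholds from two Youden fits
#'
#' Three-tier risk stratification needs two cutpoints on the calibrated
#' probability; these are obtained by applying the Youden procedure twice
#' against two nested gold binarizations -- "moderate or worse"
#' (severity >= 3) for the lower cut t1 and "severe" (severity >= 4) for the
#' upper cut t2. A fit with t1 >= t2 (non-nested operating points) is an
#' error rather than silently reordered.
#'
#' @param probs calibrated risk probabilities
#' @param severity gold 1-5 severity ratings
#' @return a `tier_thresholds` tibble with `t1 < t2`
#' @export
fit_tier_thresholds <- function(probs, severity) {
  stop_if_not(all(severity %in% 1:5), "severity ratings must be integers in 1..5")
  t1 <- youden_threshold(probs, severity >= 3)$threshold
  t2 <- youden_threshold(probs, severity >= 4)$threshold
  stop_if_not(t1 > 0 && t2 < 1 && t1 < t2,
              "degenerate tier thresholds (t1 = %.3f, t2 = %.3f): need 0 < t1 < t2 < 1",
              t1, t2)
  structure(tibble::tibble(t1 = t1, t2 = t2), class = c("tier_thresholds", "tbl_df",
                                                        "tbl", "data.frame"))
}

#' Assign a three-tier risk level from a calibrated probability
#'
#' Left-closed convention: `p < t1` -> tier 1 (asymptomatic/mild),
#' `t1 <= p < t2` -> tier 2 (moderate), `p >= t2` -> tier 3 (severe).
#'
#' @param p probabilities in [0, 1]
#' @param thresholds a [fit_tier_thresholds()] result or list with `t1 < t2`
#' @return integer vector of tiers 1-3
#' @export
assign_tier <- function(p, thresholds) {
  t1 <- thresholds$t1[1]; t2 <- thresholds$t2[1]
  stop_if_not(is.numeric(t1) && is.numeric(t2) && t1 > 0 && t2 < 1 && t1 < t2,
              "invalid thresholds: need 0 < t1 < t2 < 1")
  stop_if_not(all(p >= 0 & p <= 1), "probabilities must lie in [0, 1]")
  ifelse(p < t1, 1L, ifelse(p < t2, 2L, 3L))
}

#' Brier score
#'
#' Mean squared difference between predicted probability and binary outcome;
#' 0 for perfect probabilities, 0.25 for a constant 0.5.
#'
#' @param probs probabilities in [0, 1]
#' @param labels binary outcomes
#' @return numeric scalar
#' @export
brier_score <- function(probs, labels) {
  stop_if_not(length(probs) > 0, "empty input")
  stop_if_not(length(probs) == length(labels), "probs/labels lengths differ")
  stop_if_not(all(probs >= 0 & probs <= 1), "`probs` must lie in [0, 1]")
  stop_if_not(is_binary01(labels), "labels must be binary")
  mean((probs - as.numeric(labels))^2)
}

#' Reliability (calibration) curve
#'
#' Bins probabilities into `n_bins` equal-width bins on [0, 1] and reports,
#' per non-empty bin, the mean predicted probability and the observed event
#' rate.
#'
#' @param probs probabilities in [0, 1]
#' @param labels binary outcomes
#' @param n_bins number of equal-width bins
#' @return a `calibration_curve` tibble: `bin`, `mean_prob`, `observed_rate`,
#'   `count`
#' @export
calibration_curve <- function(probs, labels, n_bins = 10) {
  stop_if_not(length(probs) > 0, "empty input")
  stop_if_not(all(probs >= 0 & probs <= 1), "`probs` must lie in [0, 1]")
  stop_if_not(is_binary01(labels), "labels must be binary")
  bin <- pmin(n_bins, 1L + floor(probs * n_bins))
  out <- tibble::tibble(bin = bin, prob = probs, y = as.numeric(labels)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_prob = mean(.data$prob),
                     observed_rate = mean(.data$y),
                     count = dplyr::n(), .groups = "drop")
  class(out) <- c("calibration_curve", class(out))
  out
}
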
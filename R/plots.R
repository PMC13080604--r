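#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

map_to_df <- function(map) {
  tibble::tibble(row = rep(seq_len(nrow(map)) - 1L, times = ncol(map)),
                 col = rep(seq_len(ncol(map)) - 1L, each = nrow(map)),
                 value = as.numeric(map))
}

#' Plot an amplitude map
#'
#' @param object an `amplitude_map` from [compute_amplitude_map()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot amplitude_map
#' @export
autoplot.amplitude_map <- function(object, ...) {
  ggplot2::ggplot(map_to_df(object),
                  ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "A(x,y)") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Micro-vibration amplitude map",
                  x = "column (px)", y = "row (px)")
}

#' Plot a dominant-frequency map
#'
#' Undefined pixels (no in-band power) are left blank.
#' @param object a `frequency_map` from [compute_frequency_map()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot frequency_map
#' @export
autoplot.frequency_map <- function(object, ...) {
  ggplot2::ggplot(map_to_df(object),
                  ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "F(x,y) [Hz]", na.value = "grey90",
                                  limits = attr(object, "band")) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Dominant-frequency map",
                  x = "column (px)", y = "row (px)")
}

#' Plot an ROC curve
#'
#' @param object a `roc_curve` from [roc_auc()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("ROC curve (AUC = %.3f)", object$auc),
                  x = "1 - specificity", y = "sensitivity")
}

#' Plot a decision curve
#'
#' Net benefit of the model against the treat-all and treat-none policies.
#' @param object a `decision_curve` from [decision_curve()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot decision_curve
#' @export
autoplot.decision_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("net_benefit", "nb_treat_all", "nb_treat_none"),
                              names_to = "policy", values_to = "nb")
  long$policy <- factor(long$policy,
                        levels = c("net_benefit", "nb_treat_all", "nb_treat_none"),
                        labels = c("model", "treat all", "treat none"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$nb,
                                     colour = .data$policy)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Decision curve analysis",
                  x = "threshold probability", y = "net benefit",
                  colour = NULL)
}

#' Plot a reliability (calibration) curve
#'
#' @param object a `calibration_curve` from [calibration_curve()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$mean_prob, y = .data$observed_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = "Reliability curve",
                  x = "mean predicted probability", y = "observed event rate",
                  size = "n")
}
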
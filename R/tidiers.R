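#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained risk model
#'
#' One row per parameter group with its size and L2 norm -- a compact view
#' of where the model's capacity sits.
#' @param x a `risk_model`
#' @param ... unused
#' @return tibble `component`, `n_parameters`, `l2_norm`
#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) {
  flat_groups <- function(p, prefix) {
    if (is.list(p)) {
      nms <- names(p) %||% as.character(seq_along(p))
      return(purrr::list_rbind(purrr::map2(p, nms, function(el, nm)
        flat_groups(el, paste(prefix, nm, sep = ".")))))
    }
    tibble::tibble(component = sub("^\\.", "", prefix),
                   n_parameters = length(p),
                   l2_norm = sqrt(sum(p^2)))
  }
  flat_groups(x$params, "")
}

#' Glance at a trained risk model
#' @param x a `risk_model`
#' @param ... unused
#' @return one-row tibble with sizes and the first/last training loss
#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, epochs = length(x$loss_history),
                 initial_loss = x$loss_history[1],
                 final_loss = x$loss_history[length(x$loss_history)],
                 d = x$config$d, hidden = x$config$hidden,
                 n_parameters = length(rm_flatten(x$params)))
}

#' Tidy a temperature-scaling model
#' @param x a `calibration_model`
#' @param ... unused
#' @return tibble `term`, `estimate`
#' @method tidy calibration_model
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble::tibble(term = "temperature", estimate = x$temperature)
}

#' Glance at a temperature-scaling model
#' @param x a `calibration_model`
#' @param ... unused
#' @return one-row tibble `temperature`, `nll`, `nll_identity`
#' @method glance calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(temperature = x$temperature, nll = x$nll,
                 nll_identity = x$nll_identity)
}

#' Tidy an ROC curve
#' @param x a `roc_curve`
#' @param ... unused
#' @return the curve tibble (`threshold`, `sensitivity`, `specificity`)
#' @method tidy roc_curve
#' @export
tidy.roc_curve <- function(x, ...) x$curve

#' Glance at an ROC curve
#' @param x a `roc_curve`
#' @param ... unused
#' @return one-row tibble `auc`, `n_pos`, `n_neg`
#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}
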
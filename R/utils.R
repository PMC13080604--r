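# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero to an integer
#'
#' Chinese-norm scale scoring rounds .5 upward (base `round()` rounds half to
#' even, which would send 62.5 to 62).
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @keywords internal
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

# clip probabilities away from {0,1} before a logit transform
clip_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Shannon entropy in bits of a vector of non-negative masses; zero-mass
# entries contribute 0.
shannon_entropy_bits <- function(mass) {
  tot <- sum(mass)
  if (tot <= 0) return(0)
  p <- mass[mass > 0] / tot
  -sum(p * log2(p))
}

is_binary01 <- function(x) {
  (is.numeric(x) || is.logical(x)) && all(x %in% c(0, 1))
}
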
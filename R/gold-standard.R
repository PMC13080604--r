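#' Default diagnostic-keyword severity map
#'
#' The dual-axis quantification maps narrative clinical diagnoses onto 1-5
#' severity levels via severity-defining keywords (5 = most severe / with
#' psychotic features, 1 = subclinical / no obvious pathology). The shipped
#' map is read from the package's YAML resource and can be replaced by any
#' file with the same layout.
#'
#' @param path YAML file; default the packaged resource
#' @return tibble with columns `severity` (integer 1-5) and `keyword`
#' @export
default_keyword_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "severity_keywords.yaml",
                                package = "vibroscreen", mustWork = TRUE)
  raw <- yaml::read_yaml(path)$severity_keywords
  out <- purrr::imap_dfr(raw, function(kws, lvl)
    tibble::tibble(severity = as.integer(lvl), keyword = tolower(as.character(kws))))
  stop_if_not(all(1:5 %in% out$severity),
              "keyword map must cover every severity level 1..5")
  dplyr::arrange(out, dplyr::desc(.data$severity))
}

#' Severity level from a narrative diagnosis
#'
#' Case-insensitive fixed-phrase matching against a keyword map; when several
#' keywords match, the highest severity wins (clinical grading takes the
#' worst finding). Text with no match is graded 1 (subclinical), not an
#' error.
#'
#' @param text character vector of diagnosis strings (non-empty)
#' @param map keyword map tibble, see [default_keyword_map()]
#' @return integer vector of severity levels 1-5
#' @export
severity_from_keywords <- function(text, map = default_keyword_map()) {
  stop_if_not(is.character(text) && all(nzchar(text)),
              "`text` must be non-empty strings")
  lowered <- tolower(text)
  vapply(lowered, function(tx) {
    hits <- map$severity[vapply(map$keyword, grepl, logical(1), x = tx, fixed = TRUE)]
    if (length(hits)) max(hits) else 1L
  }, integer(1), USE.NAMES = FALSE)
}

#' High-risk binarization of a 1-5 severity rating
#'
#' The screening gold standard: positive iff severity >= 3 (moderate or
#' worse).
#' @param severity integer vector in 1..5
#' @return logical vector
#' @export
binarize_high_risk <- function(severity) {
  stop_if_not(all(severity %in% 1:5), "severity ratings must be integers in 1..5")
  severity >= 3
}

#' Three-tier grouping of a 1-5 severity rating
#'
#' Gold-standard tiers: severities 1-2 -> tier 1 (asymptomatic/mild,
#' routine follow-up), 3 -> tier 2 (moderate, adjustment or follow-up
#' needed), 4-5 -> tier 3 (severe, referral to specialty care). By
#' construction `tier >= 2` coincides with [binarize_high_risk()].
#'
#' @param severity integer vector in 1..5
#' @return integer vector of tiers in 1..3
#' @export
to_tier <- function(severity) {
  stop_if_not(all(severity %in% 1:5), "severity ratings must be integers in 1..5")
  ifelse(severity <= 2, 1L, ifelse(severity == 3, 2L, 3L))
}
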
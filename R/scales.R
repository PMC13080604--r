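#' Zung scale definitions (SDS / SAS)
#'
#' Scoring rules for the Self-Rating Depression Scale and Self-Rating
#' Anxiety Scale: 20 items on a 1-4 scale, a subset reverse-keyed
#' (contribution `5 - response`), raw total 20-80, standard score =
#' raw x 1.25 (rounded half-up), and Chinese-norm severity categories.
#' SDS categories: `< 53` none, 53-62 mild, 63-72 moderate-to-severe,
#' `> 72` severe. SAS: `< 50` none, 50-59 mild, 60-69 moderate, `>= 70`
#' severe. The canonical Zung reverse-keyed item sets are the shipped
#' defaults (the reverse set is a convention of the instrument's published
#' form and can be overridden).
#'
#' @param name `"sds"` or `"sas"`
#' @param reverse_items optional integer vector overriding the reverse-keyed
#'   item indices (must stay within 1..20)
#' @return a `scale_definition` list with fields `name`, `n_items`,
#'   `reverse_items`, `multiplier`, `category_cuts`, `categories`
#' @export
scale_definition <- function(name = c("sds", "sas"), reverse_items = NULL) {
  name <- match.arg(tolower(name), c("sds", "sas"))
  def <- switch(name,
    sds = list(name = "sds",
               reverse_items = c(2L, 5L, 6L, 11L, 12L, 14L, 16L, 17L, 18L, 20L),
               category_cuts = c(53L, 63L, 73L),
               categories = c("none", "mild", "moderate_to_severe", "severe")),
    sas = list(name = "sas",
               reverse_items = c(5L, 9L, 13L, 17L, 19L),
               category_cuts = c(50L, 60L, 70L),
               categories = c("none", "mild", "moderate", "severe")))
  if (!is.null(reverse_items)) {
    reverse_items <- sort(unique(as.integer(reverse_items)))
    stop_if_not(all(reverse_items >= 1 & reverse_items <= 20),
                "reverse_items must be indices in 1..20")
    def$reverse_items <- reverse_items
  }
  def$n_items <- 20L
  def$item_range <- c(1L, 4L)
  def$multiplier <- 1.25
  structure(def, class = "scale_definition")
}

#' Score one set of 20 Zung scale responses
#'
#' Reverse-keyed items contribute `5 - response`; the raw total is converted
#' to the standard score by multiplying by 1.25 and rounding half-up
#' (62.5 -> 63); the severity category comes from the definition's
#' Chinese-norm cuts with left-closed intervals.
#'
#' @param items integer vector of exactly 20 responses, each in 1..4
#' @param definition a [scale_definition()]
#' @return tibble: `raw` (20-80), `standard` (rounded), `standard_exact`
#'   (raw x 1.25 unrounded), `category`, `positive` (standard at or above
#'   the first category cut)
#' @export
score_scale <- function(items, definition = scale_definition("sds")) {
  stop_if_not(inherits(definition, "scale_definition"),
              "`definition` must be a scale_definition")
  stop_if_not(length(items) == 20, "expected exactly 20 item responses, got %d",
              length(items))
  bad <- which(is.na(items) | !(items %in% 1:4))
  if (length(bad))
    stop(sprintf("item %s: response missing or outside 1..4",
                 paste(bad, collapse = ", ")), call. = FALSE)
  contrib <- as.integer(items)
  rev <- definition$reverse_items
  contrib[rev] <- 5L - contrib[rev]
  raw <- sum(contrib)
  std_exact <- raw * definition$multiplier
  std <- as.integer(round_half_up(std_exact))
  cat_idx <- findInterval(std, definition$category_cuts) + 1L
  tibble::tibble(raw = raw, standard = std, standard_exact = std_exact,
                 category = definition$categories[cat_idx],
                 positive = std >= definition$category_cuts[1])
}

#' Score a cohort table's SDS and/or SAS item columns
#'
#' Tidy wrapper over [score_scale()]: looks for `sds_item_1..20` and/or
#' `sas_item_1..20` columns and appends `sds_raw`, `sds_standard`,
#' `sds_category`, `sds_positive` (and the `sas_*` analogues).
#'
#' @param data data frame with item columns as produced by
#'   [generate_cohort()]
#' @param scales which scales to score (default both, where columns exist)
#' @return the input as a tibble with scoring columns appended
#' @export
score_scales <- function(data, scales = c("sds", "sas")) {
  out <- tibble::as_tibble(data)
  for (sc in scales) {
    cols <- paste0(sc, "_item_", 1:20)
    if (!all(cols %in% names(out))) next
    def <- scale_definition(sc)
    scored <- purrr::pmap_dfr(out[cols], function(...) score_scale(c(...), def))
    names(scored) <- paste0(sc, "_", names(scored))
    out <- dplyr::bind_cols(out, scored)
  }
  out
}

#' Binary screen decision from a scale result
#'
#' Positive if and only if the standard score is at or above the first
#' severity cut (53 for the SDS, 50 for the SAS).
#'
#' @param standard standard score(s)
#' @param definition a [scale_definition()]
#' @return logical vector
#' @export
scale_positive <- function(standard, definition = scale_definition("sds")) {
  standard >= definition$category_cuts[1]
}
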
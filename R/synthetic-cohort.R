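#' Generate a synthetic screening cohort table
#'
#' Builds a subject table with the statistical structure the screening
#' analysis assumes: gold-standard 1-5 severity ratings on both axes with
#' fixed positive counts at the >= 3 cutoff (fixed-count assignment, not
#' binomial, so prevalences are exact), calibrated-looking AI risk
#' probabilities whose class separation matches `ai_effect_size` standard
#' deviations on the latent scale, and 20-item SDS/SAS responses composed so
#' that the standard-score separation matches `scale_effect_size`. The AI and
#' scale noise terms are correlated at `overlap_rho`, which controls how many
#' cases each instrument detects uniquely.
#'
#' Defaults mirror a 98-outpatient cohort with 73 depression-positive and 52
#' anxiety-positive subjects at the severity >= 3 cutoff.
#'
#' @param n_subjects cohort size
#' @param n_dep_positive,n_anx_positive exact numbers of subjects with
#'   severity >= 3 on each axis
#' @param ai_effect_size standardized separation of the AI latent score
#'   between classes (0 = uninformative screener)
#' @param scale_effect_size standardized separation of the scale standard
#'   score between classes
#' @param overlap_rho correlation of the AI and scale noise terms, in [-1, 1]
#' @param seed integer; fixes all randomness
#' @return tibble with one row per subject: `subject_id`, `dep_severity`,
#'   `anx_severity`, `diagnosis`, `ai_p_dep`, `ai_p_anx`,
#'   `sds_item_1..20`, `sas_item_1..20`
#' @export
generate_cohort <- function(n_subjects = 98, n_dep_positive = 73,
                            n_anx_positive = 52, ai_effect_size = 1.5,
                            scale_effect_size = 1.5, overlap_rho = 0.3,
                            seed = 1) {
  stop_if_not(ai_effect_size >= 0 && scale_effect_size >= 0,
              "effect sizes must be >= 0")
  stop_if_not(abs(overlap_rho) <= 1, "`overlap_rho` must be in [-1, 1]")
  withr::local_seed(as.integer(seed))
  sev <- cohort_severities(n_subjects, n_dep_positive, n_anx_positive)
  km <- default_keyword_map()

  axis_signals <- function(sev_axis, scale_name) {
    pos <- as.integer(sev_axis >= 3)
    # correlated noise pair (ai, scale)
    z1 <- stats::rnorm(n_subjects)
    z2 <- overlap_rho * z1 + sqrt(1 - overlap_rho^2) * stats::rnorm(n_subjects)
    latent_ai <- ai_effect_size * (pos - 0.5) + z1
    p_ai <- stats::plogis(latent_ai)
    def <- scale_definition(scale_name)
    base_mu <- def$category_cuts[1] - 5           # negatives sit below the screen cut
    sd_std <- 8
    std <- base_mu + scale_effect_size * sd_std * pos + sd_std * z2
    raw <- pmin(80, pmax(20, round_half_up(std / def$multiplier)))
    items <- t(vapply(raw, compose_scale_items, integer(20), definition = def))
    list(p_ai = p_ai, items = items)
  }

  dep <- axis_signals(sev$sev_dep, "sds")
  anx <- axis_signals(sev$sev_anx, "sas")

  diagnosis <- vapply(pmax(sev$sev_dep, sev$sev_anx), function(s) {
    kws <- km$keyword[km$severity == s]
    kws[sample.int(length(kws), 1)]
  }, character(1))

  out <- tibble::tibble(subject_id = seq_len(n_subjects),
                        dep_severity = sev$sev_dep, anx_severity = sev$sev_anx,
                        diagnosis = diagnosis,
                        ai_p_dep = dep$p_ai, ai_p_anx = anx$p_ai)
  colnames(dep$items) <- paste0("sds_item_", 1:20)
  colnames(anx$items) <- paste0("sas_item_", 1:20)
  dplyr::bind_cols(out, tibble::as_tibble(dep$items), tibble::as_tibble(anx$items))
}

# Compose 20 item responses (1-4) whose keyed contributions sum to `raw`:
# start every contribution at 1 and scatter the remaining raw - 20 points
# uniformly over items with spare capacity, then undo the reverse keying.
compose_scale_items <- function(raw, definition) {
  stop_if_not(raw >= 20 && raw <= 80, "raw score must be in [20, 80]")
  contrib <- rep(1L, 20)
  left <- raw - 20L
  while (left > 0L) {
    open <- which(contrib < 4L)
    pick <- open[sample.int(length(open), 1)]
    contrib[pick] <- contrib[pick] + 1L
    left <- left - 1L
  }
  resp <- contrib
  resp[definition$reverse_items] <- 5L - contrib[definition$reverse_items]
  resp
}

#' Reference confusion-matrix fixtures for the 98-subject screening study
#'
#' The six binary screening confusion matrices (depression and anxiety; AI
#' screener, Zung scale, and their logical-OR combination) reconstructed from
#' the study's printed counts and rates. Each row carries the matrix counts
#' plus the metric values as printed in the study's comparison tables
#' (`table_f1`, `table_precision`, `table_recall`); for the SDS the printed
#' precision/F1 are inconsistent with the printed false-positive count (14)
#' and specificity (44.0%), so both readings are preserved: compute from
#' counts via [binary_metrics()], or use the `table_*` columns where an
#' analysis is anchored to the printed values.
#'
#' @return tibble with columns `axis` (dep/anx), `instrument` (scale/ai/
#'   combined), `tp`, `fp`, `fn`, `tn`, `table_f1`, `table_precision`,
#'   `table_recall`, `unique_detections` (cases found only by that
#'   instrument, where reported)
#' @export
study_fixtures <- function() {
  tibble::tribble(
    ~axis, ~instrument, ~tp, ~fp, ~fn, ~tn, ~table_f1, ~table_precision, ~table_recall, ~unique_detections,
    "dep", "scale",    61L, 14L, 12L, 11L, 0.813, 0.792, 0.836, 2L,
    "dep", "ai",       70L, 24L,  3L,  1L, 0.838, 0.745, 0.959, 11L,
    "dep", "combined", 72L, 25L,  1L,  0L, 0.847, 0.742, 0.986, NA_integer_,
    "anx", "scale",    24L, 26L, 28L, 20L, 0.471, 0.480, 0.462, 13L,
    "anx", "ai",       23L, 26L, 29L, 20L, 0.455, 0.469, 0.442, 12L,
    "anx", "combined", 36L, 34L, 16L, 12L, 0.590, 0.514, 0.692, NA_integer_)
}
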
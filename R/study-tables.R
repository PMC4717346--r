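#' Reference model-ranking tables from the motivating camera-trap study
#'
#' The published model-selection tables of a two-study-area bobcat-puma
#' camera survey, bundled as plain CSV: for each study area ("WS", the
#' more rural area; "FR", the more urbanized one) the candidate model
#' strings with their printed `K`, `AICc`, `delta_aicc`, Akaike weight
#' and reported log-likelihood column. These printed values are inputs
#' for benchmarking: [akaike_weights()] applied to a `delta_aicc` column
#' should reproduce the printed top-model weight, and
#' [parse_occu_model()] / [parse_two_species_model()] plus the parameter
#' counters should reproduce the printed `K`.
#'
#' Note the broad-scale "WS" weight column is known to be internally
#' inconsistent with its own delta column (the printed weights sum to
#' more than 1); recomputed weights are the authoritative ones there.
#'
#' @param scale `"broad"` (two-species seasonal models) or `"fine"`
#'   (single-species daily models).
#' @return tibble with columns `study_area`, `rank`, `model`, `K`,
#'   `aicc`, `delta_aicc`, `weight`, `log_l`.
#' @export
study_model_rankings <- function(scale = c("broad", "fine")) {
  scale <- match.arg(scale)
  f <- system.file("extdata",
                   paste0(scale, "_scale_rankings.csv"),
                   package = "urbanfelid", mustWork = TRUE)
  readr::read_csv(f, show_col_types = FALSE)
}

#' Reference activity-overlap estimates from the motivating study
#'
#' Published overlap coefficients (with 95% bootstrap confidence
#' intervals) between the two felids' circadian activity patterns, one
#' per study-area x grid. The pairs of intervals are the inputs to
#' [interval_overlap_metrics()].
#'
#' @return tibble with columns `study_area`, `grid`, `delta_hat`,
#'   `ci_low`, `ci_high`.
#' @export
study_activity_overlap <- function() {
  f <- system.file("extdata", "activity_overlap.csv",
                   package = "urbanfelid", mustWork = TRUE)
  readr::read_csv(f, show_col_types = FALSE)
}

#' Reference photo-count summary from the motivating study
#'
#' Published per-grid counts of sites with at least one detection and of
#' independent photographs for each species; the ratio of detected to
#' total sites is the published naive occupancy.
#'
#' @return tibble with columns `study_area`, `species`, `grid_area`,
#'   `n_sites_detected`, `n_photographs`, `n_sites_total`.
#' @export
study_photo_summary <- function() {
  f <- system.file("extdata", "photo_summary.csv",
                   package = "urbanfelid", mustWork = TRUE)
  readr::read_csv(f, show_col_types = FALSE)
}
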
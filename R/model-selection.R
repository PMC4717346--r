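#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 log L + 2K + 2K(K + 1) / (n - K - 1)`. When the correction
#' is undefined (`n <= K + 1`) the plain AIC is returned with a warning.
#'
#' @param neg2loglik `-2 log L` of the fitted model.
#' @param K number of estimated parameters.
#' @param n effective sample size (for site-occupancy models,
#'   conventionally the number of sites).
#' @return the AICc value (scalar, vectorized over its arguments).
#' @export
aicc <- function(neg2loglik, K, n) {
  aic <- neg2loglik + 2 * K
  corr <- ifelse(n > K + 1, 2 * K * (K + 1) / (n - K - 1), NA_real_)
  if (anyNA(corr)) {
    warn_ufl("n <= K + 1: AICc correction undefined, returning plain AIC")
    corr[is.na(corr)] <- 0
  }
  aic + corr
}

#' Akaike weights from AICc differences
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)`. The input may be
#' raw AICc values or differences from the best model; weights are
#' invariant to adding a constant.
#'
#' @param delta numeric vector of AICc values or Delta-AICc values.
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(delta) {
  if (!length(delta)) stop_ufl("empty model set")
  d <- delta - min(delta)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Rank candidate models by AICc
#'
#' Builds the standard model-comparison table: models sorted by AICc with
#' Delta-AICc, Akaike weights and `-2 log L`. Models flagged as excluded
#' (non-convergent or degenerate-dominant fits) are ranked separately and
#' carry no weight. Exact AICc ties are broken by smaller `K`, then label
#' order, and flagged in the `tie` column.
#'
#' @param fits a list of fitted models (each with `$neg2loglik`, `$K`,
#'   `$label` and optionally `$converged` / `$excluded`), or a tibble
#'   with columns `label`, `K`, `neg2loglik` (+ optional `excluded`).
#' @param n effective sample size for AICc (default 40 sites).
#' @return a `model_comparison` tibble with columns `model`, `K`, `AICc`,
#'   `delta_AICc`, `weight`, `neg2loglik`, `tie`; excluded models are
#'   attached as the `"excluded"` attribute.
#' @export
rank_models <- function(fits, n = 40) {
  if (inherits(fits, "data.frame")) {
    tab <- tibble::as_tibble(fits)
    if (!"excluded" %in% names(tab)) tab$excluded <- FALSE
  } else {
    tab <- purrr::map_dfr(fits, function(f) {
      tibble::tibble(
        label = f$label %||% "model",
        K = f$K,
        neg2loglik = f$neg2loglik,
        excluded = isTRUE(f$excluded) || !isTRUE(f$converged %||% TRUE)
      )
    })
  }
  if (nrow(tab) == 0) stop_ufl("empty model set")
  excluded <- tab[tab$excluded, , drop = FALSE]
  tab <- tab[!tab$excluded, , drop = FALSE]
  if (nrow(tab) == 0) stop_ufl("no usable model: all candidates excluded")
  tab$AICc <- aicc(tab$neg2loglik, tab$K, n)
  tab <- dplyr::arrange(tab, .data$AICc, .data$K, .data$label)
  tab$delta_AICc <- tab$AICc - tab$AICc[1]
  tab$weight <- akaike_weights(tab$AICc)
  ties <- duplicated(round(tab$AICc, 8)) |
    duplicated(round(tab$AICc, 8), fromLast = TRUE)
  out <- tibble::tibble(
    model = tab$label, K = tab$K, AICc = tab$AICc,
    delta_AICc = tab$delta_AICc, weight = tab$weight,
    neg2loglik = tab$neg2loglik, tie = ties
  )
  attr(out, "n") <- n
  attr(out, "excluded") <- excluded
  class(out) <- c("model_comparison", class(out))
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (n = %s):\n", attr(x, "n")))
  NextMethod()
  exc <- attr(x, "excluded")
  if (!is.null(exc) && nrow(exc)) {
    cat("Excluded models:", paste(exc$label, collapse = "; "), "\n")
  }
  invisible(x)
}
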
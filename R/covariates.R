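#' Kernel-density human-development covariate
#'
#' Sums a radially decreasing kernel, centred on each human structure
#' point (residence or building), at every camera site. The default
#' kernel is a truncated Gaussian with `sigma = radius / sigma_divisor`
#' and a hard zero beyond `radius`, so influence is greatest directly at
#' a structure and falls to nothing at the chosen radius. Values are
#' additive over structures and are meaningful only relative to one
#' another (the covariate enters models standardized), so no absolute
#' normalization is applied: a structure exactly at a site contributes 1.
#'
#' @param hops tibble of structure coordinates with columns `x`, `y`
#'   (projected metres). May have zero rows.
#' @param sites tibble of camera sites with columns `site_id`, `x`, `y`.
#' @param radius kernel truncation radius in metres (> 0).
#' @param sigma_divisor the Gaussian scale is `radius / sigma_divisor`
#'   (default 3, i.e. the kernel has essentially decayed at the radius).
#' @param kernel `"gaussian"` (default) or `"linear"` (cone to zero at
#'   the radius).
#' @return tibble with columns `site_id`, `hd`.
#' @export
hop_kernel_density <- function(hops, sites, radius, sigma_divisor = 3,
                               kernel = c("gaussian", "linear")) {
  kernel <- match.arg(kernel)
  if (radius <= 0) stop_ufl("radius must be positive")
  hd <- vapply(seq_len(nrow(sites)), function(i) {
    if (nrow(hops) == 0) return(0)
    d <- sqrt((hops$x - sites$x[i])^2 + (hops$y - sites$y[i])^2)
    d <- d[d <= radius]
    if (!length(d)) return(0)
    if (kernel == "gaussian") {
      sum(exp(-d^2 / (2 * (radius / sigma_divisor)^2)))
    } else {
      sum(1 - d / radius)
    }
  }, numeric(1))
  tibble::tibble(site_id = sites$site_id, hd = hd)
}

#' Choose the spatial scale of the development covariate by AICc
#'
#' Fits one univariate detection model per candidate radius (the models
#' must be identical apart from the development column, which the caller
#' rebuilds inside `fitter`) and returns the radius whose model has the
#' lowest AICc. Non-convergent radii are excluded with a warning. Exact
#' AICc ties are broken toward the smallest radius and flagged.
#'
#' @param radii numeric vector of at least two candidate radii (metres).
#' @param fitter function of one argument (a radius) returning a fitted
#'   model with `$neg2loglik`, `$K` and `$converged` elements (e.g. an
#'   `occu_fit`).
#' @param n effective sample size for AICc (default: number of sites of
#'   the first successful fit, else 40).
#' @return list with `radius` (chosen scale), `tie` (logical) and
#'   `table` (tibble: radius, K, AICc, converged), sorted by AICc.
#' @export
select_scale <- function(radii, fitter, n = NULL) {
  if (length(radii) < 2) stop_ufl("need at least two candidate radii")
  fits <- lapply(radii, function(r) tryCatch(fitter(r), error = function(e) NULL))
  rows <- purrr::map2_dfr(fits, radii, function(f, r) {
    if (is.null(f) || !isTRUE(f$converged)) {
      return(tibble::tibble(radius = r, K = NA_integer_, aicc = NA_real_,
                            converged = FALSE))
    }
    nn <- n %||% f$n_sites %||% 40
    tibble::tibble(radius = r, K = f$K, aicc = aicc(f$neg2loglik, f$K, nn),
                   converged = TRUE)
  })
  if (any(!rows$converged)) {
    warn_ufl("excluded ", sum(!rows$converged), " non-convergent radius/radii")
  }
  ok <- rows[rows$converged, , drop = FALSE]
  if (nrow(ok) == 0) stop_ufl("no candidate radius produced a convergent fit")
  ok <- dplyr::arrange(ok, .data$aicc, .data$radius)
  best <- ok$aicc[1]
  tie <- sum(abs(ok$aicc - best) < 1e-8) > 1
  list(radius = ok$radius[1], tie = tie,
       table = dplyr::arrange(rows, .data$aicc))
}

#' Build dominant-species lag covariates P1-P4
#'
#' For each lag length `k`, `Pk[i, t] = 1` if the dominant species was
#' detected at site `i` on any of days `t - k + 1, ..., t`; i.e. the
#' indicator covers the detection day plus `k - 1` following days.
#' Windows from multiple detections union, and windows are truncated at
#' the survey end. `P1` equals the dominant species' daily detection
#' history itself. Days without effort in the dominant history count as
#' no detection for lag construction.
#'
#' @param dominant_history daily `detection_history` of the dominant
#'   species.
#' @param max_lag longest lag (default 4).
#' @return named list of 0/1 site-by-occasion matrices `P1`..`P<max_lag>`.
#' @export
build_lag_covariates <- function(dominant_history, max_lag = 4) {
  stopifnot(inherits(dominant_history, "detection_history"))
  if (!dominant_history$daily) {
    stop_ufl("lag covariates are daily constructs; pass the unpooled history")
  }
  D <- dominant_history$Y
  D[is.na(D)] <- 0
  t <- ncol(D)
  out <- list()
  for (k in seq_len(max_lag)) {
    P <- matrix(0, nrow = nrow(D), ncol = t, dimnames = dimnames(D))
    for (lag in 0:(k - 1)) {
      cols <- seq_len(t - lag)
      P[, cols + lag] <- pmax(P[, cols + lag, drop = FALSE],
                              D[, cols, drop = FALSE])
    }
    out[[paste0("P", k)]] <- P
  }
  out
}

#' Standardize continuous site covariates
#'
#' Centres and scales the named continuous columns to zero mean and unit
#' variance, leaving binary columns untouched, and attaches the transform
#' (per-column mean and sd) as the `"scaling"` attribute so fitted
#' coefficients can be mapped back to the raw scale. Zero-variance
#' columns are left unscaled with a warning.
#'
#' @param table site covariate tibble.
#' @param cols character vector of columns to standardize; defaults to
#'   every numeric column with more than two distinct values.
#' @return the table with standardized columns and a `"scaling"`
#'   attribute (tibble: column, mean, sd).
#' @export
standardize_covariates <- function(table, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(table)[vapply(table, function(x) {
      is.numeric(x) && length(unique(x[!is.na(x)])) > 2
    }, logical(1))]
  }
  scaling <- tibble::tibble(column = character(), mean = numeric(), sd = numeric())
  for (cl in cols) {
    m <- mean(table[[cl]], na.rm = TRUE)
    # population sd: the z-score of {1,2,3} is exactly +/- 1.2247
    s <- sqrt(mean((table[[cl]] - m)^2, na.rm = TRUE))
    if (!is.finite(s) || s == 0) {
      warn_ufl("column '", cl, "' has zero variance; left unscaled")
      next
    }
    table[[cl]] <- (table[[cl]] - m) / s
    scaling <- dplyr::bind_rows(scaling,
                                tibble::tibble(column = cl, mean = m, sd = s))
  }
  attr(table, "scaling") <- scaling
  table
}
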
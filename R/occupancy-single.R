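#' Specify a single-species occupancy model
#'
#' A single-season occupancy model with logit links on occupancy (psi)
#' and detection (p). Occupancy terms name site covariates; detection
#' terms may mix site covariates (e.g. `PumaCount`, `HD`, `G`),
#' occasion-level covariates (`P1`..`P4`, effort `E`) and interactions
#' written as products (`"G*P3"`). Intercepts are implicit.
#'
#' @param p_terms character vector of detection covariate terms (may be
#'   empty for `p(.)`).
#' @param psi_terms character vector of occupancy covariate terms
#'   (default empty: `psi(.)`).
#' @param label optional model label; defaults to the conventional
#'   `"psi(.), p(a + b)"` string.
#' @return an `occu_model_spec`.
#' @export
occu_model_spec <- function(p_terms = character(), psi_terms = character(),
                            label = NULL) {
  lab <- label %||% sprintf(
    "psi(%s), p(%s)",
    if (length(psi_terms)) paste(psi_terms, collapse = " + ") else ".",
    if (length(p_terms)) paste(p_terms, collapse = " + ") else "."
  )
  structure(list(psi_terms = psi_terms, p_terms = p_terms, label = lab),
            class = "occu_model_spec")
}

#' Parse a model string in the conventional table notation
#'
#' Accepts strings such as `"psi(.), p(PumaCount + HD + G + P3 + G*P3)"`.
#'
#' @param string model string.
#' @return an `occu_model_spec`.
#' @export
parse_occu_model <- function(string) {
  s <- gsub("\\s+", "", string)
  m_psi <- regmatches(s, regexec("(?i)psi\\(([^()]*)\\)", s, perl = TRUE))[[1]]
  m_p <- regmatches(s, regexec("(?<![si])p\\(([^()]*)\\)", s, perl = TRUE))[[1]]
  if (length(m_psi) < 2 || length(m_p) < 2) {
    stop_ufl("cannot parse model string: ", string)
  }
  split_terms <- function(x) {
    if (x == "." || x == "") return(character())
    strsplit(x, "+", fixed = TRUE)[[1]]
  }
  occu_model_spec(p_terms = split_terms(m_p[2]),
                  psi_terms = split_terms(m_psi[2]),
                  label = string)
}

#' Number of estimated parameters of an occupancy model
#'
#' One intercept per linear predictor plus one slope per term (main
#' effects and interactions each count once).
#'
#' @param spec an `occu_model_spec`.
#' @return integer `K`.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "occu_model_spec"))
  as.integer(2L + length(spec$psi_terms) + length(spec$p_terms))
}

# Resolve covariate terms into site-by-occasion matrices. Site covariates
# are recycled across occasions; occasion covariates must be matrices
# aligned with the history; "a*b" terms are elementwise products.
resolve_p_terms <- function(terms, history, site_covs, occ_covs) {
  n <- nrow(history$Y)
  t <- ncol(history$Y)
  one <- function(term) {
    if (grepl("*", term, fixed = TRUE)) {
      parts <- strsplit(term, "*", fixed = TRUE)[[1]]
      return(Reduce(`*`, lapply(parts, one)))
    }
    if (!is.null(occ_covs) && term %in% names(occ_covs)) {
      M <- occ_covs[[term]]
      if (!all(dim(M) == c(n, t))) {
        stop_ufl("occasion covariate '", term, "' has wrong dimensions")
      }
      return(M)
    }
    v <- site_cov_vector(term, history, site_covs)
    matrix(v, nrow = n, ncol = t)
  }
  lapply(terms, one)
}

site_cov_vector <- function(term, history, site_covs) {
  if (is.null(site_covs) || !term %in% names(site_covs)) {
    stop_ufl("unknown covariate '", term, "'")
  }
  idx <- match(history$sites, site_covs$site_id)
  if (anyNA(idx)) stop_ufl("site covariate table is missing some sites")
  v <- site_covs[[term]][idx]
  if (anyNA(v) || any(!is.finite(v))) {
    stop_ufl("non-finite values in covariate '", term, "'")
  }
  v
}

#' Negative log-likelihood of a single-species occupancy model
#'
#' The single-season likelihood with imperfect detection: for site `i`
#' with detections `y_it`,
#' `L_i = psi_i * prod_t p_it^y (1 - p_it)^(1 - y) + (1 - psi_i) * I(no detection)`,
#' with missing occasions (no effort) contributing no factor.
#' Parameters are on the logit scale, occupancy block first.
#'
#' @param par parameter vector: psi intercept (+ psi slopes), then p
#'   intercept (+ p slopes), in the order of `spec` terms.
#' @param history a `detection_history`.
#' @param spec an `occu_model_spec`.
#' @param site_covs tibble of site covariates keyed by `site_id`.
#' @param occ_covs named list of site-by-occasion covariate matrices.
#' @return the negative log-likelihood (scalar).
#' @export
occu_negloglik <- function(par, history, spec, site_covs = NULL,
                           occ_covs = NULL) {
  K <- count_parameters(spec)
  if (length(par) != K) stop_ufl("expected ", K, " parameters, got ", length(par))
  pieces <- occu_design(history, spec, site_covs, occ_covs)
  occu_negloglik_core(par, pieces)
}

occu_design <- function(history, spec, site_covs, occ_covs) {
  n <- nrow(history$Y)
  Xpsi <- cbind(rep(1, n))
  for (term in spec$psi_terms) {
    Xpsi <- cbind(Xpsi, site_cov_vector(term, history, site_covs))
  }
  p_mats <- c(list(matrix(1, n, ncol(history$Y))),
              resolve_p_terms(spec$p_terms, history, site_covs, occ_covs))
  list(Y = history$Y, Xpsi = Xpsi, p_mats = p_mats,
       n_psi = ncol(Xpsi), n_p = length(p_mats))
}

occu_negloglik_core <- function(par, d) {
  b_psi <- par[seq_len(d$n_psi)]
  b_p <- par[d$n_psi + seq_len(d$n_p)]
  psi <- inv_logit(drop(d$Xpsi %*% b_psi))
  lp <- Reduce(`+`, Map(function(M, b) M * b, d$p_mats, as.list(b_p)))
  obs <- !is.na(d$Y)
  # per-site detection log-likelihood, conditional on presence
  ll_mat <- matrix(0, nrow(d$Y), ncol(d$Y))
  y <- d$Y[obs]
  l <- lp[obs]
  ll_mat[obs] <- y * stats::plogis(l, log.p = TRUE) +
    (1 - y) * stats::plogis(-l, log.p = TRUE)
  ll_det <- rowSums(ll_mat)
  never <- rowSums(d$Y == 1, na.rm = TRUE) == 0
  li <- psi * exp(ll_det) + (1 - psi) * never
  -sum(log(pmax(li, 1e-300)))
}

#' Fit a single-species occupancy model by maximum likelihood
#'
#' Minimizes [occu_negloglik()] by quasi-Newton (BFGS) from multiple
#' jittered starts and reports coefficients, standard errors from the
#' inverse observed information, `-2 log L` and `K`. A boundary flag is
#' set when the occupancy estimate is pushed against 1 (saturated data),
#' where the information matrix is unreliable.
#'
#' @inheritParams occu_negloglik
#' @param n_starts number of optimizer starts (first at zero, the rest
#'   jittered; default 5).
#' @param start_sd jitter standard deviation for the extra starts.
#' @return an `occu_fit` object; see [tidy.occu_fit()] and
#'   [glance.occu_fit()].
#' @export
fit_occupancy <- function(history, spec, site_covs = NULL, occ_covs = NULL,
                          n_starts = 5, start_sd = 0.5) {
  if (sum(history$Y == 1, na.rm = TRUE) == 0) {
    stop_ufl("no detections in the data; occupancy is not estimable")
  }
  d <- occu_design(history, spec, site_covs, occ_covs)
  K <- d$n_psi + d$n_p
  starts <- with_private_seed(760541, {
    s <- replicate(max(0, n_starts - 1), stats::rnorm(K, 0, start_sd),
                   simplify = FALSE)
    c(list(rep(0, K)), s)
  })
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, occu_negloglik_core, d = d, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, spec = spec, K = K,
                          label = spec$label,
                          diagnostics = "all optimizer starts failed"),
                     class = "occu_fit"))
  }
  H <- tryCatch(
    stats::optimHess(best$par, occu_negloglik_core, d = d),
    error = function(e) NULL)
  vc <- NULL
  pd <- FALSE
  if (!is.null(H)) {
    ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) NA)
    pd <- all(is.finite(ev)) && all(ev > 1e-8)
    if (pd) vc <- solve(H)
  }
  beta <- best$par
  names(beta) <- c(paste0("psi_", c("(Intercept)", spec$psi_terms)),
                   paste0("p_", c("(Intercept)", spec$p_terms)))
  psi_hat <- inv_logit(beta[1])
  boundary <- psi_hat > 0.99 || max(abs(beta)) > 15
  structure(list(
    beta = beta,
    se = if (!is.null(vc)) sqrt(pmax(diag(vc), 0)) else rep(NA_real_, K),
    vcov = vc,
    psi_hat = unname(psi_hat),
    p_hat = unname(inv_logit(beta[d$n_psi + 1])),
    neg2loglik = 2 * best$value,
    K = K,
    n_sites = nrow(history$Y),
    converged = best$convergence == 0 && (pd || boundary),
    boundary = boundary,
    spec = spec,
    label = spec$label,
    n_psi = d$n_psi
  ), class = "occu_fit")
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("Single-species occupancy fit:", x$label, "\n")
  if (!isTRUE(x$converged)) cat("  (not converged)\n")
  if (isTRUE(x$boundary)) cat("  (boundary estimate: psi ~ 1)\n")
  cat(sprintf("  psi-hat = %.3f, -2logL = %.2f, K = %d\n",
              x$psi_hat %||% NA, x$neg2loglik %||% NA, x$K))
  invisible(x)
}

#' Tidy method for occupancy fits
#'
#' @param x an `occu_fit`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error` (logit scale).
#' @method tidy occu_fit
#' @export
tidy.occu_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta),
                 std.error = unname(x$se))
}

#' Glance method for occupancy fits
#'
#' @param x an `occu_fit`.
#' @param ... unused.
#' @return one-row tibble with fit summaries.
#' @method glance occu_fit
#' @export
glance.occu_fit <- function(x, ...) {
  tibble::tibble(K = x$K, neg2loglik = x$neg2loglik,
                 AICc = aicc(x$neg2loglik, x$K, x$n_sites),
                 psi_hat = x$psi_hat, converged = x$converged,
                 boundary = x$boundary)
}

#' Predict detection probability with a delta-method interval
#'
#' Evaluates the fitted detection probability at covariate profiles. The
#' confidence interval is computed on the logit scale by the delta method
#' and back-transformed, so it stays inside (0, 1). Interaction terms are
#' formed from the named main-effect columns of `newdata`.
#'
#' @param fit a converged `occu_fit`.
#' @param newdata tibble of covariate values, one column per main effect
#'   appearing in the detection formula.
#' @param level confidence level (default 0.95).
#' @return `newdata` with columns `p`, `conf.low`, `conf.high` appended.
#' @export
predict_detection <- function(fit, newdata, level = 0.95) {
  if (!isTRUE(fit$converged)) stop_ufl("fit has not converged")
  terms <- fit$spec$p_terms
  term_col <- function(term) {
    if (grepl("*", term, fixed = TRUE)) {
      parts <- strsplit(term, "*", fixed = TRUE)[[1]]
      return(Reduce(`*`, lapply(parts, term_col)))
    }
    if (!term %in% names(newdata)) stop_ufl("newdata lacks covariate '", term, "'")
    newdata[[term]]
  }
  X <- cbind(1, do.call(cbind, c(list(NULL), lapply(terms, term_col))))
  idx <- fit$n_psi + seq_len(1 + length(terms))
  lp <- drop(X %*% fit$beta[idx])
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (!is.null(fit$vcov)) {
    se_lp <- sqrt(pmax(rowSums((X %*% fit$vcov[idx, idx]) * X), 0))
  } else {
    se_lp <- rep(NA_real_, length(lp))
  }
  dplyr::mutate(tibble::as_tibble(newdata),
                p = inv_logit(lp),
                conf.low = inv_logit(lp - z * se_lp),
                conf.high = inv_logit(lp + z * se_lp))
}

#' Plot fitted detection probability against one covariate
#'
#' @param object a converged `occu_fit`.
#' @param covariate name of the covariate to vary.
#' @param newdata tibble of profiles (output of [predict_detection()] is
#'   recomputed internally); other covariates held at 0.
#' @param range numeric length-2 range for the varied covariate.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot occu_fit
#' @export
autoplot.occu_fit <- function(object, covariate, range = c(0, 8),
                              newdata = NULL, ...) {
  main_effects <- unique(unlist(strsplit(object$spec$p_terms, "*", fixed = TRUE)))
  if (is.null(newdata)) {
    newdata <- tibble::as_tibble(stats::setNames(
      as.list(rep(0, length(main_effects))), main_effects))
    newdata <- newdata[rep(1, 101), , drop = FALSE]
    newdata[[covariate]] <- seq(range[1], range[2], length.out = 101)
  }
  pred <- predict_detection(object, newdata)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data[[covariate]], y = .data$p)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "daily detection probability") +
    ggplot2::theme_minimal()
}
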
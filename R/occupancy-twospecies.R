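#' Specify a conditional two-species occupancy model
#'
#' The conditional parameterization for a dominant species A and a
#' subordinate species B uses eight parameters: `psiA` (occupancy of A),
#' `psiBA` / `psiBa` (occupancy of B given A present / absent), `pA`
#' (detection of A when B is absent), `rA` (detection of A when both are
#' present), `pB` (detection of B when A is absent) and `rBA` / `rBa`
#' (detection of B when both are present and A was / was not detected
#' that occasion). Constraint sets tie parameters together:
#'
#' * `occ = "shared"`: `psiBA = psiBa` (B's occupancy ignores A);
#'   `"conditional"`: both estimated.
#' * `det = "shared"`: `pB = rBA = rBa`; `"conditional"`: `pB` free with
#'   `rBA = rBa`; `"full"`: all three free.
#'
#' Detection parameters can be covariate-linked on the logit scale;
#' covariates are shared (one slope set) within an equality group and
#' separate across groups.
#'
#' @param occ occupancy constraint for species B.
#' @param det detection constraint for species B.
#' @param detA detection constraint for species A: `"free"` (separate
#'   `pA`, `rA`, the usual case) or `"shared"` (`pA = rA`; with `occ` and
#'   `det` also shared, the joint likelihood factors exactly into two
#'   independent single-species likelihoods).
#' @param covsA character vector of covariate terms on `pA` and `rA`
#'   (each gets its own intercept and slopes).
#' @param covsB character vector of covariate terms on the B detection
#'   group(s).
#' @param label optional model label in the conventional notation.
#' @return a `two_species_spec`.
#' @export
two_species_spec <- function(occ = c("shared", "conditional"),
                             det = c("shared", "conditional", "full"),
                             detA = c("free", "shared"),
                             covsA = character(), covsB = character(),
                             label = NULL) {
  occ <- match.arg(occ)
  det <- match.arg(det)
  detA <- match.arg(detA)
  occ_groups <- if (occ == "shared") {
    list(list(names = "psiA", covs = character()),
         list(names = c("psiBA", "psiBa"), covs = character()))
  } else {
    list(list(names = "psiA", covs = character()),
         list(names = "psiBA", covs = character()),
         list(names = "psiBa", covs = character()))
  }
  b_groups <- switch(det,
    shared = list(list(names = c("pB", "rBA", "rBa"), covs = covsB)),
    conditional = list(list(names = "pB", covs = covsB),
                       list(names = c("rBA", "rBa"), covs = covsB)),
    full = list(list(names = "pB", covs = covsB),
                list(names = "rBA", covs = covsB),
                list(names = "rBa", covs = covsB))
  )
  a_groups <- if (detA == "shared") {
    list(list(names = c("pA", "rA"), covs = covsA))
  } else {
    list(list(names = "pA", covs = covsA),
         list(names = "rA", covs = covsA))
  }
  det_groups <- c(a_groups, b_groups)
  new_two_species_spec(occ_groups, det_groups, occ, det, label)
}

new_two_species_spec <- function(occ_groups, det_groups, occ, det, label) {
  lab <- label %||% two_species_label(occ_groups, det_groups)
  structure(list(occ_groups = occ_groups, det_groups = det_groups,
                 occ = occ, det = det, label = lab),
            class = "two_species_spec")
}

two_species_label <- function(occ_groups, det_groups) {
  fmt <- function(g) {
    core <- paste(g$names, collapse = "=")
    if (length(g$covs)) core <- paste0(core, "(", paste(g$covs, collapse = "+"), ")")
    if (length(g$names) > 1) core <- paste0("(", core, ")")
    core
  }
  paste(c(vapply(occ_groups, fmt, character(1)),
          vapply(det_groups, fmt, character(1))), collapse = ", ")
}

#' Parse a two-species model string
#'
#' Accepts the conventional table notation in ASCII, e.g.
#' `"psiA, (psiBA=psiBa), pA(E), rA(E), (pB=rBA=rBa(G+HD+E))"`. Each
#' comma-separated token is a parameter or a parenthesized equality
#' group, optionally carrying a covariate list in trailing parentheses.
#'
#' @param string model string.
#' @return a `two_species_spec`.
#' @export
parse_two_species_model <- function(string) {
  s <- gsub("\\s+", "", string)
  tokens <- split_top_level(s)
  groups <- lapply(tokens, function(tok) {
    if (startsWith(tok, "(") && endsWith(tok, ")")) {
      tok <- substr(tok, 2, nchar(tok) - 1)
    }
    covs <- character()
    m <- regexec("^([^()]*)\\(([^()]*)\\)$", tok)[[1]]
    if (m[1] != -1) {
      parts <- regmatches(gsub("\\s", "", tok),
                          regexec("^([^()]*)\\(([^()]*)\\)$", tok))[[1]]
      tok <- parts[2]
      covs <- strsplit(parts[3], "+", fixed = TRUE)[[1]]
    }
    list(names = strsplit(tok, "=", fixed = TRUE)[[1]], covs = covs)
  })
  is_occ <- vapply(groups, function(g) any(grepl("^psi", g$names)), logical(1))
  occ_groups <- groups[is_occ]
  det_groups <- groups[!is_occ]
  occ <- if (any(vapply(occ_groups, function(g) length(g$names) > 1, logical(1))))
    "shared" else "conditional"
  b_names <- lapply(det_groups, function(g) g$names)
  det <- if (any(vapply(b_names, function(nm) all(c("pB", "rBA", "rBa") %in% nm),
                        logical(1)))) {
    "shared"
  } else if (any(vapply(b_names, function(nm) setequal(nm, c("rBA", "rBa")),
                        logical(1)))) {
    "conditional"
  } else "full"
  new_two_species_spec(occ_groups, det_groups, occ, det, label = string)
}

split_top_level <- function(s) {
  depth <- 0
  cuts <- integer()
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") depth <- depth - 1
    if (chars[i] == "," && depth == 0) cuts <- c(cuts, i)
  }
  starts <- c(1, cuts + 1)
  ends <- c(cuts - 1, nchar(s))
  vapply(seq_along(starts), function(j) substr(s, starts[j], ends[j]),
         character(1))
}

#' Number of estimated parameters of a two-species model
#'
#' One parameter per occupancy group, and one intercept plus one slope
#' per covariate for each detection group.
#'
#' @param spec a `two_species_spec`.
#' @return integer `K`.
#' @export
count_parameters_two_species <- function(spec) {
  stopifnot(inherits(spec, "two_species_spec"))
  k_occ <- length(spec$occ_groups)
  k_det <- sum(vapply(spec$det_groups, function(g) 1L + length(g$covs),
                      integer(1)))
  as.integer(k_occ + k_det)
}

#' Joint likelihood of one site's paired detection history
#'
#' Sums the four latent joint states (both present, A only, B only,
#' neither) weighted by the conditional occupancy probabilities, with the
#' occasion-level detection kernel: when both species are present, B's
#' detection probability is `rBA` on occasions where A was detected and
#' `rBa` where A was not. Probability-scale parameters, no covariates —
#' this is the constant-parameter kernel the fitter generalizes.
#'
#' @param params named list or vector with elements `psiA`, `psiBA`,
#'   `psiBa`, `pA`, `rA`, `pB`, `rBA`, `rBa` (probabilities).
#' @param a,b 0/1 detection vectors of species A and B over occasions
#'   (NA cells are skipped in both).
#' @return the probability of the observed pair of histories.
#' @export
two_species_site_likelihood <- function(params, a, b) {
  if (length(a) != length(b)) stop_ufl("history vectors differ in length")
  q <- as.list(params)
  obs <- !is.na(a) & !is.na(b)
  a <- a[obs]; b <- b[obs]
  bern <- function(p, y) prod(p^y * (1 - p)^(1 - y))
  f_both <- prod(
    ifelse(a == 1, q$rA, 1 - q$rA) *
      ifelse(a == 1,
             ifelse(b == 1, q$rBA, 1 - q$rBA),
             ifelse(b == 1, q$rBa, 1 - q$rBa))
  )
  f_Aonly <- if (all(b == 0)) bern(q$pA, a) else 0
  f_Bonly <- if (all(a == 0)) bern(q$pB, b) else 0
  f_none <- as.numeric(all(a == 0) && all(b == 0))
  q$psiA * q$psiBA * f_both +
    q$psiA * (1 - q$psiBA) * f_Aonly +
    (1 - q$psiA) * q$psiBa * f_Bonly +
    (1 - q$psiA) * (1 - q$psiBa) * f_none
}

ts_design <- function(spec, historyA, historyB, site_covs, occ_covs) {
  if (!identical(dim(historyA$Y), dim(historyB$Y))) {
    stop_ufl("the two species' histories must share sites and occasions")
  }
  mats <- lapply(spec$det_groups, function(g) {
    resolve_p_terms(g$covs, historyA, site_covs, occ_covs)
  })
  obs <- !is.na(historyA$Y) & !is.na(historyB$Y)
  list(YA = historyA$Y, YB = historyB$Y, obs = obs,
       det_mats = mats, spec = spec,
       n_occ = length(spec$occ_groups),
       k_det = vapply(spec$det_groups, function(g) 1L + length(g$covs),
                      integer(1)))
}

ts_negloglik_core <- function(par, d) {
  n <- nrow(d$YA); t <- ncol(d$YA)
  occ_p <- inv_logit(par[seq_len(d$n_occ)])
  if (d$spec$occ == "shared") {
    psiA <- occ_p[1]; psiBA <- occ_p[2]; psiBa <- occ_p[2]
  } else {
    psiA <- occ_p[1]; psiBA <- occ_p[2]; psiBa <- occ_p[3]
  }
  # linear predictors per detection group -> probability matrices
  offset <- d$n_occ
  probs <- list()
  for (gi in seq_along(d$spec$det_groups)) {
    k <- d$k_det[gi]
    bg <- par[offset + seq_len(k)]
    offset <- offset + k
    lp <- matrix(bg[1], n, t)
    mats <- d$det_mats[[gi]]
    for (j in seq_along(mats)) lp <- lp + bg[1 + j] * mats[[j]]
    P <- inv_logit(lp)
    for (nm in d$spec$det_groups[[gi]]$names) probs[[nm]] <- P
  }
  obs <- d$obs
  A <- d$YA; B <- d$YB
  A0 <- A; A0[!obs] <- 0
  B0 <- B; B0[!obs] <- 0

  lg <- function(P, Y) {
    M <- matrix(0, n, t)
    M[obs] <- ifelse(Y[obs] == 1, log(P[obs]), log1p(-P[obs]))
    rowSums(M)
  }
  # both present: A detected w.p. rA; B w.p. rBA (A detected) / rBa (not)
  ll_A_both <- lg(probs$rA, A)
  PB_both <- probs$rBA * (A0 == 1) + probs$rBa * (A0 == 0)
  ll_B_both <- lg(PB_both, B)
  l_both <- exp(ll_A_both + ll_B_both)

  a_none <- rowSums(A0) == 0
  b_none <- rowSums(B0) == 0
  l_Aonly <- exp(lg(probs$pA, A)) * b_none
  l_Bonly <- exp(lg(probs$pB, B)) * a_none
  l_none <- as.numeric(a_none & b_none)

  li <- psiA * psiBA * l_both +
    psiA * (1 - psiBA) * l_Aonly +
    (1 - psiA) * psiBa * l_Bonly +
    (1 - psiA) * (1 - psiBa) * l_none
  -sum(log(pmax(li, 1e-300)))
}

#' Negative log-likelihood of a two-species occupancy model
#'
#' @param par parameter vector on the logit scale: occupancy groups
#'   first (`psiA`, then B's occupancy group(s)), then detection groups
#'   in specification order (`pA`, `rA`, then B's group(s)), each as
#'   intercept followed by covariate slopes.
#' @param historyA,historyB pooled detection histories of the dominant
#'   and subordinate species on identical sites and occasions.
#' @param spec a `two_species_spec`.
#' @param site_covs,occ_covs covariate tables as in [occu_negloglik()].
#' @return the negative log-likelihood.
#' @export
two_species_negloglik <- function(par, historyA, historyB, spec,
                                  site_covs = NULL, occ_covs = NULL) {
  d <- ts_design(spec, historyA, historyB, site_covs, occ_covs)
  K <- count_parameters_two_species(spec)
  if (length(par) != K) stop_ufl("expected ", K, " parameters, got ", length(par))
  ts_negloglik_core(par, d)
}

#' Fit a conditional two-species occupancy model
#'
#' Maximum likelihood over the free parameters implied by the constraint
#' set, using BFGS from multiple jittered starts. The fit records a
#' degenerate-dominant flag ([detect_degenerate_dominant()]) when the
#' dominant species' occupancy estimate sits on the boundary, the
#' documented failure mode of conditional-detection models.
#'
#' @inheritParams two_species_negloglik
#' @param n_starts number of optimizer starts (default 5).
#' @param start_sd jitter standard deviation for the extra starts.
#' @return a `two_species_fit`.
#' @export
fit_two_species <- function(historyA, historyB, spec, site_covs = NULL,
                            occ_covs = NULL, n_starts = 5, start_sd = 0.5) {
  d <- ts_design(spec, historyA, historyB, site_covs, occ_covs)
  K <- count_parameters_two_species(spec)
  starts <- with_private_seed(318229, {
    s <- replicate(max(0, n_starts - 1), stats::rnorm(K, 0, start_sd),
                   simplify = FALSE)
    c(list(rep(0, K)), s)
  })
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, ts_negloglik_core, d = d, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, excluded = TRUE, spec = spec,
                          K = K, label = spec$label,
                          diagnostics = "all optimizer starts failed"),
                     class = "two_species_fit"))
  }
  H <- tryCatch(stats::optimHess(best$par, ts_negloglik_core, d = d),
                error = function(e) NULL)
  vc <- NULL; pd <- FALSE
  if (!is.null(H)) {
    ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) NA)
    pd <- all(is.finite(ev)) && all(ev > 1e-8)
    if (pd) vc <- solve(H)
  }
  par_names <- c(
    vapply(spec$occ_groups, function(g) paste(g$names, collapse = "="),
           character(1)),
    unlist(lapply(spec$det_groups, function(g) {
      base <- paste(g$names, collapse = "=")
      c(paste0(base, "_(Intercept)"),
        if (length(g$covs)) paste0(base, "_", g$covs))
    }))
  )
  beta <- stats::setNames(best$par, par_names)
  occ_hat <- inv_logit(best$par[seq_len(d$n_occ)])
  psiA_hat <- unname(occ_hat[1])
  psiB_hat <- if (spec$occ == "shared") {
    c(psiBA = unname(occ_hat[2]), psiBa = unname(occ_hat[2]))
  } else {
    c(psiBA = unname(occ_hat[2]), psiBa = unname(occ_hat[3]))
  }
  fit <- structure(list(
    beta = beta,
    se = if (!is.null(vc)) sqrt(pmax(diag(vc), 0)) else rep(NA_real_, K),
    vcov = vc,
    psiA_hat = psiA_hat,
    psiB_hat = psiB_hat,
    neg2loglik = 2 * best$value,
    K = K,
    n_sites = nrow(historyA$Y),
    converged = best$convergence == 0,
    hessian_pd = pd,
    spec = spec,
    label = spec$label
  ), class = "two_species_fit")
  fit$degenerate <- detect_degenerate_dominant(fit)
  fit$excluded <- fit$degenerate && spec$det != "shared"
  fit
}

#' Flag a degenerate dominant-species estimate
#'
#' Conditional-detection two-species models are not identifiable when the
#' dominant species' occupancy estimate reaches the boundary (psiA ~ 1):
#' sites that A "does not occupy" vanish from the data, so `pB` has no
#' information. The flag is set when the estimate exceeds `threshold` or
#' the observed information is singular, and such models are excluded
#' from ranking by [rank_models()] via their `excluded` field.
#'
#' @param fit a `two_species_fit`.
#' @param threshold boundary threshold for `psiA` (default 0.99).
#' @return logical flag.
#' @export
detect_degenerate_dominant <- function(fit, threshold = 0.99) {
  if (!isTRUE(fit$converged)) return(TRUE)
  isTRUE(fit$psiA_hat > threshold) || !isTRUE(fit$hessian_pd)
}

#' @export
print.two_species_fit <- function(x, ...) {
  cat("Two-species occupancy fit:", x$label, "\n")
  if (!isTRUE(x$converged)) cat("  (not converged)\n")
  if (isTRUE(x$degenerate)) cat("  (degenerate dominant: psiA ~ 1 or singular information)\n")
  cat(sprintf("  psiA = %.3f, psiBA = %.3f, psiBa = %.3f, -2logL = %.2f, K = %d\n",
              x$psiA_hat %||% NA, x$psiB_hat[["psiBA"]] %||% NA,
              x$psiB_hat[["psiBa"]] %||% NA, x$neg2loglik %||% NA, x$K))
  invisible(x)
}

#' Tidy method for two-species fits
#'
#' @param x a `two_species_fit`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error` (logit scale).
#' @method tidy two_species_fit
#' @export
tidy.two_species_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta),
                 std.error = unname(x$se))
}

#' Glance method for two-species fits
#'
#' @param x a `two_species_fit`.
#' @param ... unused.
#' @return one-row tibble with fit summaries.
#' @method glance two_species_fit
#' @export
glance.two_species_fit <- function(x, ...) {
  tibble::tibble(K = x$K, neg2loglik = x$neg2loglik,
                 AICc = aicc(x$neg2loglik, x$K, x$n_sites),
                 psiA_hat = x$psiA_hat,
                 psiBA_hat = x$psiB_hat[["psiBA"]],
                 psiBa_hat = x$psiB_hat[["psiBa"]],
                 converged = x$converged, degenerate = x$degenerate)
}
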
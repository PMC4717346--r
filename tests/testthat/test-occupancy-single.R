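test_that("the likelihood matches closed forms on one site", {
  spec <- occu_model_spec()
  h10 <- make_history(matrix(c(1, 0), 1, 2))
  # psi = p = 0.5: L = 0.5 * 0.5 * 0.5
  expect_equal(occu_negloglik(c(0, 0), h10, spec), -log(0.125))
  h00 <- make_history(matrix(c(0, 0), 1, 2))
  # L = 0.5 * 0.25 + 0.5
  expect_equal(occu_negloglik(c(0, 0), h00, spec), -log(0.625))
  expect_error(occu_negloglik(c(0, 0, 0), h10, spec), "expected 2")
})

test_that("site likelihoods normalize over all possible histories", {
  spec <- occu_model_spec()
  withr::local_seed(99)
  for (t in 2:4) {
    H <- all_histories(t)
    for (rep in 1:5) {
      par <- rnorm(2, 0, 2)
      tot <- sum(apply(H, 1, function(y) {
        exp(-occu_negloglik(par, make_history(matrix(y, 1, t)), spec))
      }))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
  }
})

test_that("parameter counting reproduces the published K values", {
  expect_equal(count_parameters(
    parse_occu_model("psi(.), p(PumaCount+HD+G+P3+G*P3)")), 7)
  expect_equal(count_parameters(parse_occu_model("psi(.), p(.)")), 2)
  expect_equal(count_parameters(parse_occu_model("psi(.), p(HD)")), 3)
  # every published fine-scale model string parses to its printed K
  tab <- study_model_rankings("fine")
  expect_equal(vapply(tab$model, function(m) count_parameters(parse_occu_model(m)),
                      integer(1), USE.NAMES = FALSE), tab$K)
})

test_that("the intercept-only MLE matches a brute-force grid optimum", {
  Y <- rbind(c(1, 0, 1), c(0, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0, 0, 0))
  h <- make_history(Y)
  fit <- fit_occupancy(h, occu_model_spec())
  grid <- seq(0.01, 0.99, by = 0.005)
  ll <- outer(grid, grid, Vectorize(function(psi, p) {
    sum(apply(Y, 1, function(y) {
      d <- sum(y); t <- length(y)
      log(psi * p^d * (1 - p)^(t - d) + (1 - psi) * (d == 0))
    }))
  }))
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  expect_equal(fit$psi_hat, grid[best[1]], tolerance = 0.01)
  expect_equal(fit$p_hat, grid[best[2]], tolerance = 0.01)
  expect_equal(fit$neg2loglik, -2 * max(ll), tolerance = 1e-4)
})

test_that("simulation recovery: estimates near truth at moderate scale", {
  withr::local_seed(314)
  n <- 300; t <- 10; psi <- 0.8; p <- 0.4
  z <- rbinom(n, 1, psi)
  Y <- matrix(rbinom(n * t, 1, rep(z * p, t)), n, t)
  fit <- fit_occupancy(make_history(Y), occu_model_spec(), n_starts = 3)
  # Monte-Carlo SEs: sd(psi-hat) ~ sqrt(psi(1-psi)/n) with near-perfect
  # cumulative detection; p-hat se ~ sqrt(p(1-p)/(n psi t))
  expect_lt(abs(fit$psi_hat - psi), 3 * sqrt(psi * (1 - psi) / n) + 0.02)
  expect_lt(abs(fit$p_hat - p), 3 * sqrt(p * (1 - p) / (n * psi * t)) + 0.02)
  expect_true(fit$converged)
  expect_false(fit$boundary)
})

test_that("saturated data push psi to the boundary and are flagged", {
  h <- make_history(matrix(1, 6, 4))
  fit <- fit_occupancy(h, occu_model_spec())
  expect_true(fit$boundary)
  expect_gt(fit$psi_hat, 0.99)
})

test_that("adding a detection never decreases fitted occupancy", {
  withr::local_seed(5)
  Y <- matrix(rbinom(40, 1, 0.3), 8, 5)
  Y[2, ] <- 0
  base <- fit_occupancy(make_history(Y), occu_model_spec(), n_starts = 2)
  Y2 <- Y; Y2[2, 3] <- 1
  more <- fit_occupancy(make_history(Y2), occu_model_spec(), n_starts = 2)
  expect_gte(more$psi_hat + 1e-8, base$psi_hat)
})

test_that("detection predictions respect the link and the fitted signs", {
  s <- sim_survey(61, sim_config(suppression = 1))
  fit <- fit_occupancy(s$hB, parse_occu_model("psi(.), p(PumaCount+HD)"),
                       s$site_covs, s$lags)
  prof0 <- tibble::tibble(PumaCount = 0, HD = 0)
  pred0 <- predict_detection(fit, prof0)
  expect_equal(pred0$p, plogis(fit$beta[["p_(Intercept)"]]))
  expect_true(pred0$conf.low < pred0$p && pred0$p < pred0$conf.high)

  # negative coefficient => strictly decreasing prediction
  b_pc <- fit$beta[["p_PumaCount"]]
  pred <- predict_detection(fit, tibble::tibble(PumaCount = 0:5, HD = 0))
  if (b_pc < 0) expect_true(all(diff(pred$p) < 0)) else
    expect_true(all(diff(pred$p) > 0))
  expect_error(predict_detection(fit, tibble::tibble(PumaCount = 0)),
               "lacks covariate")
})

test_that("delta-method intervals agree with a parametric bootstrap", {
  withr::local_seed(2718)
  n <- 120; t <- 12; psi <- 0.75
  x <- rnorm(n)
  p <- plogis(-0.5 + 0.8 * x)
  z <- rbinom(n, 1, psi)
  Y <- matrix(rbinom(n * t, 1, rep(z, t) * rep(p, t)), n, t)
  sc <- tibble::tibble(site_id = sprintf("s%03d", 1:n), X = x)
  h <- make_history(Y); rownames(h$Y) <- rownames(h$effort) <- sc$site_id
  h$sites <- sc$site_id
  spec <- occu_model_spec("X")
  fit <- fit_occupancy(h, spec, sc, n_starts = 2)
  prof <- tibble::tibble(X = 1)
  delta_ci <- predict_detection(fit, prof)

  boot_p <- replicate(80, {
    zb <- rbinom(n, 1, fit$psi_hat)
    pb <- plogis(fit$beta[["p_(Intercept)"]] + fit$beta[["p_X"]] * x)
    Yb <- matrix(rbinom(n * t, 1, rep(zb, t) * rep(pb, t)), n, t)
    hb <- make_history(Yb); rownames(hb$Y) <- rownames(hb$effort) <- sc$site_id
    hb$sites <- sc$site_id
    fb <- fit_occupancy(hb, spec, sc, n_starts = 1)
    plogis(fb$beta[["p_(Intercept)"]] + fb$beta[["p_X"]])
  })
  boot_ci <- quantile(boot_p, c(0.025, 0.975))
  expect_lt(abs(delta_ci$conf.low - boot_ci[[1]]), 0.06)
  expect_lt(abs(delta_ci$conf.high - boot_ci[[2]]), 0.06)
})
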
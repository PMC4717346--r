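test_that("structure kernel density peaks at the site and truncates", {
  sites <- tibble::tibble(site_id = "s1", x = 0, y = 0)
  none <- tibble::tibble(x = numeric(), y = numeric())
  expect_equal(hop_kernel_density(none, sites, 200)$hd, 0)

  at_site <- tibble::tibble(x = 0, y = 0)
  expect_equal(hop_kernel_density(at_site, sites, 200)$hd, 1)  # kernel max

  far <- tibble::tibble(x = 201, y = 0)
  expect_equal(hop_kernel_density(far, sites, 200)$hd, 0)

  # additive over structures: two identical points double the value
  one <- tibble::tibble(x = 50, y = 0)
  two <- dplyr::bind_rows(one, one)
  expect_equal(hop_kernel_density(two, sites, 200)$hd,
               2 * hop_kernel_density(one, sites, 200)$hd)

  expect_error(hop_kernel_density(one, sites, -5), "positive")
})

test_that("kernel density decreases monotonically with distance", {
  sites <- tibble::tibble(site_id = sprintf("s%d", 1:50),
                          x = seq(0, 490, by = 10), y = 0)
  hd <- hop_kernel_density(tibble::tibble(x = 0, y = 0), sites, 400)$hd
  expect_true(all(diff(hd) <= 1e-12))
  lin <- hop_kernel_density(tibble::tibble(x = 0, y = 0), sites, 400,
                            kernel = "linear")$hd
  expect_true(all(diff(lin) <= 1e-12))
})

test_that("scale selection recovers the generating radius and flags ties", {
  # detection responds to development measured at 200 m; candidate fits
  # differ only in the radius used to rebuild the covariate
  withr::local_seed(42)
  n <- 80; t <- 40
  sites <- tibble::tibble(site_id = sprintf("s%02d", 1:n),
                          x = runif(n, 0, 4000), y = runif(n, 0, 4000))
  hops <- tibble::tibble(x = runif(300, 0, 4000), y = runif(300, 0, 4000))
  hd_true <- hop_kernel_density(hops, sites, 200)$hd
  hd_z <- (hd_true - mean(hd_true)) / sd(hd_true)
  p <- plogis(-1 - 1.5 * hd_z)
  Y <- matrix(rbinom(n * t, 1, rep(p, t)), n, t)
  rownames(Y) <- sites$site_id
  h <- make_history(Y)
  fitter <- function(r) {
    sc <- sites
    sc$HD <- hop_kernel_density(hops, sites, r)$hd
    sc <- standardize_covariates(sc, "HD")
    fit_occupancy(h, occu_model_spec("HD"), site_covs = sc, n_starts = 2)
  }
  sel <- select_scale(c(100, 200, 800), fitter)
  expect_equal(sel$radius, 200)
  expect_false(sel$tie)
  expect_equal(nrow(sel$table), 3)

  # identical fits at all radii -> tie broken toward the smallest radius
  const_fit <- list(neg2loglik = 100, K = 3, converged = TRUE, n_sites = 40)
  sel2 <- select_scale(c(100, 300), function(r) const_fit)
  expect_equal(sel2$radius, 100)
  expect_true(sel2$tie)
  expect_error(select_scale(200, fitter), "at least two")
})

test_that("lag covariates cover the detection day plus k-1 following days", {
  Y <- matrix(0, 1, 10); Y[1, 5] <- 1
  lags <- build_lag_covariates(make_history(Y))
  expect_equal(unname(lags$P3[1, ]), c(0, 0, 0, 0, 1, 1, 1, 0, 0, 0))
  expect_equal(lags$P1, make_history(Y)$Y)

  # union of overlapping windows: detections on days 5 and 6, P2
  Y2 <- matrix(0, 1, 10); Y2[1, 5:6] <- 1
  l2 <- build_lag_covariates(make_history(Y2))
  expect_equal(unname(l2$P2[1, ]), c(0, 0, 0, 0, 1, 1, 1, 0, 0, 0))

  # truncation at the survey end
  Y3 <- matrix(0, 1, 5); Y3[1, 5] <- 1
  expect_equal(unname(build_lag_covariates(make_history(Y3))$P4[1, ]),
               c(0, 0, 0, 0, 1))

  expect_error(build_lag_covariates(make_history(Y, daily = FALSE)), "daily")
})

test_that("lag windows nest: P1 <= P2 <= P3 <= P4", {
  withr::local_seed(7)
  for (rep in 1:5) {
    Y <- matrix(rbinom(60, 1, 0.2), 4, 15)
    lags <- build_lag_covariates(make_history(Y))
    expect_true(all(lags$P1 <= lags$P2))
    expect_true(all(lags$P2 <= lags$P3))
    expect_true(all(lags$P3 <= lags$P4))
    # every window contains its triggering day
    expect_true(all(lags$P4[Y == 1] == 1))
  }
})

test_that("standardization is exact, skips binaries, and back-transforms", {
  tab <- tibble::tibble(site_id = c("a", "b", "c"), HD = c(1, 2, 3),
                        G = c(0, 1, 0))
  out <- standardize_covariates(tab, "HD")
  expect_equal(out$HD, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(out$G, tab$G)
  sc <- attr(out, "scaling")
  expect_equal(out$HD * sc$sd + sc$mean, tab$HD)

  flat <- tibble::tibble(site_id = "a", HD = c(2, 2, 2))
  expect_warning(standardize_covariates(flat, "HD"), "zero variance")
})
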
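test_that("the landscape reproduces the two-grid design deterministically", {
  cfg <- sim_config()
  l1 <- simulate_landscape(cfg, seed = 1)
  expect_equal(nrow(l1$sites), 40)
  expect_equal(as.integer(table(l1$sites$grid)), c(20L, 20L))
  # 20 cells of 2 x 2 km = 80 km2 per grid: sites span a 10 x 8 km block
  for (g in c("urban", "wildland")) {
    gs <- l1$sites[l1$sites$grid == g, ]
    expect_equal(diff(range(gs$x)) + 2000, 10000)
    expect_equal(diff(range(gs$y)) + 2000, 8000)
  }
  l2 <- simulate_landscape(cfg, seed = 1)
  expect_identical(l1, l2)
  expect_false(identical(simulate_landscape(cfg, seed = 2)$hops, l1$hops))

  # no structures on a grid -> development covariate identically zero
  cfg0 <- sim_config(hop_intensity_wild = 1e-9)
  l0 <- simulate_landscape(cfg0, seed = 3)
  wild <- l0$sites[l0$sites$grid == "wildland", ]
  expect_true(all(hop_kernel_density(l0$hops, wild, 500)$hd == 0))
})

test_that("marginal subordinate occupancy matches the conditional mixture", {
  cfg <- sim_config(n_sites_per_grid = 400, survey_start = "2010-10-01",
                    survey_end = "2010-10-05", psiA = 0.6,
                    psiBA = 0.4, psiBa = 0.9, burst_prob = 0)
  l <- simulate_landscape(cfg, seed = 5)
  sim <- simulate_detection_data(cfg, l, seed = 6)
  target <- 0.6 * 0.4 + 0.4 * 0.9   # psiA psiBA + (1 - psiA) psiBa
  n <- nrow(l$sites)
  expect_lt(abs(mean(sim$truth$zB) - target),
            3 * sqrt(target * (1 - target) / n))
})

test_that("daily detection frequency converges to its configured level", {
  # no suppression, no HD effect: every occupied site detects B at its
  # grid's configured daily probability
  cfg <- sim_config(n_sites_per_grid = 150, suppression = 1, beta_hd = 0,
                    psiBA = 0.999, psiBa = 0.999, burst_prob = 0)
  l <- simulate_landscape(cfg, seed = 7)
  sim <- simulate_detection_data(cfg, l, seed = 8)
  urban <- l$sites$grid == "urban"
  n_days <- ncol(sim$truth$YB)
  freq_u <- mean(sim$truth$YB[urban & sim$truth$zB == 1, ])
  freq_w <- mean(sim$truth$YB[!urban & sim$truth$zB == 1, ])
  se <- sqrt(0.15 * 0.85 / (sum(urban) * n_days))
  expect_lt(abs(freq_u - cfg$pB_daily_urban), 4 * se)
  expect_lt(abs(freq_w - cfg$pB_daily_wild), 4 * se)
})

test_that("suppression empties the subordinate's lag window on wildland only", {
  cfg <- sim_config(n_sites_per_grid = 100, suppression = 0,
                    suppression_days = 3, burst_prob = 0)
  l <- simulate_landscape(cfg, seed = 15)
  sim <- simulate_detection_data(cfg, l, seed = 16)
  hA <- make_history(sim$truth$YA)
  lag3 <- build_lag_covariates(hA, 3)$P3
  wild <- l$sites$grid == "wildland"
  # wildland: B never detected inside a 3-day window after an A visit
  expect_equal(sum(sim$truth$YB[wild, ][lag3[wild, ] == 1]), 0)
  # urbanized grid is unaffected: detections do occur inside windows
  expect_gt(sum(sim$truth$YB[!wild, ][lag3[!wild, ] == 1]), 0)
})

test_that("null mechanism leaves subordinate detections independent of lags", {
  cfg <- sim_config(n_sites_per_grid = 150, suppression = 1, burst_prob = 0)
  l <- simulate_landscape(cfg, seed = 17)
  sim <- simulate_detection_data(cfg, l, seed = 18)
  lag3 <- build_lag_covariates(make_history(sim$truth$YA), 3)$P3
  wild <- l$sites$grid == "wildland" & sim$truth$zB == 1
  inside <- mean(sim$truth$YB[wild, ][lag3[wild, ] == 1])
  outside <- mean(sim$truth$YB[wild, ][lag3[wild, ] == 0])
  n_in <- sum(lag3[wild, ] == 1)
  expect_lt(abs(inside - outside),
            4 * sqrt(outside * (1 - outside) / n_in))
})

test_that("activity times follow the configured circadian mixture", {
  cfg <- sim_config(n_sites_per_grid = 200, burst_prob = 0)
  l <- simulate_landscape(cfg, seed = 25)
  sim <- simulate_detection_data(cfg, l, seed = 26)
  tB <- time_to_radians(sim$photos$timestamp[sim$photos$species == "bobcat"])
  mix <- cfg$activity$B
  breaks <- seq(0, 2 * pi, length.out = 13)
  obs <- table(cut(tB, breaks))
  dens <- function(x) {
    rowSums(sapply(seq_along(mix$weight), function(j) {
      mix$weight[j] * urbanfelid:::dvonmises(x, 2 * pi * mix$mu[j] / 24,
                                             mix$kappa[j])
    }))
  }
  p_bin <- vapply(seq_len(12), function(j) {
    g <- seq(breaks[j], breaks[j + 1], length.out = 200)
    mean(dens(g)) * (breaks[j + 1] - breaks[j])
  }, numeric(1))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = p_bin / sum(p_bin)))
  expect_gt(gof$p.value, 0.001)
})

test_that("fixtures round-trip byte-identically under a fixed seed", {
  cfg <- sim_config(n_sites_per_grid = 5, survey_end = "2010-10-20")
  l <- simulate_landscape(cfg, seed = 33)
  sim <- simulate_detection_data(cfg, l, seed = 34)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(sim, l, d1)
  rec <- read_photo_records(file.path(d1, "photos.csv"))
  expect_equal(nrow(rec), nrow(sim$photos))
  expect_equal(sort(rec$timestamp), sort(sim$photos$timestamp),
               ignore_attr = TRUE)
  expect_equal(sort(unique(rec$site_id)), sort(unique(sim$photos$site_id)))

  sim_b <- simulate_detection_data(cfg, l, seed = 34)
  write_fixture(sim_b, l, d2)
  expect_identical(readLines(file.path(d1, "photos.csv")),
                   readLines(file.path(d2, "photos.csv")))
  d3 <- withr::local_tempdir()
  write_fixture(simulate_detection_data(cfg, l, seed = 35), l, d3)
  expect_false(identical(readLines(file.path(d1, "photos.csv")),
                         readLines(file.path(d3, "photos.csv"))))
})
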
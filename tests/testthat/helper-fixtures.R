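# Shared fixture builders: everything is generated in code at test time.

# A detection history directly from a matrix (full effort unless given).
make_history <- function(Y, effort = NULL, daily = TRUE) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) {
    rownames(Y) <- sprintf("s%02d", seq_len(nrow(Y)))
  }
  if (is.null(effort)) effort <- matrix(1, nrow(Y), ncol(Y))
  rownames(effort) <- rownames(Y)
  urbanfelid:::new_detection_history(
    Y, effort, occasion_dates = as.Date("2010-10-01") + seq_len(ncol(Y)) - 1,
    daily = daily)
}

# Photo-record tibble from (site, species, time-string) triplets.
make_photos <- function(site, species, times, individual = NA_character_) {
  tibble::tibble(
    site_id = site, species = species,
    timestamp = as.POSIXct(times, tz = "UTC"),
    individual_id = individual, dependent_young = FALSE
  )
}

# Random probability-scale two-species parameter set.
random_ts_params <- function() {
  p <- stats::runif(8, 0.05, 0.95)
  names(p) <- c("psiA", "psiBA", "psiBa", "pA", "rA", "pB", "rBA", "rBa")
  as.list(p)
}

# All 0/1 detection histories of length t (rows of a matrix).
all_histories <- function(t) {
  as.matrix(expand.grid(rep(list(0:1), t)))
}

# Numerical oracle for the true overlap of two von Mises mixtures.
true_overlap_vm <- function(mu1, kappa1, mu2, kappa2, n_grid = 4096) {
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  f <- urbanfelid:::dvonmises(grid, mu1, kappa1)
  g <- urbanfelid:::dvonmises(grid, mu2, kappa2)
  sum(pmin(f, g)) * 2 * pi / n_grid
}

# One simulated survey with histories, lags and standardized covariates.
sim_survey <- function(seed, config = sim_config(), n_starts = 2) {
  landscape <- simulate_landscape(config, seed = seed)
  sim <- simulate_detection_data(config, landscape, seed = seed + 1)
  events <- filter_independent(sim$photos)
  design <- survey_design(config$survey_start, config$survey_end)
  hA <- assign_daily_occasions(events, design, species = "puma",
                               sites = landscape$sites$site_id)
  hB <- assign_daily_occasions(events, design, species = "bobcat",
                               sites = landscape$sites$site_id)
  sc <- landscape$sites
  sc$HD <- hop_kernel_density(landscape$hops, landscape$sites, 200)$hd
  sc$PumaCount <- event_count_by_site(events, "puma",
                                      landscape$sites$site_id)$n_events
  sc <- standardize_covariates(sc, c("HD", "PumaCount"))
  list(landscape = landscape, sim = sim, events = events, design = design,
       hA = hA, hB = hB, site_covs = sc, lags = build_lag_covariates(hA))
}
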
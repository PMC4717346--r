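#' Configuration for the synthetic camera-trap survey generator
#'
#' Defines the generative model the simulator draws from. The defaults
#' reproduce the design of a two-grid carnivore camera survey: two 80 km2
#' grids of 20 sites on 2 x 2 km cells (one urbanized, one wildland), a
#' ~3-month daily survey, latent two-species occupancy with optional
#' conditional dependence, daily detection with a multi-day suppression
#' of the subordinate species after dominant-species visits on the
#' wildland grid only, bimodal crepuscular/nocturnal activity-time
#' distributions, and a human-structure surface concentrated on the
#' urbanized grid.
#'
#' Daily detection intercepts are chosen so that survey-length detection
#' frequencies sit in the range observed for mid-sized and large felids:
#' the subordinate species (B, bobcat-like) is detected on roughly 12-15%
#' of days at an occupied site, the dominant species (A, puma-like) on
#' roughly 4%, giving 0-8 independent events per site over ~90 days.
#'
#' @param n_sites_per_grid sites per grid (default 20).
#' @param survey_start,survey_end survey window (default a 92-day
#'   October-December window).
#' @param psiA,psiBA,psiBa occupancy of the dominant species and of the
#'   subordinate species conditional on dominant presence/absence.
#' @param pA_daily daily detection probability of the dominant species.
#' @param pB_daily_urban,pB_daily_wild daily detection probability of the
#'   subordinate species on each grid.
#' @param beta_hd effect (logit scale, per standardized unit) of the
#'   human-development covariate on both species' daily detection.
#' @param suppression multiplier `s` applied to B's daily detection
#'   probability during the avoidance window (0 = full avoidance,
#'   1 = no effect).
#' @param suppression_days length of the avoidance window in days
#'   (detection day plus `suppression_days - 1` following days).
#' @param suppression_grids grids on which the avoidance mechanism
#'   operates (default wildland only).
#' @param hop_intensity_urban,hop_intensity_wild expected number of human
#'   structures per km2 on each grid.
#' @param activity named list of activity-time mixtures per species; each
#'   a list of `mu` (peak hours), `kappa` and `weight` vectors.
#' @param burst_prob probability that a detection event spawns extra
#'   sub-hour photographs (exercises the independence filter).
#' @param day_boundary occasion boundary time of day.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_sites_per_grid = 20,
                       survey_start = "2010-10-01",
                       survey_end = "2010-12-31",
                       psiA = 0.6, psiBA = 0.9, psiBa = 0.9,
                       pA_daily = 0.04,
                       pB_daily_urban = 0.15, pB_daily_wild = 0.12,
                       beta_hd = -0.4,
                       suppression = 0, suppression_days = 3,
                       suppression_grids = "wildland",
                       hop_intensity_urban = 3, hop_intensity_wild = 0.05,
                       activity = list(
                         B = list(mu = c(6, 20), kappa = c(2.5, 2.5),
                                  weight = c(0.5, 0.5)),
                         A = list(mu = c(21, 2), kappa = c(2, 1.5),
                                  weight = c(0.6, 0.4))
                       ),
                       burst_prob = 0.25,
                       day_boundary = "12:00") {
  cfg <- as.list(environment())
  stopifnot(psiA > 0, psiA < 1, psiBA > 0, psiBA < 1, psiBa > 0, psiBa < 1,
            pA_daily > 0, pA_daily < 1,
            suppression >= 0, suppression <= 1, suppression_days >= 0)
  for (sp in names(activity)) {
    w <- activity[[sp]]$weight
    if (abs(sum(w) - 1) > 1e-8) stop_ufl("activity weights must sum to 1")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate the landscape: sites, grids and human structures
#'
#' Places one camera site at the centre of each 2 x 2 km cell of two
#' 4 x 5-cell grids (urbanized and wildland, 80 km2 each) and scatters
#' human structure points from a homogeneous Poisson process whose
#' intensity differs by grid. Coordinates are projected metres.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (private stream).
#' @return list with `sites` (tibble: `site_id`, `x`, `y`, `grid`, `G`)
#'   and `hops` (tibble: `x`, `y`).
#' @export
simulate_landscape <- function(config, seed = 1) {
  n <- config$n_sites_per_grid
  ncol_cells <- 5
  nrow_cells <- ceiling(n / ncol_cells)
  cell <- 2000
  one_grid <- function(grid_name, offset_x, G) {
    idx <- seq_len(n) - 1
    tibble::tibble(
      site_id = sprintf("%s_%02d", toupper(substr(grid_name, 1, 1)), seq_len(n)),
      x = offset_x + (idx %% ncol_cells) * cell + cell / 2,
      y = (idx %/% ncol_cells) * cell + cell / 2,
      grid = grid_name, G = G
    )
  }
  # grids ~6 km apart, urbanized coded G = 1
  sites <- dplyr::bind_rows(one_grid("urban", 0, 1L),
                            one_grid("wildland", ncol_cells * cell + 6000, 0L))
  hops <- with_private_seed(seed, {
    area_km2 <- ncol_cells * nrow_cells * (cell / 1000)^2
    draw <- function(intensity, offset_x) {
      m <- stats::rpois(1, intensity * area_km2)
      tibble::tibble(x = stats::runif(m, offset_x, offset_x + ncol_cells * cell),
                     y = stats::runif(m, 0, nrow_cells * cell))
    }
    dplyr::bind_rows(draw(config$hop_intensity_urban, 0),
                     draw(config$hop_intensity_wild, ncol_cells * cell + 6000))
  })
  list(sites = sites, hops = hops)
}

#' Simulate photo records with known truth
#'
#' Draws latent occupancy states (A present with probability `psiA`; B
#' with `psiBA` or `psiBa` conditional on A), then daily detections: A is
#' detected with probability `plogis(logit(pA_daily) + beta_hd * HD)`;
#' B's daily probability (grid-specific intercept plus the same HD
#' effect) is multiplied by `suppression` for `suppression_days` days
#' starting at each day with an A detection, on the configured grids
#' only. Each detection becomes a photo record with a timestamp drawn
#' from the species' circadian mixture within that occasion's
#' noon-to-noon window; with probability `burst_prob` an event spawns
#' 1-2 extra photographs within the following hour, which the
#' independence filter must collapse.
#'
#' @param config a [sim_config()].
#' @param landscape output of [simulate_landscape()].
#' @param seed RNG seed (private stream).
#' @return list with `photos` (photo-record tibble), `deployments`,
#'   `truth` (latent states, per-site daily detection matrices, event
#'   counts and the config).
#' @export
simulate_detection_data <- function(config, landscape, seed = 1) {
  sites <- landscape$sites
  design <- survey_design(config$survey_start, config$survey_end,
                          config$day_boundary)
  t <- design$n_occasions
  n <- nrow(sites)
  hd <- hop_kernel_density(landscape$hops, sites, radius = 200)$hd
  hd_z <- if (stats::sd(hd) > 0) (hd - mean(hd)) / stats::sd(hd) else hd * 0

  with_private_seed(seed, {
    zA <- stats::rbinom(n, 1, config$psiA)
    zB <- stats::rbinom(n, 1, ifelse(zA == 1, config$psiBA, config$psiBa))
    pA <- inv_logit(logit(config$pA_daily) + config$beta_hd * hd_z)
    pB_base <- inv_logit(
      logit(ifelse(sites$G == 1, config$pB_daily_urban, config$pB_daily_wild)) +
        config$beta_hd * hd_z)

    YA <- matrix(0L, n, t, dimnames = list(sites$site_id, NULL))
    YB <- matrix(0L, n, t, dimnames = list(sites$site_id, NULL))
    suppressed_grid <- sites$grid %in% config$suppression_grids
    for (i in seq_len(n)) {
      if (zA[i] == 1) YA[i, ] <- stats::rbinom(t, 1, pA[i])
      if (zB[i] == 1) {
        p_day <- rep(pB_base[i], t)
        if (suppressed_grid[i] && config$suppression_days > 0) {
          hit <- which(YA[i, ] == 1)
          for (d in hit) {
            win <- d:min(d + config$suppression_days - 1, t)
            p_day[win] <- p_day[win] * config$suppression
          }
        }
        YB[i, ] <- stats::rbinom(t, 1, p_day)
      }
    }

    bnd <- occasion_boundaries(design)
    make_photos <- function(Y, species) {
      mix <- config$activity[[species]]
      cells <- which(Y == 1, arr.ind = TRUE)
      if (!nrow(cells)) {
        return(tibble::tibble(site_id = character(), species = character(),
                              timestamp = as.POSIXct(character(), tz = "UTC"),
                              individual_id = NA_character_,
                              dependent_young = logical()))
      }
      purrr::map_dfr(seq_len(nrow(cells)), function(k) {
        i <- cells[k, 1]; d <- cells[k, 2]
        comp <- sample.int(length(mix$weight), 1, prob = mix$weight)
        theta <- rvonmises(1, 2 * pi * mix$mu[comp] / 24, mix$kappa[comp])
        sec_of_day <- theta * 86400 / (2 * pi)
        # place within the occasion's noon-to-noon window
        day_start <- as.numeric(bnd[d])
        offset <- (sec_of_day - 12 * 3600) %% 86400
        ts0 <- as.POSIXct(day_start + offset, origin = "1970-01-01", tz = "UTC")
        ts <- ts0
        if (stats::runif(1) < config$burst_prob) {
          extra <- sample(1:2, 1)
          ts <- c(ts0, ts0 + sort(stats::runif(extra, 60, 3500)))
        }
        tibble::tibble(site_id = sites$site_id[i],
                       species = if (species == "A") "puma" else "bobcat",
                       timestamp = ts, individual_id = NA_character_,
                       dependent_young = FALSE)
      })
    }
    photos <- dplyr::bind_rows(make_photos(YA, "A"), make_photos(YB, "B")) |>
      dplyr::arrange(.data$site_id, .data$species, .data$timestamp)

    deployments <- tibble::tibble(
      site_id = sites$site_id,
      start = format(bnd[1], "%Y-%m-%dT%H:%M:%S"),
      end = format(bnd[t + 1], "%Y-%m-%dT%H:%M:%S")
    )
    list(photos = photos, deployments = deployments,
         truth = list(zA = zA, zB = zB, YA = YA, YB = YB,
                      hd = hd, hd_z = hd_z, pA = pA, pB_base = pB_base,
                      event_counts_A = rowSums(YA), event_counts_B = rowSums(YB),
                      design = design, config = config))
  })
}

#' Write a simulated dataset as the pipeline's CSV fixture files
#'
#' Emits `photos.csv`, `deployments.csv`, `sites.csv` and `hops.csv` in
#' exactly the formats the ingestion functions consume, so a simulated
#' survey round-trips through the full pipeline. Output is byte-stable
#' for a given simulation.
#'
#' @param sim output of [simulate_detection_data()].
#' @param landscape output of [simulate_landscape()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_fixture <- function(sim, landscape, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  photos <- sim$photos |>
    dplyr::mutate(timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%S"),
                  dependent_young = as.integer(.data$dependent_young))
  readr::write_csv(photos, file.path(dir, "photos.csv"))
  readr::write_csv(sim$deployments, file.path(dir, "deployments.csv"))
  readr::write_csv(landscape$sites, file.path(dir, "sites.csv"))
  readr::write_csv(landscape$hops, file.path(dir, "hops.csv"))
  invisible(dir)
}
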
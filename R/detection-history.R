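#' Define a survey design
#'
#' A survey design fixes the occasion structure of a camera survey: one
#' daily occasion per calendar day from `start_date` through `end_date`
#' inclusive, with each occasion running from `day_boundary` on that day
#' to `day_boundary` on the next. A noon boundary (the default) keeps the
#' crepuscular/nocturnal activity of the focal species within a single
#' occasion.
#'
#' @param start_date,end_date survey window (anything `as.Date()` accepts).
#' @param day_boundary time of day at which occasions roll over,
#'   `"HH:MM"` (default `"12:00"`).
#' @param pool_length optional pooling length in days; when set,
#'   `floor(t / pool_length)` pooled occasions are available and trailing
#'   remainder days are dropped by [pool_occasions()].
#' @return an object of class `survey_design`.
#' @export
survey_design <- function(start_date, end_date, day_boundary = "12:00",
                          pool_length = NULL) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || end_date < start_date) {
    stop_ufl("invalid survey window")
  }
  t <- as.integer(end_date - start_date) + 1L
  structure(
    list(start_date = start_date, end_date = end_date,
         day_boundary = day_boundary, n_occasions = t,
         pool_length = pool_length,
         n_pooled = if (!is.null(pool_length)) t %/% as.integer(pool_length)),
    class = "survey_design"
  )
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Survey design:", format(x$start_date), "to", format(x$end_date),
      sprintf("(%d daily occasions, boundary %s)\n", x$n_occasions, x$day_boundary))
  if (!is.null(x$pool_length)) {
    cat(sprintf("  pooled: %d occasions of %d days (%d trailing days dropped)\n",
                x$n_pooled, x$pool_length,
                x$n_occasions - x$n_pooled * x$pool_length))
  }
  invisible(x)
}

new_detection_history <- function(Y, effort, occasion_dates, daily = TRUE,
                                  pool_length = NULL) {
  stopifnot(all(dim(Y) == dim(effort)))
  Y[effort == 0] <- NA
  structure(
    list(Y = Y, effort = effort, sites = rownames(Y),
         occasion_dates = occasion_dates, daily = daily,
         pool_length = pool_length),
    class = "detection_history"
  )
}

#' @export
print.detection_history <- function(x, ...) {
  cat(sprintf("Detection history: %d sites x %d %s occasions\n",
              nrow(x$Y), ncol(x$Y), if (x$daily) "daily" else "pooled"))
  cat(sprintf("  detections: %d, missing cells: %d\n",
              sum(x$Y == 1, na.rm = TRUE), sum(is.na(x$Y))))
  invisible(x)
}

#' Tidy a detection history into long format
#'
#' @param x a `detection_history`.
#' @param ... unused.
#' @return tibble with columns `site_id`, `occasion`, `detected`, `effort`.
#' @method tidy detection_history
#' @export
tidy.detection_history <- function(x, ...) {
  tibble::tibble(
    site_id = rep(x$sites, times = ncol(x$Y)),
    occasion = rep(seq_len(ncol(x$Y)), each = nrow(x$Y)),
    detected = as.vector(x$Y),
    effort = as.vector(x$effort)
  )
}

#' Build a daily detection history from independent events
#'
#' Assigns each independent event of one species to the daily occasion
#' whose boundary-to-boundary interval contains it, and records a 1 for
#' every site-occasion with at least one event. Effort for a daily
#' occasion is 1 if the camera was active during any part of that
#' interval, else 0, and cells without effort are missing (`NA`), not 0.
#'
#' Events falling outside the survey window are excluded with a warning.
#'
#' @param events tibble of independent events ([filter_independent()]),
#'   already restricted to (or filtered by) `species`.
#' @param design a [survey_design()].
#' @param species optional species label to filter `events` by.
#' @param sites character vector of all camera sites (rows of the
#'   history). Defaults to the sites present in `events`.
#' @param deployments optional tibble (`site_id`, `start`, `end`) of
#'   camera deployment windows; optionally a `deployments_inactive`
#'   tibble of the same shape lists failure intervals. Sites default to
#'   full effort when no deployment table is given.
#' @param deployments_inactive optional tibble (`site_id`, `start`,
#'   `end`) of within-deployment inactive intervals (camera failures).
#' @return a `detection_history`.
#' @export
assign_daily_occasions <- function(events, design, species = NULL, sites = NULL,
                                   deployments = NULL,
                                   deployments_inactive = NULL) {
  stopifnot(inherits(design, "survey_design"))
  if (!is.null(species)) {
    sp <- species
    events <- dplyr::filter(events, .data$species == sp)
  }
  if (is.null(sites)) sites <- sort(unique(events$site_id))
  t <- design$n_occasions
  bnd <- occasion_boundaries(design)   # length t + 1 POSIXct

  Y <- matrix(0, nrow = length(sites), ncol = t,
              dimnames = list(sites, NULL))
  if (nrow(events)) {
    occ <- findInterval(as.numeric(events$timestamp), as.numeric(bnd))
    outside <- occ < 1 | occ > t
    if (any(outside)) {
      warn_ufl(sum(outside), " event(s) outside the survey window excluded")
    }
    ev <- events[!outside, , drop = FALSE]
    occ <- occ[!outside]
    keep <- ev$site_id %in% sites
    for (j in which(keep)) Y[ev$site_id[j], occ[j]] <- 1
  }

  effort <- effort_matrix(sites, bnd, deployments, deployments_inactive)
  new_detection_history(Y, effort, occasion_dates = as.Date(bnd[seq_len(t)]),
                        daily = TRUE)
}

occasion_boundaries <- function(design) {
  days <- seq(design$start_date, design$end_date + 1L, by = "day")
  as.POSIXct(paste(format(days), design$day_boundary), tz = "UTC")
}

effort_matrix <- function(sites, bnd, deployments, inactive) {
  t <- length(bnd) - 1L
  eff <- matrix(1, nrow = length(sites), ncol = t,
                dimnames = list(sites, NULL))
  if (is.null(deployments)) return(eff)
  lo <- as.numeric(bnd[seq_len(t)])
  hi <- as.numeric(bnd[-1L])
  active <- matrix(FALSE, nrow = length(sites), ncol = t,
                   dimnames = list(sites, NULL))
  as_time <- function(x) {
    if (inherits(x, "POSIXct")) as.numeric(x) else as.numeric(parse_timestamp(x))
  }
  for (k in seq_len(nrow(deployments))) {
    s <- deployments$site_id[k]
    if (!s %in% sites) next
    d0 <- as_time(deployments$start[k])
    d1 <- as_time(deployments$end[k])
    active[s, ] <- active[s, ] | (d0 < hi & d1 > lo)
  }
  if (!is.null(inactive)) {
    for (k in seq_len(nrow(inactive))) {
      s <- inactive$site_id[k]
      if (!s %in% sites) next
      d0 <- as_time(inactive$start[k])
      d1 <- as_time(inactive$end[k])
      # an occasion fully inside an outage loses its effort
      active[s, ] <- active[s, ] & !(d0 <= lo & d1 >= hi)
    }
  }
  eff * (active * 1)
}

#' Pool daily occasions into longer sampling occasions
#'
#' Collapses blocks of `L` consecutive daily occasions into single pooled
#' occasions: a pooled cell is 1 if any constituent day with effort holds
#' a detection, 0 if all constituent days with effort are zero, and
#' missing if no constituent day had effort. Pooled effort is the sum of
#' the daily efforts (operating days per occasion). Trailing
#' `t - floor(t/L) * L` days are dropped.
#'
#' @param daily a daily `detection_history`.
#' @param L pooling length in days.
#' @return a pooled `detection_history` with `floor(t/L)` occasions.
#' @export
pool_occasions <- function(daily, L) {
  stopifnot(inherits(daily, "detection_history"))
  L <- as.integer(L)
  t <- ncol(daily$Y)
  if (L < 1) stop_ufl("pool length must be >= 1")
  if (L > t) stop_ufl("pool length exceeds the number of daily occasions")
  T_p <- t %/% L
  Yp <- matrix(NA_real_, nrow = nrow(daily$Y), ncol = T_p,
               dimnames = list(rownames(daily$Y), NULL))
  Ep <- matrix(0, nrow = nrow(daily$Y), ncol = T_p,
               dimnames = list(rownames(daily$Y), NULL))
  for (j in seq_len(T_p)) {
    cols <- ((j - 1L) * L + 1L):(j * L)
    block <- daily$Y[, cols, drop = FALSE]
    Ep[, j] <- rowSums(daily$effort[, cols, drop = FALSE])
    has_data <- rowSums(!is.na(block)) > 0
    Yp[has_data, j] <- apply(block[has_data, , drop = FALSE], 1,
                             function(r) max(r, na.rm = TRUE))
  }
  new_detection_history(Yp, Ep,
                        occasion_dates = daily$occasion_dates[seq(1, T_p * L, by = L)],
                        daily = FALSE, pool_length = L)
}

#' Naive occupancy
#'
#' The proportion of sites with at least one detection, uncorrected for
#' imperfect detection.
#'
#' @param history a `detection_history`.
#' @param sites optional subset of site ids (e.g. one grid).
#' @return a single proportion.
#' @export
naive_occupancy <- function(history, sites = NULL) {
  Y <- history$Y
  if (!is.null(sites)) {
    missing_sites <- setdiff(sites, rownames(Y))
    if (length(missing_sites)) stop_ufl("unknown site(s): ",
                                        paste(missing_sites, collapse = ", "))
    Y <- Y[sites, , drop = FALSE]
  }
  if (nrow(Y) == 0) stop_ufl("empty site subset")
  mean(rowSums(Y == 1, na.rm = TRUE) > 0)
}

#' Plot a detection history as a site-by-occasion tile map
#'
#' @param object a `detection_history`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot detection_history
#' @export
autoplot.detection_history <- function(object, ...) {
  df <- tidy.detection_history(object)
  df$state <- factor(
    dplyr::case_when(is.na(df$detected) ~ "no effort",
                     df$detected == 1 ~ "detected",
                     TRUE ~ "not detected"),
    levels = c("detected", "not detected", "no effort")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$occasion, y = .data$site_id,
                                   fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`detected` = "#1b7837",
                                          `not detected` = "grey90",
                                          `no effort` = "white")) +
    ggplot2::labs(x = "occasion", y = "site", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Write a detection history and its effort matrix to CSV
#'
#' @param history a `detection_history`.
#' @param path_y,path_effort output paths; sites as rows, occasions as
#'   columns, detection cells in \{0, 1, NA\}.
#' @return `history`, invisibly.
#' @export
write_detection_history <- function(history, path_y, path_effort) {
  y <- tibble::as_tibble(history$Y, .name_repair = ~ paste0("occ_", seq_along(.x)))
  y <- dplyr::bind_cols(tibble::tibble(site_id = history$sites), y)
  e <- tibble::as_tibble(history$effort, .name_repair = ~ paste0("occ_", seq_along(.x)))
  e <- dplyr::bind_cols(tibble::tibble(site_id = history$sites), e)
  readr::write_csv(y, path_y)
  readr::write_csv(e, path_effort)
  invisible(history)
}
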
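#' Read a photo-record table
#'
#' Reads a CSV of time-stamped species photographs from motion-activated
#' cameras. Required columns are `site_id`, `species` and `timestamp`
#' (ISO 8601, minute resolution is sufficient); `individual_id` (marked
#' animals) and `dependent_young` (0/1, kittens travelling with their
#' mother) are optional and filled with `NA`/`FALSE` when absent.
#'
#' Rows whose timestamp cannot be parsed are dropped with a warning that
#' reports their line numbers; well-formed rows are kept. The result is
#' sorted by site, species and time.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector remapping the expected
#'   column names, e.g. `c(site_id = "station", timestamp = "datetime")`.
#' @return a tibble of photo records with columns `site_id`, `species`,
#'   `timestamp` (POSIXct, UTC), `individual_id`, `dependent_young`.
#' @seealso [filter_independent()] to collapse photographs into
#'   independent detection events.
#' @export
read_photo_records <- function(path, schema = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(raw)) {
        stop_ufl("schema maps '", std, "' to missing column '", schema[[std]], "'")
      }
      names(raw)[names(raw) == schema[[std]]] <- std
    }
  }
  required <- c("site_id", "species", "timestamp")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop_ufl("photo-record file is missing required column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  if (!"individual_id" %in% names(raw)) raw$individual_id <- NA_character_
  if (!"dependent_young" %in% names(raw)) raw$dependent_young <- "0"

  ts <- parse_timestamp(raw$timestamp)
  bad <- which(is.na(ts) | is.na(raw$site_id) | is.na(raw$species))
  if (length(bad)) {
    # +1 for the header line so numbers match the file on disk
    warn_ufl(length(bad), " malformed photo-record row(s) dropped (file line(s) ",
             paste(bad + 1L, collapse = ", "), ")")
  }
  out <- tibble::tibble(
    site_id = raw$site_id,
    species = raw$species,
    timestamp = ts,
    individual_id = raw$individual_id,
    dependent_young = !is.na(raw$dependent_young) &
      raw$dependent_young %in% c("1", "TRUE", "true", "T")
  )
  if (length(bad)) out <- out[-bad, , drop = FALSE]
  dplyr::arrange(out, .data$site_id, .data$species, .data$timestamp)
}

parse_timestamp <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
                "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(x[todo], format = fmt, tz = "UTC")
  }
  # reject impossible dates that strptime silently rolled over
  roll <- !is.na(out) & !is.na(x) &
    substr(format(out, "%Y-%m-%d"), 1, 7) != substr(x, 1, 7)
  out[roll] <- NA
  out
}

#' Collapse photographs into independent detection events
#'
#' Applies the photographic-independence rule used for camera-trap count
#' statistics: within a site and species, a photograph starts a new event
#' only if it was taken more than `window_minutes` after the most recent
#' *retained* event, or if it shows a different marked individual than
#' that event. Photographs of dependent young are excluded first. Exactly
#' `window_minutes` apart is *not* independent (the rule is strict).
#'
#' Assessing independence against the most recent retained event (rather
#' than the most recent raw photograph) prevents a chain of sub-window
#' photographs from suppressing detections indefinitely; it also makes the
#' filter idempotent.
#'
#' @param records tibble of photo records as returned by
#'   [read_photo_records()].
#' @param window_minutes independence window in minutes (default 60).
#' @return tibble of independent events (`site_id`, `species`,
#'   `timestamp`, `individual_id`), sorted in time within site/species.
#' @export
filter_independent <- function(records, window_minutes = 60) {
  if (window_minutes < 0) stop_ufl("window_minutes must be non-negative")
  records <- dplyr::filter(records, !.data$dependent_young %in% TRUE)
  records <- dplyr::arrange(records, .data$site_id, .data$species, .data$timestamp)
  keep_group <- function(ts, ind) {
    n <- length(ts)
    keep <- logical(n)
    if (n == 0) return(keep)
    keep[1] <- TRUE
    last_ts <- ts[1]
    last_ind <- ind[1]
    if (n > 1) for (i in 2:n) {
      gap_min <- as.numeric(difftime(ts[i], last_ts, units = "mins"))
      new_ind <- !is.na(ind[i]) && !is.na(last_ind) && ind[i] != last_ind
      if (gap_min > window_minutes || new_ind) {
        keep[i] <- TRUE
        last_ts <- ts[i]
        last_ind <- ind[i]
      }
    }
    keep
  }
  out <- records |>
    dplyr::group_by(.data$site_id, .data$species) |>
    dplyr::filter(keep_group(.data$timestamp, .data$individual_id)) |>
    dplyr::ungroup()
  dplyr::select(out, "site_id", "species", "timestamp", "individual_id")
}

#' Count independent events per site for one species
#'
#' The per-site totals of independent photographs of a species across the
#' whole survey (e.g. the `PumaCount` site covariate for the dominant
#' species).
#'
#' @param events tibble of independent events ([filter_independent()]).
#' @param species species label to count.
#' @param sites character vector of all site ids; sites without events get
#'   a zero count. Defaults to the sites present in `events`.
#' @return tibble with columns `site_id`, `n_events`.
#' @export
event_count_by_site <- function(events, species, sites = NULL) {
  sp <- species
  counts <- events |>
    dplyr::filter(.data$species == sp) |>
    dplyr::count(.data$site_id, name = "n_events")
  if (is.null(sites)) sites <- sort(unique(events$site_id))
  tibble::tibble(site_id = sites) |>
    dplyr::left_join(counts, by = "site_id") |>
    dplyr::mutate(n_events = dplyr::coalesce(.data$n_events, 0L))
}
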
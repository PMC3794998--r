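#' Great-circle distance in kilometres
#'
#' Haversine formula on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius).  Vectorized over coordinates.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees
#' @return distance in km
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  R <- 6371.0088
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# implied speeds (m/s) between consecutive records of a data frame
implied_speeds <- function(rec) {
  n <- nrow(rec)
  if (n < 2) return(numeric(0))
  d_km <- great_circle_km(rec$lat[-n], rec$lon[-n], rec$lat[-1], rec$lon[-1])
  dt_s <- as.numeric(difftime(rec$timestamp[-1], rec$timestamp[-n], units = "secs"))
  ifelse(dt_s > 0, d_km * 1000 / dt_s, Inf)
}

#' Remove positions requiring unrealistic swimming speeds
#'
#' Iterative greedy filter: while any consecutive-pair implied speed exceeds
#' `v_max`, remove the single point whose removal most reduces the number of
#' violations (ties broken by the larger maximum adjacent implied speed,
#' then by the later timestamp), recomputing speeds after each removal.
#' The result satisfies the speed constraint exactly and the filter is
#' idempotent on its own output.
#'
#' @param track a [telemetry_track()]
#' @param v_max maximum plausible speed in m/s
#' @return the filtered track; removed points are appended to `filter_log`
#' @export
speed_filter <- function(track, v_max = 2.0) {
  rec <- track$records
  if (nrow(rec) < 2) return(track)
  removed <- list()
  repeat {
    sp <- implied_speeds(rec)
    bad <- which(sp > v_max)
    if (!length(bad)) break
    candidates <- sort(unique(c(bad, bad + 1)))
    n_viol <- vapply(candidates, function(i) {
      sum(implied_speeds(rec[-i, , drop = FALSE]) > v_max)
    }, numeric(1))
    best <- candidates[n_viol == min(n_viol)]
    if (length(best) > 1) {
      adj <- vapply(best, function(i) {
        max(c(if (i > 1) sp[i - 1], if (i <= length(sp)) sp[i]), na.rm = TRUE)
      }, numeric(1))
      best <- best[adj == max(adj)]
      best <- best[length(best)]   # later timestamp wins remaining ties
    }
    removed[[length(removed) + 1]] <- cbind(rec[best, , drop = FALSE],
                                            reason = "speed")
    rec <- rec[-best, , drop = FALSE]
    if (nrow(rec) == 0) stop("speed filter removed every position")
  }
  track$records <- rec
  track$filter_log <- rbind(track$filter_log, do.call(rbind, removed))
  track
}

#' Season of a timestamp
#'
#' Ice-bound: December-May; open-water: June-November (calendar months,
#' UTC).
#'
#' @param timestamp POSIXct (or coercible)
#' @return character vector `"ice_bound"` / `"open_water"`
#' @export
season_of <- function(timestamp) {
  m <- as.integer(format(as.POSIXct(timestamp, tz = "UTC"), "%m"))
  ifelse(m >= 6 & m <= 11, "open_water", "ice_bound")
}

#' Seasonal distance comparison with a permutation t-test
#'
#' Distances from the capture site are split into ice-bound and open-water
#' observations; the statistic is the absolute difference of seasonal mean
#' distances (permutation-equivalent to the t statistic under equal
#' variance) and the null permutes season labels over the track's
#' observations at fixed counts.  Seasonal means and maxima are reported
#' regardless; the p-value is `NA` when either season has no data.
#'
#' @param track a [telemetry_track()] (run [speed_filter()] first)
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return object of class `seasonal_comparison`
#' @export
seasonal_distance_test <- function(track, n_perm = 10000, seed = 1L) {
  rec <- track$records
  d <- great_circle_km(track$capture_site[1], track$capture_site[2],
                       rec$lat, rec$lon)
  season <- season_of(rec$timestamp)
  ice <- d[season == "ice_bound"]; open <- d[season == "open_water"]
  summ <- function(x) if (length(x)) c(mean = mean(x), max = max(x))
                      else c(mean = NA_real_, max = NA_real_)
  p <- NA_real_; obs <- NA_real_
  if (length(ice) >= 1 && length(open) >= 1) {
    obs <- abs(mean(open) - mean(ice))
    n_open <- length(open)
    b <- 0L
    withr::with_seed(sub_seed(seed, "season", track$animal_id), {
      for (r in seq_len(n_perm)) {
        idx <- sample.int(length(d), n_open)
        stat <- abs(mean(d[idx]) - mean(d[-idx]))
        if (stat >= obs - 1e-12) b <- b + 1L
      }
    })
    p <- perm_pvalue(b, n_perm)
  }
  structure(list(animal_id = track$animal_id,
                 ice_bound = c(summ(ice), n = length(ice)),
                 open_water = c(summ(open), n = length(open)),
                 statistic = obs, p = p, n_perm = n_perm, seed = seed),
            class = "seasonal_comparison")
}

#' @export
print.seasonal_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: ice-bound (mean %.1f, max %.1f, n=%d); open-water (mean %.1f, max %.1f, n=%d); p = %s\n",
    x$animal_id, x$ice_bound["mean"], x$ice_bound["max"], x$ice_bound["n"],
    x$open_water["mean"], x$open_water["max"], x$open_water["n"],
    ifelse(is.na(x$p), "NA", format(x$p, digits = 3))))
  invisible(x)
}

#' Circadian haulout summary from an hourly dry-time series
#'
#' For each complete day (at least `min_hours` of 24 hourly values) the
#' daily mid-range is `(min + max)/2`; the per-hour-of-day exceedance is
#' the fraction of days whose dry fraction at that hour strictly exceeds
#' that day's mid-range.  Also reports the per-hour mean and range across
#' days, the longest run of consecutive hours with dry fraction exactly 0
#' (the longest wet bout), and the minimum hourly dry time in minutes.
#'
#' @param series data frame with `timestamp` (hourly POSIXct) and
#'   `dry_fraction`
#' @param min_hours hourly values required for a day to count as complete
#' @return object of class `haulout_summary`
#' @export
haulout_summary <- function(series, min_hours = 20) {
  stopifnot(all(c("timestamp", "dry_fraction") %in% names(series)))
  ts <- parse_utc_times(series$timestamp)
  if (anyNA(ts)) stop("unparseable timestamps in haulout series")
  day <- format(ts, "%Y-%m-%d")
  hour <- as.integer(format(ts, "%H"))
  ok_days <- names(which(table(day) >= min_hours))
  if (!length(ok_days)) stop("no complete day (need >= %d hourly values)" |>
                               sprintf(min_hours))
  keep <- day %in% ok_days & !is.na(series$dry_fraction)
  df <- data.frame(day = day[keep], hour = hour[keep],
                   dry = series$dry_fraction[keep])
  midrange <- tapply(df$dry, df$day, function(x) (min(x) + max(x)) / 2)
  df$exceed <- df$dry > midrange[df$day] + 0  # strict inequality
  by_hour <- function(f) vapply(0:23, function(h) {
    x <- df[df$hour == h, , drop = FALSE]
    if (!nrow(x)) NA_real_ else f(x)
  }, numeric(1))
  exceedance <- by_hour(function(x) mean(x$exceed))
  mean_dry <- by_hour(function(x) mean(x$dry))
  range_dry <- by_hour(function(x) diff(range(x$dry)))
  # longest wet bout over the chronological series (complete days only)
  dry_seq <- df$dry[order(df$day, df$hour)]
  wet <- rle(dry_seq == 0)
  longest_wet <- if (any(wet$values)) max(wet$lengths[wet$values]) else 0L
  structure(list(hours = 0:23, exceedance = exceedance,
                 mean_dry = mean_dry, range_dry = range_dry,
                 longest_wet_bout_h = longest_wet,
                 min_dry_minutes = min(df$dry) * 60,
                 n_days = length(ok_days)),
            class = "haulout_summary")
}

#' @export
print.haulout_summary <- function(x, ...) {
  cat(sprintf("haulout_summary: %d complete days; longest wet bout %d h; min hourly dry %.0f min\n",
              x$n_days, x$longest_wet_bout_h, x$min_dry_minutes))
  invisible(x)
}

#' Monthly mean distance from the capture site, per animal
#'
#' @param tracks list of filtered [telemetry_track()] objects
#' @return data frame `animal_id, month (yyyy-mm), n, mean_distance_km`;
#'   months with no data are absent
#' @export
monthly_localization <- function(tracks) {
  if (inherits(tracks, "telemetry_track")) tracks <- list(tracks)
  do.call(rbind, lapply(tracks, function(tr) {
    d <- great_circle_km(tr$capture_site[1], tr$capture_site[2],
                         tr$records$lat, tr$records$lon)
    mon <- format(tr$records$timestamp, "%Y-%m")
    agg <- tapply(d, mon, mean)
    data.frame(animal_id = tr$animal_id, month = names(agg),
               n = as.integer(table(mon)[names(agg)]),
               mean_distance_km = as.numeric(agg), row.names = NULL)
  }))
}
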
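#' Satellite telemetry track for one animal
#'
#' Timestamped positions plus the capture-site anchor from which
#' distance-from-breeding-site series are measured.  Records are sorted by
#' time at construction; duplicate timestamps are collapsed to the first
#' occurrence with a warning.
#'
#' @param animal_id identifier
#' @param records data frame with columns `timestamp` (POSIXct, UTC),
#'   `lat`, `lon` and optionally `dry_fraction` in `[0,1]`
#' @param capture_site `c(lat, lon)`; defaults to the first position
#' @param meta optional named list (sex, age, ...)
#' @return object of class `telemetry_track`
#' @export
telemetry_track <- function(animal_id, records, capture_site = NULL, meta = list()) {
  stopifnot(all(c("timestamp", "lat", "lon") %in% names(records)))
  if (!inherits(records$timestamp, "POSIXct")) {
    records$timestamp <- as.POSIXct(records$timestamp, tz = "UTC")
  }
  attr(records$timestamp, "tzone") <- "UTC"
  if (any(is.na(records$timestamp))) stop("unparseable timestamp in track")
  if (any(abs(records$lat) > 90, na.rm = TRUE)) stop("latitude out of range [-90, 90]")
  if (any(abs(records$lon) > 180, na.rm = TRUE)) stop("longitude out of range [-180, 180]")
  records <- records[order(records$timestamp), , drop = FALSE]
  dup <- duplicated(records$timestamp)
  if (any(dup)) {
    warning(sprintf("track %s: %d duplicate timestamps collapsed to first occurrence",
                    animal_id, sum(dup)))
    records <- records[!dup, , drop = FALSE]
  }
  rownames(records) <- NULL
  if (is.null(capture_site)) capture_site <- c(records$lat[1], records$lon[1])
  if (!"dry_fraction" %in% names(records)) records$dry_fraction <- NA_real_
  if (any(records$dry_fraction < 0 | records$dry_fraction > 1, na.rm = TRUE)) {
    stop("dry_fraction must lie in [0, 1]")
  }
  structure(list(animal_id = as.character(animal_id),
                 capture_site = as.numeric(capture_site),
                 records = records, meta = meta,
                 filter_log = data.frame()),
            class = "telemetry_track")
}

#' @export
print.telemetry_track <- function(x, ...) {
  cat(sprintf("telemetry_track %s: %d records, %s to %s\n", x$animal_id,
              nrow(x$records),
              format(min(x$records$timestamp)), format(max(x$records$timestamp))))
  invisible(x)
}

#' Read a telemetry CSV into per-animal tracks
#'
#' Expects columns `animal_id,timestamp,lat,lon[,dry_fraction]` with
#' ISO-8601 timestamps interpreted as UTC.  Rows are assigned to one track
#' per animal and time-sorted, so row order in the file is immaterial.  In
#' strict mode (default) an unparseable timestamp or out-of-range coordinate
#' aborts with a row-level message; in lenient mode offending rows are
#' dropped with a warning listing them.
#'
#' @param path CSV path
#' @param lenient drop bad rows instead of erroring
#' @return named list of [telemetry_track()] objects
#' @export
read_telemetry_csv <- function(path, lenient = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("animal_id", "timestamp", "lat", "lon") %in% names(df)))
  ts <- parse_utc_times(df$timestamp)
  bad <- is.na(ts) | !is.finite(df$lat) | !is.finite(df$lon) |
    abs(df$lat) > 90 | abs(df$lon) > 180
  if (any(bad)) {
    msg <- sprintf("rows with invalid timestamp/coordinates: %s",
                   paste(which(bad), collapse = ", "))
    if (!lenient) stop(msg)
    warning(paste("dropped", msg))
    df <- df[!bad, , drop = FALSE]
    ts <- ts[!bad]
  }
  df$timestamp <- ts
  lapply(split(df, df$animal_id), function(d) {
    telemetry_track(d$animal_id[1],
                    d[, intersect(c("timestamp", "lat", "lon", "dry_fraction"),
                                  names(d)), drop = FALSE])
  })
}

#' Write telemetry tracks to CSV
#'
#' @param tracks list of [telemetry_track()] objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_telemetry_csv <- function(tracks, path) {
  if (inherits(tracks, "telemetry_track")) tracks <- list(tracks)
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(animal_id = tr$animal_id,
               timestamp = format(tr$records$timestamp, "%Y-%m-%dT%H:%M:%S"),
               lat = tr$records$lat, lon = tr$records$lon,
               dry_fraction = tr$records$dry_fraction)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
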
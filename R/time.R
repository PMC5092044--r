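#' Raw-file dialect
#'
#' Describes how timestamps and columns are laid out in raw antenna log
#' files. Acquisition software in the field writes tab-separated columns
#' but the on-disk date format varies between installations, so the
#' dialect is configurable; the default matches the `DD.MM.YYYY` dates
#' used by experiment phase configuration files.
#'
#' @param date_format `strptime()`-style format of the date column.
#'   Default `"%d.%m.%Y"`.
#' @param fields Order of the columns in a raw line. Must be a permutation
#'   of `c("event", "date", "time", "antenna", "duration", "tag", "name")`
#'   with `"name"` last (the name column is optional per line).
#' @param file_pattern `sprintf()` pattern for hourly file names, receiving
#'   the file prefix and the `YYYYMMDD_HH` hour stamp.
#'
#' @return A list of class `ecohab_dialect`.
#' @examples
#' eh_dialect()
#' eh_dialect(date_format = "%Y-%m-%d")
#' @export
eh_dialect <- function(date_format = "%d.%m.%Y",
                       fields = c("event", "date", "time", "antenna",
                                  "duration", "tag", "name"),
                       file_pattern = "%s_%s.txt") {
  canonical <- c("event", "date", "time", "antenna", "duration", "tag", "name")
  if (!identical(sort(fields), sort(canonical))) {
    abort("`fields` must be a permutation of the seven raw-log columns.")
  }
  if (fields[7L] != "name") {
    abort("the optional `name` column must come last in `fields`.")
  }
  structure(
    list(date_format = date_format, fields = fields,
         file_pattern = file_pattern),
    class = "ecohab_dialect"
  )
}

# Millisecond-exact timestamp handling. Internally a timestamp is a POSIXct
# (UTC), i.e. a double of seconds since the epoch; at 2015-scale magnitudes a
# double resolves ~0.5 us, so milliseconds are safe provided we always
# reconstruct the integer millisecond by rounding rather than truncation.

eh_origin <- as.POSIXct("1970-01-01", tz = "UTC")

#' @keywords internal
#' @noRd
eh_parse_timestamp <- function(date, time, dialect = eh_dialect()) {
  day <- as.POSIXct(strptime(date, dialect$date_format, tz = "UTC"))
  m <- stringr::str_match(time, "^(\\d{1,2}):(\\d{2})(?::(\\d{2})(?:\\.(\\d{1,3}))?)?$")
  bad <- is.na(day) | is.na(m[, 2L])
  if (any(bad)) {
    abort(sprintf("unparseable date/time '%s %s'",
                  date[which(bad)[1L]], time[which(bad)[1L]]))
  }
  ms <- m[, 5L]
  ms <- ifelse(is.na(ms), 0, as.numeric(stringr::str_pad(ms, 3, "right", "0")))
  secs <- as.numeric(day) +
    3600 * as.numeric(m[, 2L]) + 60 * as.numeric(m[, 3L]) +
    ifelse(is.na(m[, 4L]), 0, as.numeric(m[, 4L])) + ms / 1000
  as.POSIXct(secs, origin = eh_origin, tz = "UTC")
}

# Split a POSIXct into (whole seconds, integer milliseconds), carrying over
# rounding at the 1000 ms boundary.
eh_split_ms <- function(t) {
  s <- as.numeric(t)
  whole <- floor(s)
  ms <- round((s - whole) * 1000)
  carry <- ms >= 1000
  whole[carry] <- whole[carry] + 1
  ms[carry] <- 0
  list(whole = whole, ms = as.integer(ms))
}

#' @keywords internal
#' @noRd
eh_format_timestamp <- function(t, dialect = eh_dialect()) {
  p <- eh_split_ms(t)
  at <- as.POSIXct(p$whole, origin = eh_origin, tz = "UTC")
  list(date = format(at, dialect$date_format),
       time = sprintf("%s.%03d", format(at, "%H:%M:%S"), p$ms))
}

#' Construct a half-open time interval
#'
#' Intervals are half-open, `[start, end)`, everywhere in the package so
#' that adjacent analysis windows never double-count an instant.
#'
#' @param start,end Interval bounds as `POSIXct`, or anything
#'   `as.POSIXct()` accepts (parsed in UTC). `end` must be strictly later.
#' @return A length-2 `POSIXct` vector of class `ecohab_interval`.
#' @examples
#' eh_interval("2015-02-16 12:00:00", "2015-02-17 00:00:00")
#' @export
eh_interval <- function(start, end) {
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end)) {
    abort("`start` and `end` must be single, valid timestamps.")
  }
  if (!(end > start)) abort("interval end must be strictly after its start.")
  structure(c(start, end), class = c("ecohab_interval", "POSIXct", "POSIXt"))
}

# Coerce c(start, end) / interval into validated interval.
eh_as_interval <- function(iv) {
  if (inherits(iv, "ecohab_interval")) return(iv)
  if (length(iv) != 2L) abort("an interval is a length-2 (start, end) vector.")
  eh_interval(iv[[1L]], iv[[2L]])
}

eh_interval_length <- function(iv) as.numeric(iv[[2L]]) - as.numeric(iv[[1L]])
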
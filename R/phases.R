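#' Parse an experiment phase configuration
#'
#' Experiments are divided into named phases (adaptation dark/light
#' phases, stimulus presentation, ...) declared in an INI-style text file,
#' one section per phase:
#'
#' ```
#' [ADAPTATION - 1. dark phase]
#' startdate = 16.02.2015
#' starttime = 12:00
#' enddate = 17.02.2015
#' endtime = 00:00
#' ```
#'
#' @param text A file path, or the configuration content as a character
#'   scalar/vector of lines.
#' @param date_format `strptime()` format of the date keys; default
#'   `DD.MM.YYYY` as conventionally written.
#' @return A tibble with columns `phase`, `start`, `end` (`POSIXct`, UTC),
#'   one row per section, names unique; phases may overlap in time.
#' @examples
#' read_phase_config(c(
#'   "[ADAPTATION - 1. dark phase]",
#'   "startdate = 16.02.2015", "starttime = 12:00",
#'   "enddate = 17.02.2015", "endtime = 00:00"
#' ))
#' @export
read_phase_config <- function(text, date_format = "%d.%m.%Y") {
  lines <- if (length(text) == 1L && file.exists(text)) {
    readLines(text, warn = FALSE)
  } else if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    text
  }
  lines <- trimws(sub("\r$", "", lines))
  lines <- lines[lines != "" & !startsWith(lines, "#") & !startsWith(lines, ";")]
  if (length(lines) == 0L) {
    return(tibble::tibble(phase = character(), start = eh_origin[0],
                          end = eh_origin[0]))
  }
  is_header <- grepl("^\\[.*\\]$", lines)
  if (!is_header[1L]) abort("phase config must start with a [section] header.")
  section <- cumsum(is_header)
  names_ <- sub("^\\[(.*)\\]$", "\\1", lines[is_header])
  if (anyDuplicated(names_)) {
    abort(sprintf("duplicate phase name: '%s'", names_[duplicated(names_)][1L]))
  }
  get_key <- function(sec_lines, key, section_name) {
    hit <- grep(paste0("^", key, "\\s*="), sec_lines, value = TRUE)
    if (length(hit) != 1L) {
      abort(sprintf("phase '%s': missing key '%s'", section_name, key))
    }
    trimws(sub("^[^=]*=", "", hit[1L]))
  }
  bodies <- split(lines[!is_header],
                  factor(section[!is_header], levels = seq_along(names_)))
  phases <- purrr::map2(bodies, names_, function(body, nm) {
    start <- eh_parse_timestamp(get_key(body, "startdate", nm),
                                get_key(body, "starttime", nm),
                                eh_dialect(date_format = date_format))
    end <- eh_parse_timestamp(get_key(body, "enddate", nm),
                              get_key(body, "endtime", nm),
                              eh_dialect(date_format = date_format))
    if (!(end > start)) {
      abort(sprintf("phase '%s': end is not after start", nm))
    }
    tibble::tibble(phase = nm, start = start, end = end)
  })
  dplyr::bind_rows(phases)
}

#' Resolve a phase name to its interval
#'
#' @param phases A phase tibble from [read_phase_config()].
#' @param name A phase name.
#' @return An [eh_interval()].
#' @export
phase_interval <- function(phases, name) {
  i <- match(name, phases$phase)
  if (is.na(i)) abort(sprintf("unknown phase: '%s'", name))
  eh_interval(phases$start[i], phases$end[i])
}

#' Restrict sessions to a time window
#'
#' Two masking modes are offered. `"clip"` (the default for every
#' duration-bearing measure) keeps sessions overlapping the half-open
#' window `[start, end)` and truncates them to it, so that partitioning a
#' span into consecutive windows conserves total time. `"start_based"`
#' keeps, unmodified, exactly those sessions that start inside the window
#' — the behavior of the original analysis scripts, retained for
#' comparability; it drops or over-counts time straddling the boundary.
#'
#' @param sessions A session tibble.
#' @param interval An [eh_interval()] or `c(start, end)` pair.
#' @param mode `"clip"` or `"start_based"`.
#' @return The masked session tibble (durations recomputed under
#'   `"clip"`).
#' @export
mask_sessions <- function(sessions, interval,
                          mode = c("clip", "start_based")) {
  mode <- match.arg(mode)
  iv <- eh_as_interval(interval)
  t1 <- as.numeric(iv[[1L]]); t2 <- as.numeric(iv[[2L]])
  s <- as.numeric(sessions$start); e <- as.numeric(sessions$end)
  if (mode == "start_based") {
    return(sessions[s >= t1 & s < t2, , drop = FALSE])
  }
  keep <- e > t1 & s < t2
  out <- sessions[keep, , drop = FALSE]
  ns <- pmax(as.numeric(out$start), t1)
  ne <- pmin(as.numeric(out$end), t2)
  out$start <- as.POSIXct(ns, origin = eh_origin, tz = "UTC")
  out$end <- as.POSIXct(ne, origin = eh_origin, tz = "UTC")
  out$duration <- ne - ns
  out
}

#' Subtract exclusion windows from an analysis interval
#'
#' Corrupted recording segments are declared by the experimenter as
#' exclusion intervals; this helper removes them from an analysis window,
#' returning the remaining sub-intervals so measures can be computed on
#' clean time only.
#'
#' @param interval The analysis [eh_interval()].
#' @param exclusions A list of intervals (each an [eh_interval()] or
#'   `c(start, end)`).
#' @return A list of disjoint intervals covering the clean remainder.
#' @export
subtract_exclusions <- function(interval, exclusions) {
  iv <- eh_as_interval(interval)
  segs <- list(c(as.numeric(iv[[1L]]), as.numeric(iv[[2L]])))
  for (ex in exclusions) {
    ex <- eh_as_interval(ex)
    x1 <- as.numeric(ex[[1L]]); x2 <- as.numeric(ex[[2L]])
    segs <- purrr::list_flatten(purrr::map(segs, function(s) {
      pieces <- list()
      if (s[1L] < x1) pieces <- c(pieces, list(c(s[1L], min(s[2L], x1))))
      if (s[2L] > x2) pieces <- c(pieces, list(c(max(s[1L], x2), s[2L])))
      pieces
    }))
  }
  purrr::map(segs, function(s) {
    eh_interval(as.POSIXct(s[1L], origin = eh_origin, tz = "UTC"),
                as.POSIXct(s[2L], origin = eh_origin, tz = "UTC"))
  })
}
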
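#' Parse raw antenna log lines
#'
#' A raw log is plain text with tab-separated columns, one antenna
#' detection per line: event number, date, time (ms resolution), antenna
#' number, transponder read-out duration (ms), the unique 14-digit
#' transponder code, and an optional tag name. Lines with six fields carry
#' no tag name.
#'
#' @param text A character scalar holding file content, or a character
#'   vector of lines.
#' @param dialect An [eh_dialect()] describing date format and column
#'   order.
#' @return A tibble with one row per detection and columns `event`
#'   (integer), `time` (`POSIXct`, UTC, millisecond resolution), `antenna`
#'   (integer), `duration` (ms), `tag` (14-digit character code), `name`
#'   (character, `NA` when absent) and `mouse` (`name` when present,
#'   otherwise `tag`).
#' @examples
#' parse_raw_events(
#'   "17\t16.02.2015\t12:00:03.250\t3\t120\t90001020000123\tmouseA"
#' )
#' @export
parse_raw_events <- function(text, dialect = eh_dialect()) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    text
  }
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*$", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(eh_empty_events())

  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- nf != 6L & nf != 7L
  if (any(bad)) {
    i <- which(bad)[1L]
    abort(sprintf("line %d: expected 6 or 7 tab-separated fields, found %d",
                  line_no[i], nf[i]))
  }
  get <- function(field) {
    j <- match(field, dialect$fields)
    vapply(parts, function(p) if (j <= length(p)) p[[j]] else NA_character_,
           character(1))
  }
  event <- suppressWarnings(as.integer(get("event")))
  antenna <- suppressWarnings(as.integer(get("antenna")))
  duration <- suppressWarnings(as.numeric(get("duration")))
  tag <- get("tag")
  name <- get("name")
  name[!is.na(name) & name == ""] <- NA_character_

  for (fld in list(list(event, "event number"), list(antenna, "antenna"),
                   list(duration, "read-out duration"))) {
    if (anyNA(fld[[1L]])) {
      abort(sprintf("line %d: malformed %s field",
                    line_no[which(is.na(fld[[1L]]))[1L]], fld[[2L]]))
    }
  }
  if (any(duration < 0)) {
    abort(sprintf("line %d: negative read-out duration",
                  line_no[which(duration < 0)[1L]]))
  }
  ok_tag <- grepl("^\\d{14}$", tag)
  if (!all(ok_tag)) {
    abort(sprintf("line %d: transponder code '%s' is not a 14-digit string",
                  line_no[which(!ok_tag)[1L]], tag[which(!ok_tag)[1L]]))
  }
  time <- eh_parse_timestamp(get("date"), get("time"), dialect)
  tibble::tibble(
    event = event, time = time, antenna = antenna, duration = duration,
    tag = tag, name = name, mouse = dplyr::coalesce(name, tag)
  )
}

eh_empty_events <- function() {
  tibble::tibble(
    event = integer(), time = eh_origin[0], antenna = integer(),
    duration = numeric(), tag = character(), name = character(),
    mouse = character()
  )
}

#' Load and merge raw antenna log files
#'
#' Reads one or more raw log files (or every `*.txt` file in a directory),
#' merges them into a single chronologically sorted event log, drops exact
#' duplicate records, and resolves tag names from an optional registry.
#' Near-duplicates from antenna read bursts are deliberately kept: they are
#' eliminated downstream by the sessionizer's inter-event threshold.
#'
#' @param path Character vector of file paths, or a single directory.
#' @param registry Optional tag registry from [read_tag_registry()]; its
#'   names override names present in the files.
#' @inheritParams parse_raw_events
#' @return An event tibble as documented in [parse_raw_events()], sorted by
#'   `time` with ties broken by `(antenna, event)`.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' ev <- parse_raw_events(
#'   "1\t16.02.2015\t12:00:03.250\t3\t120\t90001020000123"
#' )
#' write_events(ev, dir)
#' read_events(dir)
#' @export
read_events <- function(path, dialect = eh_dialect(), registry = NULL) {
  if (length(path) == 1L && dir.exists(path)) {
    path <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
  }
  if (length(path) == 0L) abort("no raw log files to load.")
  missing <- path[!file.exists(path)]
  if (length(missing) > 0L) {
    abort(sprintf("raw log file not found: %s", missing[1L]))
  }
  events <- purrr::map(path, function(f) {
    parse_raw_events(readLines(f, warn = FALSE), dialect)
  })
  events <- dplyr::bind_rows(events)
  if (nrow(events) == 0L) return(eh_empty_events())
  # identity of an event is (time, antenna, tag): event numbers restart per
  # file and must not distinguish otherwise identical physical records
  events <- dplyr::distinct(events, .data$time, .data$antenna, .data$tag,
                            .keep_all = TRUE)
  events <- events[order(as.numeric(events$time), events$antenna,
                         events$event), , drop = FALSE]
  if (!is.null(registry)) {
    idx <- match(events$tag, registry$tag)
    events$name <- ifelse(is.na(idx), events$name, registry$name[idx])
    events$mouse <- dplyr::coalesce(events$name, events$tag)
  }
  events
}

#' Write an event log as hourly raw files
#'
#' Partitions events at wall-clock hour boundaries (one output file per
#' hour of operation, matching the acquisition convention), re-sequences
#' event numbers from 1 within each file, and writes tab-separated lines
#' byte-compatible with [parse_raw_events()].
#'
#' @param events An event tibble.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; files are named
#'   `<prefix>_YYYYMMDD_HH.txt`.
#' @inheritParams parse_raw_events
#' @return Invisibly, the paths written.
#' @export
write_events <- function(events, dir, prefix = "ecohab",
                         dialect = eh_dialect()) {
  if (nrow(events) == 0L) abort("refusing to write an empty event log.")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hour <- floor(as.numeric(events$time) / 3600)
  paths <- character(0)
  for (h in sort(unique(hour))) {
    chunk <- events[hour == h, , drop = FALSE]
    stamp <- format(as.POSIXct(h * 3600, origin = eh_origin, tz = "UTC"),
                    "%Y%m%d_%H")
    ts <- eh_format_timestamp(chunk$time, dialect)
    cols <- list(event = as.character(seq_len(nrow(chunk))),
                 date = ts$date, time = ts$time,
                 antenna = as.character(chunk$antenna),
                 duration = format(chunk$duration, trim = TRUE,
                                   scientific = FALSE),
                 tag = chunk$tag, name = chunk$name)
    m <- do.call(cbind, cols[dialect$fields])
    lines <- apply(m, 1L, function(r) {
      paste(if (is.na(r[["name"]])) r[-7L] else r, collapse = "\t")
    })
    path <- file.path(dir, sprintf(dialect$file_pattern, prefix, stamp))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a transponder tag registry
#'
#' A registry maps 14-digit transponder codes to short tag names, one
#' `code<TAB>name` pair per line (the `rfid_tags.txt` convention).
#'
#' @param path A file path, or a character vector of lines.
#' @return A tibble with columns `tag` and `name`; codes are unique.
#' @examples
#' read_tag_registry("90001020000123\tmouseA")
#' @export
read_tag_registry <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else if (length(path) == 1L && grepl("\n", path, fixed = TRUE)) {
    strsplit(path, "\n", fixed = TRUE)[[1L]]
  } else {
    path
  }
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(tag = character(), name = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    abort(sprintf("malformed registry line: '%s'",
                  lines[which(lengths(parts) != 2L)[1L]]))
  }
  tag <- vapply(parts, `[[`, character(1), 1L)
  name <- vapply(parts, `[[`, character(1), 2L)
  if (!all(grepl("^\\d{14}$", tag))) {
    abort("registry codes must be 14-digit strings.")
  }
  dup <- duplicated(tag)
  if (any(dup)) {
    abort(sprintf("duplicate transponder code in registry: %s", tag[dup][1L]))
  }
  tibble::tibble(tag = tag, name = name)
}
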
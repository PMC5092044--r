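#' Standard four-compartment ring topology
#'
#' The apparatus is a ring of four housing compartments bridged by four
#' tube corridors; each corridor carries two antennas, one at each end,
#' and an antenna's "nearest compartment" is the compartment at its end of
#' the corridor. The standard numbering places corridor `k` between
#' compartments `k` and `(k mod 4) + 1`, with antennas `2k - 1` and `2k`
#' nearest those two compartments respectively. Physical installations may
#' wire antennas differently, so topologies can also be read from a file
#' ([read_topology()]); the numbering here is the package's tested default.
#'
#' @return A tibble of class `ecohab_topology` with one row per antenna and
#'   columns `antenna`, `corridor`, `compartment` (the nearest
#'   compartment).
#' @examples
#' standard_topology()
#' @export
standard_topology <- function() {
  k <- rep(1:4, each = 2)
  top <- tibble::tibble(
    antenna = 1:8,
    corridor = k,
    compartment = as.integer(ifelse(1:8 %% 2 == 1, k, k %% 4 + 1))
  )
  validate_topology(top)
}

#' Read a topology file
#'
#' A topology file is a small tab-separated table with a header line and
#' columns `antenna`, `corridor`, `compartment`, one row per antenna.
#'
#' @param path Path to the file.
#' @return A validated `ecohab_topology` tibble.
#' @export
read_topology <- function(path) {
  top <- readr::read_tsv(path, col_types = readr::cols(
    antenna = readr::col_integer(), corridor = readr::col_integer(),
    compartment = readr::col_integer()
  ))
  validate_topology(top)
}

#' Validate a topology
#'
#' Checks the structural invariants of the apparatus graph: four
#' compartments and four corridors forming a single cycle, two antennas
#' per corridor with distinct nearest compartments, and two antennas per
#' compartment.
#'
#' @param top A tibble with columns `antenna`, `corridor`, `compartment`.
#' @return `top`, classed `ecohab_topology`, invisibly usable downstream.
#' @export
validate_topology <- function(top) {
  need <- c("antenna", "corridor", "compartment")
  if (!all(need %in% names(top))) {
    abort("topology needs columns antenna, corridor, compartment.")
  }
  if (anyDuplicated(top$antenna)) abort("duplicate antenna id in topology.")
  per_corr <- table(top$corridor)
  if (any(per_corr != 2L)) {
    abort("each corridor must carry exactly 2 antennas.")
  }
  ends <- dplyr::summarise(dplyr::group_by(top, .data$corridor),
                           n_comp = dplyr::n_distinct(.data$compartment))
  if (any(ends$n_comp != 2L)) {
    abort("a corridor's two antennas must have distinct nearest compartments.")
  }
  per_comp <- table(top$compartment)
  if (any(per_comp != 2L)) {
    abort("each compartment must be nearest to exactly 2 antennas.")
  }
  # the compartment-corridor incidence must form one cycle: treat corridors
  # as edges between their endpoint compartments and check a single
  # connected 2-regular graph
  edges <- dplyr::summarise(dplyr::group_by(top, .data$corridor),
                            a = min(.data$compartment),
                            b = max(.data$compartment))
  adj <- split(c(edges$b, edges$a), c(edges$a, edges$b))
  seen <- new.env()
  walk <- function(v) {
    if (!is.null(seen[[as.character(v)]])) return(invisible())
    seen[[as.character(v)]] <- TRUE
    for (w in adj[[as.character(v)]]) walk(w)
  }
  walk(edges$a[[1L]])
  if (length(ls(seen)) != length(unique(top$compartment))) {
    abort("topology graph must be a single cycle of compartments.")
  }
  class(top) <- unique(c("ecohab_topology", class(top)))
  top
}

#' Classify an antenna pair geometrically
#'
#' For two antenna detections the geometric relation of the antennas
#' decides what the intervening time means: the same antenna (the mouse
#' entered and left a compartment through one corridor), two antennas of
#' one corridor (a pass through the corridor), antennas of two different
#' corridors sharing a nearest compartment (a stay in that compartment),
#' or antennas of opposite corridors sharing no compartment (at least two
#' crossings went undetected, so no location can be assigned).
#'
#' @param top An `ecohab_topology`.
#' @param a1,a2 Integer antenna ids, vectorized and recycled.
#' @return A tibble with columns `category` (one of `same_antenna`,
#'   `same_corridor`, `shared_compartment`, `opposite`) and `compartment`
#'   (the shared/nearest compartment where defined, otherwise `NA`).
#' @examples
#' relate_antennas(standard_topology(), c(3, 1, 2, 1), c(3, 2, 3, 5))
#' @export
relate_antennas <- function(top, a1, a2) {
  n <- max(length(a1), length(a2))
  a1 <- rep_len(as.integer(a1), n)
  a2 <- rep_len(as.integer(a2), n)
  i1 <- match(a1, top$antenna)
  i2 <- match(a2, top$antenna)
  if (anyNA(i1) || anyNA(i2)) {
    abort(sprintf("unknown antenna id: %s",
                  c(a1[is.na(i1)], a2[is.na(i2)])[1L]))
  }
  same_ant <- a1 == a2
  same_corr <- !same_ant & top$corridor[i1] == top$corridor[i2]
  shared <- !same_ant & !same_corr &
    top$compartment[i1] == top$compartment[i2]
  category <- dplyr::case_when(
    same_ant ~ "same_antenna",
    same_corr ~ "same_corridor",
    shared ~ "shared_compartment",
    TRUE ~ "opposite"
  )
  tibble::tibble(
    category = category,
    compartment = ifelse(same_ant | shared, top$compartment[i1], NA_integer_)
  )
}
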
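#' Cohort sociability matrix
#'
#' Computes [in_cohort_sociability()] for every unordered pair of a cohort
#' over a window and wraps the result for matrix display, histogram export
#' and tidying.
#'
#' @inheritParams in_cohort_sociability
#' @return An object of class `ecohab_sociability`: a list with `scores`
#'   (the pair tibble), `mice`, and `interval`. Methods: [tidy()] returns
#'   the pair scores, [glance()] a one-row cohort summary, [autoplot()]
#'   the pair-matrix heat map, `as.matrix()` the symmetric score matrix
#'   (diagonal `NA`).
#' @examples
#' cfg <- sim_config(n_mice = 3, duration = 1800)
#' traj <- simulate_cohort(cfg, seed = 1)
#' ev <- emit_events(traj, seed = 2)
#' s <- reconstruct_sessions(ev)
#' sm <- sociability_matrix(s, attr(traj, "span"))
#' tidy(sm)
#' glance(sm)
#' @export
sociability_matrix <- function(sessions, interval, mice = NULL,
                               compartments = 1:4) {
  iv <- eh_as_interval(interval)
  mice <- eh_mice_of(sessions, mice)
  if (length(mice) < 2L) abort("a sociability matrix needs at least 2 mice.")
  scores <- in_cohort_sociability(sessions, iv, mice = mice,
                                  compartments = compartments)
  structure(list(scores = scores, mice = mice, interval = iv),
            class = "ecohab_sociability")
}

#' @export
print.ecohab_sociability <- function(x, ...) {
  cat(sprintf("In-cohort sociability: %d mice, %d pairs, window %s -- %s\n",
              length(x$mice), nrow(x$scores),
              format(x$interval[[1L]], "%Y-%m-%d %H:%M:%S"),
              format(x$interval[[2L]], "%Y-%m-%d %H:%M:%S")))
  print(x$scores, ...)
  invisible(x)
}

#' @export
as.matrix.ecohab_sociability <- function(x, ...) {
  m <- matrix(NA_real_, length(x$mice), length(x$mice),
              dimnames = list(x$mice, x$mice))
  i <- match(x$scores$mouse_a, x$mice)
  j <- match(x$scores$mouse_b, x$mice)
  m[cbind(i, j)] <- x$scores$sociability
  m[cbind(j, i)] <- x$scores$sociability
  m
}

#' @rdname sociability_matrix
#' @param x An `ecohab_sociability` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ecohab_sociability <- function(x, ...) x$scores

#' @rdname sociability_matrix
#' @exportS3Method generics::glance
glance.ecohab_sociability <- function(x, ...) {
  s <- x$scores$sociability
  tibble::tibble(
    n_mice = length(x$mice), n_pairs = length(s),
    mean_sociability = mean(s), sd_sociability = stats::sd(s),
    min_sociability = min(s), max_sociability = max(s)
  )
}

#' @rdname sociability_matrix
#' @param object An `ecohab_sociability` object.
#' @exportS3Method ggplot2::autoplot
autoplot.ecohab_sociability <- function(object, ...) {
  d <- dplyr::bind_rows(
    object$scores,
    dplyr::rename(object$scores, mouse_a = "mouse_b", mouse_b = "mouse_a")
  )
  d$mouse_a <- factor(d$mouse_a, levels = object$mice)
  d$mouse_b <- factor(d$mouse_b, levels = rev(object$mice))
  ggplot2::ggplot(d, ggplot2::aes(.data$mouse_a, .data$mouse_b,
                                  fill = .data$sociability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "sociability",
                  title = "In-cohort sociability") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Histogram of pair sociability scores
#'
#' The distribution of in-cohort sociability over all pairs of one or
#' more cohorts, the standard way to compare groups.
#'
#' @param ... Named `ecohab_sociability` objects (names label the
#'   groups).
#' @param binwidth Histogram bin width; default 0.005.
#' @return A ggplot object.
#' @export
plot_sociability_histogram <- function(..., binwidth = 0.005) {
  objs <- list(...)
  if (is.null(names(objs)) || any(names(objs) == "")) {
    names(objs) <- paste0("cohort", seq_along(objs))
  }
  d <- purrr::imap(objs, function(o, nm) {
    tibble::tibble(group = nm, sociability = o$scores$sociability)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(d, ggplot2::aes(.data$sociability, fill = .data$group)) +
    ggplot2::geom_histogram(binwidth = binwidth, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "in-cohort sociability", y = "pairs") +
    ggplot2::theme_minimal()
}

#' Per-mouse occupancy bar plot
#'
#' @param occ An occupancy tibble from [occupancy()].
#' @return A ggplot object.
#' @export
plot_occupancy <- function(occ) {
  ggplot2::ggplot(occ, ggplot2::aes(factor(.data$compartment),
                                    .data$time_frac)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~mouse) +
    ggplot2::labs(x = "compartment", y = "occupancy fraction") +
    ggplot2::theme_minimal()
}
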
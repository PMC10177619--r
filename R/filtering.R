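#' Maximum lifespan of a persistence diagram
#'
#' The largest `death - birth` over the diagram's points; by convention 0
#' for an empty diagram. Essential (infinite-death) pairs are not allowed:
#' lifespan-based filtering is defined on finite pairs only.
#'
#' @param pd A persistence diagram tibble with `birth` and `death` columns.
#' @return A single non-negative number.
#' @examples
#' pd <- tibble::tibble(dim = 1L, birth = c(120, 150), death = c(210, 185))
#' max_lifespan(pd)  # 90
#' @export
max_lifespan <- function(pd) {
  check_pd(pd)
  if (nrow(pd) == 0L) return(0)
  if (any(is.infinite(pd$death))) {
    stop("diagram contains essential (infinite-death) pairs; ",
         "drop them before lifespan filtering", call. = FALSE)
  }
  max(pd$death - pd$birth)
}

#' Filter a persistence diagram by fraction of its maximum lifespan
#'
#' Multi-level noise filtering of persistence diagrams: points whose
#' lifespan is not strictly greater than `level * max_lifespan(pd)` are
#' removed as noise. The maximum lifespan is always taken from the input
#' diagram, and the inequality is strict, so `level = 0` is the identity on
#' any diagram (every lifespan is positive) and a point exactly at the
#' threshold is dropped.
#'
#' @param pd A persistence diagram tibble (finite pairs only).
#' @param level A single filter fraction in `[0, 1)`; e.g. `0.2` keeps the
#'   points with lifespan greater than 20% of the maximum.
#' @return The filtered diagram tibble (possibly zero rows).
#' @examples
#' pd <- tibble::tibble(dim = 1L, birth = 0, death = c(10, 5, 2, 1))
#' filter_diagram(pd, 0.2)  # keeps lifespans 10 and 5
#' @export
filter_diagram <- function(pd, level) {
  check_pd(pd)
  check_level(level)
  if (nrow(pd) == 0L) return(pd)
  thr <- level * max_lifespan(pd)
  pd[(pd$death - pd$birth) > thr, , drop = FALSE]
}

#' Filter a diagram at several levels at once
#'
#' Applies [filter_diagram()] to the *original* diagram at each level (the
#' levels are not cascaded) and stacks the results, recording the surviving
#' Betti count per level. Because every level thresholds the same maximum
#' lifespan, the retained sets are nested and the Betti counts are
#' non-increasing in the level.
#'
#' @param pd A persistence diagram tibble (finite pairs only).
#' @param levels Ascending filter fractions in `[0, 1)`; default
#'   `c(0, 0.1, 0.2, 0.3, 0.4, 0.5)` (0 = no filtering).
#' @return A tibble of the surviving points with a leading `filter_level`
#'   column; one block per level.
#' @seealso [betti_by_level()] for just the per-level counts.
#' @export
multi_level_filter <- function(pd, levels = c(0, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  check_pd(pd)
  for (f in levels) check_level(f)
  if (is.unsorted(levels)) {
    stop("`levels` must be sorted ascending", call. = FALSE)
  }
  purrr::map_dfr(levels, function(f) {
    out <- filter_diagram(pd, f)
    dplyr::bind_cols(tibble(filter_level = rep(f, nrow(out))), out)
  })
}

#' Betti count per filter level
#'
#' @param pd A persistence diagram tibble (finite pairs only).
#' @param levels Filter fractions as in [multi_level_filter()].
#' @return A tibble with columns `filter_level` and `betti`.
#' @export
betti_by_level <- function(pd, levels = c(0, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  check_pd(pd)
  tibble(
    filter_level = levels,
    betti = vapply(levels, function(f) nrow(filter_diagram(pd, f)),
                   numeric(1))
  )
}

check_pd <- function(pd) {
  if (!is.data.frame(pd) || !all(c("birth", "death") %in% names(pd))) {
    stop("`pd` must be a data frame with `birth` and `death` columns",
         call. = FALSE)
  }
  invisible(pd)
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level < 0 || level >= 1) {
    stop("filter level must be a single number in [0, 1)", call. = FALSE)
  }
  invisible(level)
}
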
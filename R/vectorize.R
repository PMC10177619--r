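#' Persistent entropy of a diagram
#'
#' Shannon entropy of the lifespan distribution: with lifespans
#' \eqn{\ell_j = d_j - b_j} and \eqn{S = \sum_j \ell_j},
#' \deqn{PE = -\sum_j (\ell_j / S) \log(\ell_j / S).}
#' A diagram with a single feature has entropy 0; N features of equal
#' lifespan give \eqn{\log N}. The empty diagram maps to 0 by convention.
#'
#' @param pd A persistence diagram tibble (finite pairs only).
#' @param base Logarithm base; the default natural log reports nats.
#' @return A single non-negative number, at most `log(nrow(pd), base)`.
#' @examples
#' persistent_entropy(tibble::tibble(birth = 0, death = c(1, 3)))
#' @export
persistent_entropy <- function(pd, base = exp(1)) {
  check_pd(pd)
  if (nrow(pd) == 0L) return(0)
  if (any(is.infinite(pd$death))) {
    stop("diagram contains essential pairs; entropy is defined on finite ",
         "lifespans only", call. = FALSE)
  }
  l <- pd$death - pd$birth
  p <- l / sum(l)
  -sum(p * log(p, base = base)) + 0  # + 0 normalises IEEE negative zero
}

#' Persistence image of a diagram
#'
#' Vectorises a diagram by rotating each point \eqn{(b, d)} to
#' birth-persistence coordinates \eqn{(b, p)} with \eqn{p = d - b}, placing
#' a weighted isotropic Gaussian of bandwidth `sigma` at each rotated point,
#' and integrating the resulting persistence surface over each cell of a
#' `resolution[1] x resolution[2]` grid. Integration over a cell uses exact
#' separable Gaussian CDF differences, not centre sampling.
#'
#' At the default 1x1 resolution the grid is the single cell
#' `[min b, max b] x [0, max p]` of the diagram itself (degenerate widths
#' padded to 1), so each diagram yields one scalar. Set `region` to a fixed
#' `c(xmin, xmax, ymin, ymax)` for strict comparability across images.
#'
#' @param pd A persistence diagram tibble (finite pairs only).
#' @param sigma Gaussian bandwidth, in intensity units; must be positive.
#' @param resolution Integer vector `c(nx, ny)` of grid cells; default `c(1, 1)`.
#' @param weight Point weight: `"persistence"` (the default linear ramp
#'   `w = p`), `"linear"` (ramp normalised by the diagram's maximum
#'   persistence) or `"one"` (unweighted).
#' @param region Optional fixed integration region `c(xmin, xmax, ymin, ymax)`
#'   in birth-persistence coordinates; default is the per-diagram bounding box.
#' @return A numeric vector of length `prod(resolution)` (a single scalar at
#'   the default resolution), in row-major (y-outer) order. The empty
#'   diagram gives zeros.
#' @examples
#' pd <- tibble::tibble(birth = c(120, 150), death = c(210, 185))
#' persistence_image(pd, sigma = 1)
#' @export
persistence_image <- function(pd, sigma = 1, resolution = c(1, 1),
                              weight = c("persistence", "linear", "one"),
                              region = NULL) {
  check_pd(pd)
  weight <- match.arg(weight)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  resolution <- as.integer(resolution)
  stopifnot(length(resolution) == 2L, all(resolution >= 1L))
  if (nrow(pd) == 0L) return(numeric(prod(resolution)))
  if (any(is.infinite(pd$death))) {
    stop("diagram contains essential pairs; drop them before vectorising",
         call. = FALSE)
  }
  b <- pd$birth
  p <- pd$death - pd$birth
  w <- switch(weight,
    persistence = p,
    linear = p / max(p),
    one = rep(1, length(p))
  )
  if (is.null(region)) {
    region <- c(min(b), max(b), 0, max(p))
    if (diff(region[1:2]) == 0) region[2] <- region[1] + 1  # degenerate pad
    if (diff(region[3:4]) == 0) region[4] <- region[3] + 1
  }
  stopifnot(length(region) == 4L, region[2] > region[1], region[4] > region[3])
  xs <- seq(region[1], region[2], length.out = resolution[1] + 1L)
  ys <- seq(region[3], region[4], length.out = resolution[2] + 1L)
  # mass of each point's Gaussian in each cell, separable in x and y
  cx <- vapply(seq_len(resolution[1]), function(i) {
    pnorm(xs[i + 1L], b, sigma) - pnorm(xs[i], b, sigma)
  }, numeric(length(b)))
  cy <- vapply(seq_len(resolution[2]), function(j) {
    pnorm(ys[j + 1L], p, sigma) - pnorm(ys[j], p, sigma)
  }, numeric(length(b)))
  cx <- matrix(cx, nrow = length(b))
  cy <- matrix(cy, nrow = length(b))
  out <- t(cy) %*% (cx * w)  # ny x nx, weighted sum over points
  as.numeric(t(out))         # row-major: y outer, x inner
}

#' Topological feature vector of a (filtered) diagram
#'
#' Computes both scalar features of a diagram — the persistence image (PI)
#' and the persistent entropy (PE) — and returns them as an ordered
#' `(pi, pe)` pair, the concatenated "multi-vector" used for
#' classification.
#'
#' @inheritParams persistence_image
#' @param ... Passed on to [persistence_image()].
#' @return A one-row tibble with columns `pi` and `pe`.
#' @examples
#' topo_features(compute_persistence(figure4_fixture(), dims = 1))
#' @export
topo_features <- function(pd, sigma = 1, ...) {
  check_pd(pd)
  tibble(
    pi = persistence_image(pd, sigma = sigma, resolution = c(1, 1), ...)[1L],
    pe = persistent_entropy(pd)
  )
}
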
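#' Build the sublevel-set cubical filtration of a grayscale image
#'
#' Interprets an image as a 2D cubical complex under the V-construction:
#' every pixel is a vertex, 4-neighbouring pixels are joined by an edge, and
#' every 2x2 pixel block is filled by a square. A cell enters the filtration
#' at the maximum intensity over its vertex pixels, so the complex at
#' threshold t contains exactly the cells whose pixels are all at most t.
#'
#' The returned table lists one row per cell, ordered for matrix reduction:
#' non-decreasing filtration value, then dimension, then row-major anchor
#' coordinate, with horizontal edges before vertical at the same anchor.
#' Every face of a cell precedes it in this order.
#'
#' @param img An 8-bit grayscale image matrix (see [as_gray_image()]).
#' @return A tibble with columns `dim` (0 = vertex, 1 = edge, 2 = square),
#'   `row`, `col` (0-based anchor, origin top-left), `orientation`
#'   (`"h"`/`"v"` for edges, `NA` otherwise) and `value` (filtration level).
#' @examples
#' build_sublevel_filtration(matrix(c(1, 3, 2, 4), 2, 2))
#' @export
build_sublevel_filtration <- function(img) {
  img <- as_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  r <- rep(0:(h - 1L), each = w)
  cl <- rep(0:(w - 1L), times = h)
  val <- as.integer(t(img))  # row-major
  cells <- list(
    tibble(dim = 0L, row = r, col = cl, orientation = NA_character_,
           value = val)
  )
  if (w > 1L) {
    keep <- cl < w - 1L
    cells <- c(cells, list(tibble(
      dim = 1L, row = r[keep], col = cl[keep], orientation = "h",
      value = pmax(val[keep], val[which(keep) + 1L])
    )))
  }
  if (h > 1L) {
    keep <- r < h - 1L
    cells <- c(cells, list(tibble(
      dim = 1L, row = r[keep], col = cl[keep], orientation = "v",
      value = pmax(val[keep], val[which(keep) + w])
    )))
  }
  if (h > 1L && w > 1L) {
    keep <- r < h - 1L & cl < w - 1L
    idx <- which(keep)
    cells <- c(cells, list(tibble(
      dim = 2L, row = r[keep], col = cl[keep], orientation = NA_character_,
      value = pmax(val[idx], val[idx + 1L], val[idx + w], val[idx + w + 1L])
    )))
  }
  out <- dplyr::bind_rows(cells)
  dplyr::arrange(out, .data$value, .data$dim, .data$row, .data$col,
                 !is.na(.data$orientation), .data$orientation)
}

#' Compute sublevel cubical persistence diagrams of an image
#'
#' Computes the H0 (connected components) and/or H1 (loops) persistence
#' diagrams of the sublevel-set cubical filtration of `img`, using Z/2
#' boundary reduction with deterministic tie-breaking (filtration value,
#' then dimension, then row-major anchor). Pairs with zero persistence
#' (`death == birth`) are discarded. Essential classes carry `death = Inf`;
#' for a full rectangular image there is exactly one, in H0, born at the
#' global minimum intensity, and never any in H1.
#'
#' @param img An 8-bit grayscale image matrix.
#' @param dims Homology dimensions to compute, a subset of `c(0, 1)`.
#' @return A persistence diagram: a tibble with columns `dim`, `birth`,
#'   `death` and `lifespan` (`death - birth`; `Inf` for essential classes),
#'   one row per persistence pair.
#' @examples
#' compute_persistence(figure4_fixture(), dims = 1)
#' @export
compute_persistence <- function(img, dims = c(0, 1)) {
  img <- as_gray_image(img)
  if (!all(dims %in% c(0, 1)) || length(dims) < 1L) {
    stop("`dims` must be a non-empty subset of c(0, 1)", call. = FALSE)
  }
  pd <- cubical_persistence_cpp(img, 0 %in% dims, 1 %in% dims)
  pd <- as_tibble(pd)
  pd$dim <- as.integer(pd$dim)
  pd$lifespan <- pd$death - pd$birth
  dplyr::arrange(pd, .data$dim, .data$birth, .data$death)
}

#' Betti curve of an image's sublevel complexes, computed directly
#'
#' An independent verification oracle for [compute_persistence()]: for each
#' intensity threshold it builds the sublevel complex explicitly and counts
#' its Betti number from first principles — dimension 0 by connected-component
#' counting over included vertices and edges, dimension 1 by rank-nullity on
#' the explicit Z/2 boundary matrices (`b1 = (E - rank d1) - rank d2`).
#' Quadratic-ish in complex size; intended for small images (about 10x10 or
#' less).
#'
#' @param img An 8-bit grayscale image matrix (small).
#' @param dim Homology dimension, 0 or 1.
#' @param thresholds Intensity thresholds at which to evaluate; defaults to
#'   the sorted distinct pixel values of `img` (the curve is constant
#'   between them).
#' @return A tibble with columns `threshold` and `betti`.
#' @export
betti_curve <- function(img, dim, thresholds = NULL) {
  img <- as_gray_image(img)
  stopifnot(length(dim) == 1L, dim %in% c(0, 1))
  if (is.null(thresholds)) thresholds <- sort(unique(as.integer(img)))
  filt <- build_sublevel_filtration(img)
  w <- ncol(img)
  betti <- vapply(thresholds, function(t) {
    sub <- filt[filt$value <= t, ]
    if (dim == 0) betti0_direct(sub, w) else betti1_direct(sub, w)
  }, numeric(1))
  tibble(threshold = as.integer(thresholds), betti = betti)
}

# connected components of the included vertex/edge graph, by union-find
betti0_direct <- function(sub, w) {
  verts <- sub[sub$dim == 0L, ]
  if (nrow(verts) == 0L) return(0)
  vid <- verts$row * w + verts$col
  idx <- match(vid, vid)  # identity; map global id -> local
  lookup <- stats::setNames(seq_along(vid), vid)
  parent <- seq_along(vid)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  edges <- sub[sub$dim == 1L, ]
  if (nrow(edges) > 0L) {
    a <- edges$row * w + edges$col
    b <- ifelse(edges$orientation == "h", a + 1L, a + w)
    for (i in seq_len(nrow(edges))) {
      ra <- find(lookup[[as.character(a[i])]])
      rb <- find(lookup[[as.character(b[i])]])
      if (ra != rb) parent[rb] <- ra
    }
  }
  length(unique(vapply(seq_along(vid), find, integer(1))))
}

# b1 = dim ker d1 - rank d2 = (E - rank d1) - rank d2 over Z/2
betti1_direct <- function(sub, w) {
  verts <- sub[sub$dim == 0L, ]
  edges <- sub[sub$dim == 1L, ]
  squares <- sub[sub$dim == 2L, ]
  ne <- nrow(edges)
  if (ne == 0L) return(0)
  vid <- verts$row * w + verts$col
  vpos <- stats::setNames(seq_along(vid), vid)
  ea <- edges$row * w + edges$col
  eb <- ifelse(edges$orientation == "h", ea + 1L, ea + w)
  d1 <- matrix(FALSE, nrow = nrow(verts), ncol = ne)
  for (j in seq_len(ne)) {
    d1[vpos[[as.character(ea[j])]], j] <- TRUE
    d1[vpos[[as.character(eb[j])]], j] <- TRUE
  }
  r1 <- gf2_rank(d1)
  r2 <- 0
  if (nrow(squares) > 0L) {
    ekey <- paste0(edges$orientation, ea)
    epos <- stats::setNames(seq_len(ne), ekey)
    d2 <- matrix(FALSE, nrow = ne, ncol = nrow(squares))
    sa <- squares$row * w + squares$col
    for (j in seq_len(nrow(squares))) {
      faces <- c(paste0("h", sa[j]), paste0("h", sa[j] + w),
                 paste0("v", sa[j]), paste0("v", sa[j] + 1L))
      d2[unname(epos[faces]), j] <- TRUE
    }
    r2 <- gf2_rank(d2)
  }
  (ne - r1) - r2
}

# rank of a logical matrix over GF(2) by Gaussian elimination
gf2_rank <- function(m) {
  if (length(m) == 0L) return(0)
  rank <- 0L
  nr <- nrow(m); nc <- ncol(m)
  row <- 1L
  for (j in seq_len(nc)) {
    piv <- which(m[row:nr, j])
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) m[c(row, piv), ] <- m[c(piv, row), ]
    hit <- which(m[, j])
    hit <- hit[hit != row]
    if (length(hit)) m[hit, ] <- xor(m[hit, , drop = FALSE],
                                     matrix(m[row, ], length(hit), nc,
                                            byrow = TRUE))
    rank <- rank + 1L
    row <- row + 1L
    if (row > nr) break
  }
  rank
}

#' Write / read a persistence diagram as CSV
#'
#' The on-disk dialect has a `dim,birth,death` header, one row per pair, and
#' the literal `inf` for essential (infinite) deaths.
#'
#' @param pd A persistence diagram tibble (as from [compute_persistence()]).
#' @param path CSV file path.
#' @return `write_pd()` returns `path` invisibly; `read_pd()` returns the
#'   diagram tibble with a recomputed `lifespan` column.
#' @export
write_pd <- function(pd, path) {
  out <- data.frame(dim = pd$dim, birth = pd$birth,
                    death = ifelse(is.infinite(pd$death), "inf", pd$death))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pd
#' @export
read_pd <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("dim", "birth", "death") %in% names(df)))
  death <- ifelse(tolower(trimws(df$death)) == "inf", Inf,
                  as.numeric(df$death))
  tibble(dim = as.integer(df$dim), birth = as.numeric(df$birth),
         death = death, lifespan = death - as.numeric(df$birth))
}
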
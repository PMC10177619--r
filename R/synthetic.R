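#' Worked-example image: two bright spots ringed by darker pixels
#'
#' A deterministic 7x11 image whose sublevel persistence is known exactly,
#' used as the package's worked example and regression anchor. On a uniform
#' background of intensity 100 it places two 3x3 motifs, each a ring of
#' darker pixels around a single brighter centre:
#' a ring at 120 around a centre at 210, and a ring at 150 around a centre
#' at 185. The rings close before their centres fill, so
#' H0 = \{(100, Inf)\} and H1 = \{(120, 210), (150, 185)\} — loop lifespans
#' 90 and 35.
#'
#' The motifs sit on the top image border. This is essential, not
#' cosmetic: a brighter block strictly inside a darker background is
#' encircled by the background itself, which would create a loop at the
#' background intensity (100) rather than at the ring intensity. On the
#' border no background cycle can close around the motif, so each loop is
#' born exactly when its own ring completes.
#'
#' @return An 8-bit grayscale image matrix.
#' @examples
#' compute_persistence(figure4_fixture(), dims = 1)
#' @export
figure4_fixture <- function() {
  img <- matrix(100L, nrow = 7, ncol = 11)
  # motif A: ring 120, centre 210
  img[1:3, 2:4] <- 120L
  img[2, 3] <- 210L
  # motif B: ring 150, centre 185 (>= 3 background columns away)
  img[1:3, 8:10] <- 150L
  img[2, 9] <- 185L
  img
}

#' Parameters of the synthetic patch generator
#'
#' Bundles the knobs of [generate_patch()] with per-class defaults that
#' emulate the morphology contrast between benign and malignant
#' microcalcification clusters: benign clusters are few large uniform
#' bright blobs (2-4 blobs, radius 6-9 px, intensity uplift 90-120), while
#' malignant clusters are many small heterogeneous ones (20-35 blobs,
#' radius 1-3 px, uplift 20-60). Each bright blob on the darker background
#' creates one H1 loop born near the background level and dying at the
#' blob's peak, so benign patches carry few long-lived loops and malignant
#' patches many short-lived ones.
#'
#' @param label `"benign"` or `"malignant"`; selects the defaults below.
#' @param size Patch side length in pixels (square patch).
#' @param bg_mean,bg_sd Mean and standard deviation of the background
#'   intensity noise field.
#' @param bg_texture `"gaussian"` for i.i.d. Gaussian noise (default) or
#'   `"speckle"` for multiplicative speckle noise of the same sd.
#' @param n_blobs Integer range `c(min, max)` of blob count.
#' @param radius Range of blob radius in pixels.
#' @param uplift Range of blob peak intensity uplift above the background.
#' @return A list of class `"patch_params"`.
#' @export
patch_params <- function(label = c("benign", "malignant"), size = 100L,
                         bg_mean = 100, bg_sd = 5,
                         bg_texture = c("gaussian", "speckle"),
                         n_blobs = NULL, radius = NULL, uplift = NULL) {
  label <- match.arg(label)
  bg_texture <- match.arg(bg_texture)
  if (is.null(n_blobs)) n_blobs <- if (label == "benign") c(2L, 4L) else c(20L, 35L)
  if (is.null(radius)) radius <- if (label == "benign") c(6, 9) else c(1, 3)
  if (is.null(uplift)) uplift <- if (label == "benign") c(90, 120) else c(20, 60)
  stopifnot(size >= 16, bg_sd >= 0, min(radius) >= 1, min(n_blobs) >= 1,
            bg_mean + max(uplift) <= 255)
  structure(list(label = label, size = as.integer(size), bg_mean = bg_mean,
                 bg_sd = bg_sd, bg_texture = bg_texture,
                 n_blobs = as.integer(n_blobs), radius = radius,
                 uplift = uplift),
            class = "patch_params")
}

#' Generate one synthetic microcalcification patch
#'
#' Draws a noisy background field, then stamps bright blobs — cosine-tapered
#' plateau disks, so small intensity perturbations do not split loops — at
#' non-overlapping centres (after bounded retries, overlap is allowed with
#' a warning). All intensities are rounded and clipped to \[0, 255\].
#' Bit-identical output for identical `params` and `seed`.
#'
#' @param params A [patch_params()] object.
#' @param seed Integer seed.
#' @return An 8-bit grayscale image matrix of size `params$size` squared.
#' @examples
#' img <- generate_patch(patch_params("benign"), seed = 1)
#' @export
generate_patch <- function(params, seed = 0L) {
  stopifnot(inherits(params, "patch_params"))
  withr::with_seed(as.integer(seed), generate_patch_impl(params))
}

generate_patch_impl <- function(params) {
  s <- params$size
  bg <- if (params$bg_texture == "gaussian") {
    matrix(rnorm(s * s, params$bg_mean, params$bg_sd), s, s)
  } else {
    params$bg_mean * (1 + matrix(rnorm(s * s, 0, params$bg_sd / params$bg_mean),
                                 s, s))
  }
  nb <- if (params$n_blobs[1] == params$n_blobs[2]) params$n_blobs[1] else
    sample(params$n_blobs[1]:params$n_blobs[2], 1L)
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  uplift_field <- matrix(0, s, s)
  rows <- matrix(rep(seq_len(s), times = s), s, s)
  cols <- matrix(rep(seq_len(s), each = s), s, s)
  for (i in seq_len(nb)) {
    r <- runif(1, params$radius[1], params$radius[2])
    u <- runif(1, params$uplift[1], params$uplift[2])
    m <- ceiling(r) + 2  # keep background ring inside the patch
    placed <- FALSE
    for (try in seq_len(200L)) {
      cy <- runif(1, m + 1, s - m)
      cx <- runif(1, m + 1, s - m)
      if (nrow(centers) == 0L ||
          all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >
              radii + r + 2)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      warning("could not place blob ", i, " without overlap; allowing overlap")
    }
    centers <- rbind(centers, c(cy, cx))
    radii <- c(radii, r)
    rho <- sqrt((rows - cy)^2 + (cols - cx)^2)
    wdt <- max(1, min(2, r / 2))  # taper width
    prof <- ifelse(rho <= r - wdt, 1,
                   ifelse(rho <= r, 0.5 * (1 + cos(pi * (rho - (r - wdt)) / wdt)),
                          0))
    uplift_field <- pmax(uplift_field, u * prof)
  }
  img <- round(bg + uplift_field)
  img[img < 0] <- 0
  img[img > 255] <- 255
  as_gray_image(img)
}

#' Generate a two-class synthetic patch dataset
#'
#' Writes `n_per_class` benign and `n_per_class` malignant patches to
#' `dir` (as plain PGM or PNG) together with a CSV manifest
#' `image_id,path,label`. With `dir = NULL` no files are written and the
#' images are returned in memory. Fully deterministic given `seed`.
#'
#' @param n_per_class Patches per class (at least 5).
#' @param dir Output directory (created if missing), or `NULL` for
#'   in-memory output.
#' @param benign,malignant Per-class [patch_params()].
#' @param seed Integer seed.
#' @param format `"pgm"` or `"png"` for written patches.
#' @return A list with `manifest` (a tibble `image_id, path, label`) and
#'   `images` (a named list of matrices; present also when files are
#'   written).
#' @examples
#' ds <- generate_dataset(5, dir = NULL, seed = 0)
#' ds$manifest
#' @export
generate_dataset <- function(n_per_class, dir = NULL,
                             benign = patch_params("benign"),
                             malignant = patch_params("malignant"),
                             seed = 0L, format = c("pgm", "png")) {
  stopifnot(n_per_class >= 5)
  format <- match.arg(format)
  params <- list(benign = benign, malignant = malignant)
  images <- list()
  rows <- list()
  withr::with_seed(as.integer(seed), {
    for (lab in c("benign", "malignant")) {
      for (i in seq_len(n_per_class)) {
        id <- sprintf("%s_%03d", lab, i)
        images[[id]] <- generate_patch_impl(params[[lab]])
        rows[[id]] <- tibble(image_id = id, path = NA_character_, label = lab)
      }
    }
  })
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest$path <- file.path(dir, paste0(manifest$image_id, ".", format))
    for (i in seq_len(nrow(manifest))) {
      img <- images[[manifest$image_id[i]]]
      if (format == "pgm") {
        write_pgm(img, manifest$path[i])
      } else {
        png::writePNG(img / 255, manifest$path[i])
      }
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
              quote = FALSE)
  }
  list(manifest = manifest, images = images)
}
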
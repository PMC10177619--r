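#' Validate an 8-bit grayscale image matrix
#'
#' Checks that `img` is a numeric matrix of integer-valued intensities in
#' \[0, 255\] with at least one row and one column, and returns it as an
#' integer matrix. All persistence functions in this package accept only
#' 8-bit input; deeper sources must be rescaled upstream.
#'
#' @param img A numeric matrix of pixel intensities.
#' @return An integer matrix with the same dimensions as `img`.
#' @examples
#' as_gray_image(matrix(0:3, 2, 2))
#' @export
as_gray_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("`img` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop("`img` must have at least one row and one column", call. = FALSE)
  }
  if (anyNA(img)) stop("`img` contains missing values", call. = FALSE)
  if (any(img != round(img))) {
    stop("pixel intensities must be integer-valued", call. = FALSE)
  }
  if (any(img < 0) || any(img > 255)) {
    stop("pixel intensities must lie in [0, 255] (8-bit input only)",
         call. = FALSE)
  }
  storage.mode(img) <- "integer"
  img
}

#' Read an 8-bit grayscale image patch
#'
#' Reads a PGM (plain `P2` or binary `P5`) or an 8-bit single-channel PNG
#' file into an integer intensity matrix, origin at the top-left, rows
#' running downward.
#'
#' @param path Path to a `.pgm` or `.png` file.
#' @return An integer matrix of intensities in \[0, 255\].
#' @seealso [write_pgm()]
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    pgm = read_pgm(path),
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- a[, , 1L]  # grayscale channel
      round(a * 255)
    },
    stop("unsupported image format: .", ext, " (use PGM or PNG)",
         call. = FALSE)
  )
  as_gray_image(img)
}

# Minimal PGM reader for P2 (ASCII) and P5 (8-bit binary) files.
# Byte-level header tokenizer: P5 pixel data may contain any byte value,
# so the header cannot be parsed line-wise.
read_pgm <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  n <- length(raw_all)
  ws <- as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x0b, 0x0c))
  pos <- 1L
  next_token <- function() {
    repeat {
      while (pos <= n && raw_all[pos] %in% ws) pos <<- pos + 1L
      if (pos <= n && raw_all[pos] == as.raw(0x23)) {  # '#' comment
        while (pos <= n && raw_all[pos] != as.raw(0x0a)) pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= n && !(raw_all[pos] %in% ws)) pos <<- pos + 1L
    if (pos <= start) stop("truncated PGM header: ", path, call. = FALSE)
    rawToChar(raw_all[start:(pos - 1L)])
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P5")) {
    stop("not a P2/P5 PGM file: ", path, call. = FALSE)
  }
  w <- as.integer(next_token())
  h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(w) || is.na(h) || is.na(maxval)) {
    stop("malformed PGM header: ", path, call. = FALSE)
  }
  if (maxval > 255L) stop("16-bit PGM not supported (8-bit input only)",
                          call. = FALSE)
  if (magic == "P2") {
    # remainder is pure ASCII; comments are legal anywhere
    body <- rawToChar(raw_all[pos:n])
    body <- gsub("#[^\n]*", " ", body)
    vals <- scan(text = body, what = integer(), quiet = TRUE)
    if (length(vals) < w * h) stop("truncated PGM: ", path, call. = FALSE)
    vals <- vals[seq_len(w * h)]
  } else {
    # exactly one whitespace byte separates maxval from the pixel bytes;
    # next_token() has already consumed up to (not including) it
    pos <- pos + 1L
    if (pos + w * h - 1L > n) stop("truncated PGM: ", path, call. = FALSE)
    vals <- as.integer(raw_all[pos:(pos + w * h - 1L)])
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write an image matrix as plain (P2) PGM
#'
#' @param img An 8-bit grayscale image matrix (see [as_gray_image()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  img <- as_gray_image(img)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  writeLines(apply(img, 1L, paste, collapse = " "), con)
  invisible(path)
}
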
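#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one master seed; each stage draws
#' its own seed through this helper so that rerunning a single stage with the
#' same master seed reproduces its output regardless of what ran before.
#'
#' @param seed master seed (integer).
#' @param label character tag naming the sub-stream (e.g. `"tiling"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, Mersenne prime of the minstd generator
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  s <- abs(as.numeric(seed)) %% m
  s <- (s * 48271) %% m
  s <- (s + h * 69621) %% m
  as.integer(max(1, s))
}

# Half-up decimal rounding, matching the print convention of clinical tables
# (base round() is half-to-even: round(5.625, 2) == 5.62).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Luma conversion of an h x w x 3 array (0..255) to a grayscale matrix.
rgb_to_gray <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

assert_rgb_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an h x w x 3 RGB array", call. = FALSE)
  if (min(img) < 0 || max(img) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  invisible(img)
}

#' Write an RGB array or mask to a PNG file
#'
#' @param img h x w x 3 array (0..255) or an h x w matrix (0/1 or 0..255).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  if (is.matrix(img)) {
    if (max(img) <= 1) img <- img * 255
    png::writePNG(img / 255, target = path)
  } else {
    assert_rgb_image(img)
    png::writePNG(img / 255, target = path)
  }
  invisible(path)
}

#' Read an 8-bit image from PNG or TIFF
#'
#' Returns the package's working representation: an `h x w x 3` array with
#' values in 0..255 for color images, or an `h x w` matrix for grayscale.
#'
#' @param path file path (`.png` or `.tif`/`.tiff`).
#' @return numeric array/matrix with values in 0..255.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) img <- img[, , 1:3]
  img * 255
}
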
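#' Morphometric feature vector of one tile
#'
#' Summarizes a tile by hand-designed histomorphometry: grayscale intensity
#' statistics and quantiles, dark-pixel fractions at nucleus-scale cutoffs,
#' connected dark-blob density and size statistics (nucleus proxies), local
#' gradient energy, and a stain-color contrast. These spatial averages play
#' the role of the global average pooling stage of the tile classifier; the
#' trainable network operates on this pooled representation.
#'
#' @param tile_rgb `h x w x 3` array (0..255), or a grayscale matrix (the
#'   color contrast feature is then 0).
#' @return Named numeric vector of length 13.
#' @export
tile_features <- function(tile_rgb) {
  if (is.matrix(tile_rgb)) {
    gray <- tile_rgb
    rb <- 0
  } else {
    gray <- rgb_to_gray(tile_rgb)
    rb <- mean(tile_rgb[, , 1] - tile_rgb[, , 3])
  }
  n <- length(gray)
  dark <- gray < 100
  blobs <- EBImage::bwlabel(dark * 1)
  nb <- max(blobs)
  sizes <- if (nb > 0) tabulate(blobs[blobs > 0], nbins = nb) else numeric(0)
  q <- stats::quantile(gray, c(0.1, 0.25, 0.5), names = FALSE)
  grad <- mean(abs(diff(gray))) + mean(abs(t(diff(t(gray)))))
  c(gray_mean = mean(gray),
    gray_sd = stats::sd(gray),
    q10 = q[1], q25 = q[2], q50 = q[3],
    frac_dark80 = mean(gray < 80),
    frac_dark120 = mean(gray < 120),
    frac_dark160 = mean(gray < 160),
    blob_density = nb / (n / 1000),
    blob_mean_size = if (nb > 0) mean(sizes) else 0,
    blob_sd_size = if (nb > 1) stats::sd(sizes) else 0,
    gradient_energy = grad,
    red_blue_contrast = rb)
}

#' Feature matrix for the valid tumor tiles of one slide
#'
#' @param rgb_image slide image.
#' @param tiles tile records from [extract_tiles()].
#' @param which `"valid_tumor"` (default training selection) or `"valid"`
#'   (any tissue-valid tile, used by the outside-invasive-front mode).
#' @return List with `tiles` (the selected records) and `features`
#'   (matrix, one row per selected tile).
#' @export
slide_tile_features <- function(rgb_image, tiles,
                                which = c("valid_tumor", "valid")) {
  which <- match.arg(which)
  sel <- if (which == "valid_tumor") tiles$is_valid & tiles$is_tumor else tiles$is_valid
  use <- tiles[sel, , drop = FALSE]
  feats <- matrix(NA_real_, nrow(use), 13L)
  for (i in seq_len(nrow(use))) {
    t1 <- use[i, ]
    crop <- rgb_image[(t1$y0 + 1):t1$y1, (t1$x0 + 1):t1$x1, , drop = FALSE]
    fv <- tile_features(crop)
    feats[i, ] <- fv
    if (i == 1L) colnames(feats) <- names(fv)
  }
  list(tiles = use, features = feats)
}
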
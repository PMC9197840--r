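#' Tissue mask by combined binary and Otsu thresholding
#'
#' A pixel is marked tissue when its grayscale intensity is below both a
#' fixed background cutoff and the per-image Otsu split, i.e. below
#' `min(fixed_threshold, otsu)`. On a constant image, where the Otsu
#' threshold is undefined, the fixed cutoff alone is used.
#'
#' @param rgb_image `h x w x 3` array (0..255) or a grayscale matrix.
#' @param fixed_threshold fixed background cutoff on the 0..255 scale
#'   (default 220).
#' @return Logical `h x w` matrix (`TRUE` = tissue) with attributes
#'   `otsu_threshold` and `threshold` (the cutoff actually applied).
#' @export
compute_tissue_mask <- function(rgb_image, fixed_threshold = 220) {
  gray <- if (is.matrix(rgb_image)) rgb_image else {
    assert_rgb_image(rgb_image)
    rgb_to_gray(rgb_image)
  }
  ot <- otsu_threshold(gray)
  thr <- if (is.na(ot)) fixed_threshold else min(fixed_threshold, ot)
  mask <- gray < thr
  attr(mask, "otsu_threshold") <- ot
  attr(mask, "threshold") <- thr
  mask
}

#' Otsu threshold over a 256-bin histogram
#'
#' Exhaustive search over all 8-bit cut points for the threshold maximizing
#' the between-class variance. Returns `NA` for a constant image, where no
#' split exists.
#'
#' @param gray numeric matrix with values in 0..255.
#' @return Threshold on the 0..255 scale (pixels strictly below it fall in
#'   the dark class), or `NA_real_`.
#' @export
otsu_threshold <- function(gray) {
  b <- pmin(255L, pmax(0L, as.integer(round(gray))))
  counts <- tabulate(b + 1L, nbins = 256L)
  n <- sum(counts)
  if (sum(counts > 0) < 2L) return(NA_real_)
  p <- counts / n
  lev <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[256]
  # class split: dark class = bins 0..t, bright = t+1..255
  w0h <- w0[1:255]; muh <- mu[1:255]
  valid <- w0h > 0 & w0h < 1
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mu_t * w0h[valid] - muh[valid])^2 / (w0h[valid] * (1 - w0h[valid]))
  t_star <- which.max(bcv) - 1L # last bin of the dark class
  t_star + 1 # "below threshold" = intensity <= t_star
}

# Mean of tile-size blocks of a matrix over an nr x nc complete-tile grid.
block_mean <- function(m, tile_px, nr, nc) {
  m2 <- m[seq_len(nr * tile_px), seq_len(nc * tile_px), drop = FALSE]
  rs <- rowsum(m2, rep(seq_len(nr), each = tile_px))
  t(rowsum(t(rs), rep(seq_len(nc), each = tile_px))) / tile_px^2
}

#' Cut an annotated slide into labeled tiles
#'
#' Lays a non-overlapping grid of `tile_px`-sized tiles from the image origin
#' (row-major, 0-based indices, half-open pixel boxes); partial edge tiles
#' are discarded. Per tile, the tissue fraction comes from
#' [compute_tissue_mask()] and the tumor fraction from the annotation mask.
#' A tile is valid iff its tissue fraction exceeds 0.5 and a tumor tile iff
#' its tumor fraction exceeds 0.5 (both strictly); training sets use valid
#' tumor tiles only. All tiles inherit the slide's cohort label.
#'
#' @param rgb_image `h x w x 3` array (0..255).
#' @param annotation_mask `h x w` 0/1 matrix aligned with the image
#'   (manual exclusion regions simply carry mask value 0).
#' @param tile_px tile side in pixels (published sizes 1024 and 512; any
#'   positive size is accepted for reduced-scale work).
#' @param label cohort label inherited by every tile.
#' @param slide_id,patient_id,scan_batch provenance copied onto each record.
#' @param fixed_threshold passed to [compute_tissue_mask()].
#' @return A `data.frame` of tile records: grid position (`row`, `col`),
#'   pixel box (`x0`, `y0`, `x1`, `y1`), `tissue_fraction`,
#'   `tumor_fraction`, `is_valid`, `is_tumor`, `label`, `scan_batch`.
#' @export
extract_tiles <- function(rgb_image, annotation_mask, tile_px = 512L,
                          label = "non_met", slide_id = "slide",
                          patient_id = slide_id, scan_batch = "A",
                          fixed_threshold = 220) {
  assert_rgb_image(rgb_image)
  d <- dim(rgb_image)
  if (!all(dim(annotation_mask) == d[1:2]))
    stop("annotation mask shape does not match the image", call. = FALSE)
  stopifnot(tile_px >= 1)
  nr <- d[1] %/% tile_px
  nc <- d[2] %/% tile_px
  if (nr < 1 || nc < 1)
    stop("image smaller than one tile", call. = FALSE)

  tissue <- compute_tissue_mask(rgb_image, fixed_threshold = fixed_threshold)
  tf <- block_mean(tissue * 1, tile_px, nr, nc)
  uf <- block_mean((annotation_mask > 0) * 1, tile_px, nr, nc)

  grid <- expand.grid(row = 0:(nr - 1), col = 0:(nc - 1))
  grid <- grid[order(grid$row, grid$col), ]
  tiles <- data.frame(
    slide_id = slide_id, patient_id = patient_id,
    row = grid$row, col = grid$col,
    x0 = grid$col * tile_px, y0 = grid$row * tile_px,
    x1 = (grid$col + 1) * tile_px, y1 = (grid$row + 1) * tile_px,
    tissue_fraction = tf[cbind(grid$row + 1, grid$col + 1)],
    tumor_fraction = uf[cbind(grid$row + 1, grid$col + 1)],
    stringsAsFactors = FALSE
  )
  tiles$is_valid <- tiles$tissue_fraction > 0.5
  tiles$is_tumor <- tiles$tumor_fraction > 0.5
  tiles$label <- label
  tiles$scan_batch <- scan_batch
  rownames(tiles) <- NULL
  tiles
}

#' Crop one tile from a slide and resize it to the model input size
#'
#' @param rgb_image the slide image the tile was extracted from.
#' @param tile one row of the [extract_tiles()] data frame.
#' @param resize_px side of the resized (bilinear) output, default 299.
#' @return `resize_px x resize_px x 3` array, values in 0..255.
#' @export
get_tile_image <- function(rgb_image, tile, resize_px = 299L) {
  crop <- rgb_image[(tile$y0 + 1):tile$y1, (tile$x0 + 1):tile$x1, , drop = FALSE]
  if (resize_px == dim(crop)[1]) return(crop)
  out <- EBImage::resize(crop, w = resize_px, h = resize_px,
                         filter = "bilinear")
  out <- as.numeric(out)
  dim(out) <- c(resize_px, resize_px, 3L)
  out[out < 0] <- 0; out[out > 255] <- 255
  out
}

#' Select tiles at the invasive front of the annotation
#'
#' The invasive front is approximated on the tile grid: a tumor tile lies on
#' the inside front when at least one of its 4-connected neighbors is a
#' non-tumor tile; a non-tumor tile lies on the outside front when at least
#' one neighbor is a tumor tile. Grid borders do not count as boundary, so
#' an annotation covering the whole image has an empty inside front.
#'
#' @param tiles tile records of one slide ([extract_tiles()]).
#' @param side `"inside"`, `"outside"` or `"both"` (the union).
#' @return The selected subset of `tiles`.
#' @export
select_invasive_front <- function(tiles, side = c("inside", "outside", "both")) {
  side <- match.arg(side)
  stopifnot(length(unique(tiles$slide_id)) <= 1L)
  if (nrow(tiles) == 0L || !any(tiles$is_tumor))
    return(tiles[0, , drop = FALSE])
  nr <- max(tiles$row) + 1L; nc <- max(tiles$col) + 1L
  tumor <- matrix(FALSE, nr, nc)
  tumor[cbind(tiles$row + 1, tiles$col + 1)] <- tiles$is_tumor

  pad <- function(m, default) {
    out <- matrix(default, nr + 2, nc + 2)
    out[2:(nr + 1), 2:(nc + 1)] <- m
    out
  }
  # neighbors outside the grid mirror the cell itself => border is not a front
  p <- pad(tumor, NA)
  p[1, 2:(nc + 1)] <- tumor[1, ]; p[nr + 2, 2:(nc + 1)] <- tumor[nr, ]
  p[2:(nr + 1), 1] <- tumor[, 1]; p[2:(nr + 1), nc + 2] <- tumor[, nc]
  up <- p[1:nr, 2:(nc + 1)]; down <- p[3:(nr + 2), 2:(nc + 1)]
  left <- p[2:(nr + 1), 1:nc]; right <- p[2:(nr + 1), 3:(nc + 2)]
  has_tumor_nb <- (up | down | left | right)
  has_nontumor_nb <- (!up | !down | !left | !right)
  has_tumor_nb[is.na(has_tumor_nb)] <- FALSE
  has_nontumor_nb[is.na(has_nontumor_nb)] <- FALSE

  inside <- tumor & has_nontumor_nb
  outside <- !tumor & has_tumor_nb
  keep <- switch(side, inside = inside, outside = outside,
                 both = inside | outside)
  tiles[keep[cbind(tiles$row + 1, tiles$col + 1)], , drop = FALSE]
}

#' Partition valid tumor tiles into disjoint stacks
#'
#' Randomly partitions each slide's valid tumor tiles into stacks of `n`
#' tiles (the multi-tile input mode). No tile appears in two stacks, so a
#' dataset of T tiles yields `sum over slides of floor(T_s / n)` stacks;
#' leftover tiles are dropped. Deterministic given the seed.
#'
#' @param tiles tile records; only rows with `is_valid & is_tumor` are used.
#' @param n stack size, `n >= 1` (`n = 1` reproduces single-tile mode).
#' @param seed integer seed.
#' @return `tiles` subset with an added `stack_id` column.
#' @export
make_tile_stacks <- function(tiles, n, seed = 1L) {
  stopifnot(n >= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  use <- tiles[tiles$is_valid & tiles$is_tumor, , drop = FALSE]
  out <- lapply(split(use, use$slide_id), function(s) {
    k <- nrow(s) %/% n
    if (k == 0L) return(s[0, , drop = FALSE])
    s <- s[sample.int(nrow(s)), , drop = FALSE]
    s <- s[seq_len(k * n), , drop = FALSE]
    s$stack_id <- sprintf("%s_stack%03d", s$slide_id[1], rep(seq_len(k), each = n))
    s
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    warning("stack size n exceeds the valid tumor tile count of every slide")
    use$stack_id <- character(0)[seq_len(nrow(use))]
    return(use[0, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Write a tile manifest CSV
#'
#' @param tiles tile records from [extract_tiles()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tile_manifest <- function(tiles, path) {
  utils::write.csv(tiles, path, row.names = FALSE)
  invisible(path)
}
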
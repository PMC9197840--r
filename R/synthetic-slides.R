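#' Specification of one synthetic annotated slide
#'
#' Describes a synthetic stand-in for a hematoxylin--eosin whole-slide image:
#' a pale (near-white) background with an annotated tumor region filled with
#' eosin-pink tissue and dark, nucleus-like ellipses. The two
#' texture-distinguishable classes differ only through `texture_effect`,
#' which shifts nucleus density and radius for the rapidly metastatic cohort;
#' at `texture_effect = 0` the class-conditional pixel statistics are
#' identical in expectation. The slowly metastatic cohort reuses the
#' non-metastatic texture.
#'
#' @param slide_id,patient_id identifiers; one slide per patient is the
#'   default study design.
#' @param cohort one of `"non_met"`, `"rapid_met"`, `"slow_met"`.
#' @param width_px,height_px slide size in pixels.
#' @param texture_effect real in `[0, 1]`; 0 makes the classes
#'   indistinguishable, 1 gives the full density/radius shift.
#' @param annotation_polygons list of closed polygons, each an `n x 2` matrix
#'   of `(x, y)` pixel coordinates inside the image bounds. `NULL` draws a
#'   default irregular blob covering roughly half the slide.
#' @param scan_batch `"A"` or `"B"`; carried through to tiles so a scan-batch
#'   confound can be constructed and then filtered out.
#' @param seed integer; the slide is a deterministic function of its spec.
#' @param nucleus_radius_px,nucleus_density base nucleus radius (pixels) and
#'   expected nucleus count per tissue pixel before the cohort shift.
#' @return An object of class `slide_spec`.
#' @export
synthetic_slide_spec <- function(slide_id, patient_id = slide_id,
                                 cohort = c("non_met", "rapid_met", "slow_met"),
                                 width_px = 4096L, height_px = 4096L,
                                 texture_effect = 1,
                                 annotation_polygons = NULL,
                                 scan_batch = c("A", "B"),
                                 seed = 1L,
                                 nucleus_radius_px = max(3, round(width_px / 200)),
                                 nucleus_density = 0.2 / (pi * nucleus_radius_px^2)) {
  cohort <- match.arg(cohort)
  scan_batch <- match.arg(scan_batch)
  stopifnot(width_px >= 32, height_px >= 32,
            texture_effect >= 0, texture_effect <= 1)
  if (is.null(annotation_polygons)) {
    annotation_polygons <- list(
      default_annotation_polygon(width_px, height_px,
                                 derive_seed(seed, "polygon"))
    )
  }
  annotation_polygons <- lapply(annotation_polygons, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2L, nrow(p) >= 3L)
    p
  })
  for (p in annotation_polygons) {
    if (min(p[, 1]) < 0 || max(p[, 1]) > width_px ||
        min(p[, 2]) < 0 || max(p[, 2]) > height_px)
      stop("annotation polygon lies outside image bounds", call. = FALSE)
  }
  structure(
    list(slide_id = as.character(slide_id),
         patient_id = as.character(patient_id),
         cohort = cohort, width_px = as.integer(width_px),
         height_px = as.integer(height_px),
         texture_effect = texture_effect,
         annotation_polygons = annotation_polygons,
         scan_batch = scan_batch, seed = as.integer(seed),
         nucleus_radius_px = nucleus_radius_px,
         nucleus_density = nucleus_density),
    class = "slide_spec"
  )
}

# Irregular star-convex blob centred on the slide; deterministic given seed.
default_annotation_polygon <- function(w, h, seed) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  k <- 24L
  ang <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  r <- 0.36 * min(w, h) * stats::runif(k, 0.8, 1.15)
  cbind(x = w / 2 + r * cos(ang), y = h / 2 + r * sin(ang))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Even-odd scanline rasterization of polygons into an h x w logical matrix.
# Pixel (row r, col c) has centre (c - 0.5, r - 0.5) in (x, y) coordinates.
rasterize_polygons <- function(polygons, height_px, width_px) {
  mask <- matrix(FALSE, height_px, width_px)
  if (length(polygons) == 0L) return(mask)
  edges <- do.call(rbind, lapply(polygons, function(p) {
    q <- rbind(p, p[1, , drop = FALSE])
    cbind(x1 = q[-nrow(q), 1], y1 = q[-nrow(q), 2],
          x2 = q[-1, 1], y2 = q[-1, 2])
  }))
  edges <- edges[edges[, "y1"] != edges[, "y2"], , drop = FALSE]
  if (nrow(edges) == 0L) return(mask)
  ylo <- pmin(edges[, "y1"], edges[, "y2"])
  yhi <- pmax(edges[, "y1"], edges[, "y2"])
  for (r in seq_len(height_px)) {
    yc <- r - 0.5
    hit <- ylo <= yc & yc < yhi
    if (!any(hit)) next
    e <- edges[hit, , drop = FALSE]
    xs <- e[, "x1"] + (yc - e[, "y1"]) * (e[, "x2"] - e[, "x1"]) / (e[, "y2"] - e[, "y1"])
    xs <- sort(xs)
    for (i in seq(1, length(xs) - 1, by = 2)) {
      c0 <- ceiling(xs[i] + 0.5)
      c1 <- ceiling(xs[i + 1] + 0.5) - 1L
      if (c1 >= c0) mask[r, max(1L, c0):min(width_px, c1)] <- TRUE
    }
  }
  mask
}

#' Generate a synthetic annotated slide image
#'
#' Renders the slide described by a [synthetic_slide_spec()]: near-white
#' background outside the annotation, pink tissue with dark nucleus-like
#' ellipses inside. The rapidly metastatic cohort receives
#' `1 + 0.6 * texture_effect` times the nucleus density and
#' `1 + 0.35 * texture_effect` times the nucleus radius of the other cohorts,
#' so the class signal is monotone in `texture_effect` and vanishes at 0.
#' Output is deterministic given the spec (including its seed).
#'
#' @param spec a [synthetic_slide_spec()].
#' @return A list with `rgb_image` (`h x w x 3` array, values 0..255) and
#'   `annotation_mask` (`h x w` 0/1 matrix).
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(spec$seed)
  h <- spec$height_px; w <- spec$width_px
  mask <- rasterize_polygons(spec$annotation_polygons, h, w)

  img <- array(0, dim = c(h, w, 3))
  n <- h * w
  # near-white scanner background
  for (ch in 1:3) img[, , ch] <- 250 + stats::rnorm(n, 0, 2)
  # eosin-pink tissue inside the annotation; tint chosen clearly darker than
  # the scanner background so the Otsu split falls between tissue and glass
  tint <- c(206, 156, 176)
  idx <- which(mask)
  if (length(idx) > 0) {
    for (ch in 1:3)
      img[, , ch][idx] <- tint[ch] + stats::rnorm(length(idx), 0, 6)

    # nucleus-like dark ellipses; cohort effect on density and radius
    shift <- if (spec$cohort == "rapid_met") spec$texture_effect else 0
    dens <- spec$nucleus_density * (1 + 0.6 * shift)
    rad <- spec$nucleus_radius_px * (1 + 0.35 * shift)
    n_nuc <- stats::rpois(1, dens * length(idx))
    if (n_nuc > 0) {
      centers <- idx[sample.int(length(idx), n_nuc, replace = TRUE)]
      cr <- ((centers - 1L) %% h) + 1L
      cc <- ((centers - 1L) %/% h) + 1L
      a <- rad * stats::runif(n_nuc, 0.75, 1.25)
      b <- rad * stats::runif(n_nuc, 0.65, 1.1)
      th <- stats::runif(n_nuc, 0, pi)
      shade <- stats::runif(n_nuc, 0.8, 1.2)
      base <- c(84, 62, 130) # hematoxylin-dark nucleus color
      for (i in seq_len(n_nuc)) {
        rr <- max(1L, cr[i] - ceiling(a[i])):min(h, cr[i] + ceiling(a[i]))
        cc2 <- max(1L, cc[i] - ceiling(a[i])):min(w, cc[i] + ceiling(a[i]))
        dy <- rr - cr[i]; dx <- cc2 - cc[i]
        u <- outer(dy, dx, function(y, x) (x * cos(th[i]) + y * sin(th[i])) / a[i])
        v <- outer(dy, dx, function(y, x) (-x * sin(th[i]) + y * cos(th[i])) / b[i])
        inside <- u^2 + v^2 <= 1
        if (!any(inside)) next
        for (ch in 1:3) {
          sub <- img[rr, cc2, ch]
          sub[inside] <- base[ch] * shade[i]
          img[rr, cc2, ch] <- sub
        }
      }
    }
  }
  img[img < 0] <- 0; img[img > 255] <- 255
  list(rgb_image = img, annotation_mask = mask * 1)
}
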
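mk_rgb <- function(gray_matrix) {
  array(rep(gray_matrix, 3), dim = c(dim(gray_matrix), 3))
}

test_that("tissue mask combines the fixed and Otsu thresholds", {
  white <- mk_rgb(matrix(255, 32, 32))
  expect_equal(sum(compute_tissue_mask(white)), 0)

  dark <- mk_rgb(matrix(40, 32, 32)) # constant: Otsu undefined, fixed rules
  m <- compute_tissue_mask(dark)
  expect_true(all(m))
  expect_true(is.na(attr(m, "otsu_threshold")))
  expect_equal(attr(m, "threshold"), 220)

  half <- matrix(30, 32, 32); half[, 17:32] <- 250
  mh <- compute_tissue_mask(mk_rgb(half))
  expect_equal(mean(mh), 0.5)
  ot <- attr(mh, "otsu_threshold")
  expect_true(ot > 30 && ot <= 250) # split lies between the two modes

  # agreement with the reference Otsu implementation on a bimodal image
  set.seed(1)
  g <- matrix(c(rnorm(500, 60, 10), rnorm(500, 220, 10)), 20, 50)
  g <- pmin(255, pmax(0, g))
  ours <- otsu_threshold(g)
  ref <- EBImage::otsu(EBImage::Image(g / 255), range = c(0, 1), levels = 256) * 255
  # thresholds may sit anywhere on the empty-histogram plateau between the
  # modes; the induced dark/bright split must agree
  expect_equal(g < ours, g < ref)
})

test_that("tile grid arithmetic, strict > 0.5 rules and edge discarding", {
  img <- mk_rgb(matrix(40, 1024, 1024))
  mask <- matrix(1, 1024, 1024)
  tiles <- extract_tiles(img, mask, tile_px = 512, label = "met")
  expect_equal(nrow(tiles), 4)
  expect_setequal(paste(tiles$row, tiles$col), c("0 0", "0 1", "1 0", "1 1"))
  expect_true(all(tiles$is_valid & tiles$is_tumor)) # fully dark, fully annotated
  expect_true(all(tiles$x1 - tiles$x0 == 512))

  # tumor fraction exactly 0.5 is NOT a tumor tile (strict >)
  mask2 <- matrix(0, 1024, 1024); mask2[, 1:512] <- 1
  t2 <- extract_tiles(img, mask2, tile_px = 1024)
  expect_equal(t2$tumor_fraction, 0.5)
  expect_false(t2$is_tumor)

  # partial edge tiles are discarded
  img3 <- mk_rgb(matrix(40, 700, 1100))
  t3 <- extract_tiles(img3, matrix(1, 700, 1100), tile_px = 512)
  expect_equal(nrow(t3), 1 * 2)

  expect_error(extract_tiles(img, matrix(1, 10, 10), tile_px = 512), "shape")
})

test_that("tile fractions are invariant under 90-degree rotation", {
  sl <- generate_slide(synthetic_slide_spec("s", cohort = "rapid_met",
                                            width_px = 256, height_px = 256,
                                            seed = 4))
  t0 <- extract_tiles(sl$rgb_image, sl$annotation_mask, tile_px = 64)
  rot_img <- aperm(sl$rgb_image[dim(sl$rgb_image)[1]:1, , , drop = FALSE],
                   c(2, 1, 3))
  rot_mask <- t(sl$annotation_mask[nrow(sl$annotation_mask):1, ])
  t1 <- extract_tiles(rot_img, rot_mask, tile_px = 64)
  expect_equal(sort(t0$tissue_fraction), sort(t1$tissue_fraction))
  expect_equal(sort(t0$tumor_fraction), sort(t1$tumor_fraction))
})

test_that("invasive front selection follows 4-connected tile adjacency", {
  grid33 <- expand.grid(row = 0:2, col = 0:2)
  tiles <- data.frame(slide_id = "s", patient_id = "s",
                      row = grid33$row, col = grid33$col,
                      is_valid = TRUE, is_tumor = FALSE)
  tiles$is_tumor[tiles$row == 1 & tiles$col == 1] <- TRUE

  inside <- select_invasive_front(tiles, "inside")
  expect_equal(nrow(inside), 1)
  expect_true(inside$row == 1 && inside$col == 1)

  outside <- select_invasive_front(tiles, "outside")
  expect_equal(nrow(outside), 4)
  expect_setequal(paste(outside$row, outside$col),
                  c("0 1", "1 0", "1 2", "2 1"))

  both <- select_invasive_front(tiles, "both")
  expect_setequal(paste(both$row, both$col),
                  c(paste(inside$row, inside$col),
                    paste(outside$row, outside$col)))

  # full annotation: no boundary inside the grid
  all_tumor <- tiles; all_tumor$is_tumor <- TRUE
  expect_equal(nrow(select_invasive_front(all_tumor, "inside")), 0)

  # empty annotation
  none <- tiles; none$is_tumor <- FALSE
  expect_equal(nrow(select_invasive_front(none, "both")), 0)

  # both is a superset of inside on random tumor patterns
  set.seed(11)
  for (i in 1:20) {
    t1 <- tiles
    t1$is_tumor <- runif(9) < 0.5
    b <- select_invasive_front(t1, "both")
    ins <- select_invasive_front(t1, "inside")
    expect_true(all(paste(ins$row, ins$col) %in% paste(b$row, b$col)))
  }
})

test_that("tile stacks partition each slide's valid tumor tiles", {
  tiles <- do.call(rbind, lapply(c("a", "b"), function(sid)
    data.frame(slide_id = sid, patient_id = sid, row = 0:9, col = 0,
               is_valid = TRUE, is_tumor = TRUE, label = "met")))
  st <- make_tile_stacks(tiles, n = 3, seed = 1)
  expect_equal(nrow(st), 2 * 9)                   # floor(10/3)=3 stacks of 3 per slide
  expect_equal(length(unique(st$stack_id)), 6)
  expect_equal(unname(table(st$stack_id)), rep(3L, 6), ignore_attr = TRUE)
  expect_false(anyDuplicated(paste(st$slide_id, st$row, st$col)) > 0)
  expect_true(all(tapply(st$slide_id, st$stack_id, function(x) length(unique(x))) == 1))
  expect_identical(st, make_tile_stacks(tiles, n = 3, seed = 1))

  one <- make_tile_stacks(tiles, n = 1, seed = 1)
  expect_equal(nrow(one), 20)
  expect_equal(length(unique(one$stack_id)), 20)  # single-tile mode

  expect_warning(big <- make_tile_stacks(tiles, n = 99, seed = 1), "exceeds")
  expect_equal(nrow(big), 0)
})
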
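test_that("slide generation is deterministic and seed-sensitive", {
  spec <- synthetic_slide_spec("s1", cohort = "rapid_met", width_px = 128,
                               height_px = 128, seed = 7)
  a <- generate_slide(spec)
  b <- generate_slide(spec)
  expect_identical(a, b)
  spec2 <- synthetic_slide_spec("s1", cohort = "rapid_met", width_px = 128,
                                height_px = 128, seed = 8)
  expect_false(identical(generate_slide(spec2)$rgb_image, a$rgb_image))
})

test_that("texture effect 0 makes cohorts pixel-identical; effect 1 darkens the metastatic class", {
  mk <- function(cohort, effect) {
    generate_slide(synthetic_slide_spec("s", cohort = cohort, width_px = 160,
                                        height_px = 160,
                                        texture_effect = effect, seed = 5))
  }
  a <- mk("non_met", 0); b <- mk("rapid_met", 0)
  expect_identical(a$rgb_image, b$rgb_image)  # same seed family, zero effect
  a1 <- mk("non_met", 1); b1 <- mk("rapid_met", 1)
  # more / larger nuclei => lower mean intensity inside the annotation
  expect_lt(mean(b1$rgb_image[, , 1][b1$annotation_mask == 1]),
            mean(a1$rgb_image[, , 1][a1$annotation_mask == 1]))
})

test_that("slides without annotation are near-white with an empty mask", {
  spec <- synthetic_slide_spec("s", cohort = "non_met", width_px = 64,
                               height_px = 64, annotation_polygons = list(),
                               seed = 1)
  sl <- generate_slide(spec)
  expect_true(all(sl$annotation_mask == 0))
  expect_gt(min(sl$rgb_image), 230)
})

test_that("out-of-bounds polygons are rejected", {
  poly <- cbind(c(-10, 50, 50), c(10, 10, 50))
  expect_error(
    synthetic_slide_spec("s", cohort = "non_met", width_px = 64, height_px = 64,
                         annotation_polygons = list(poly)),
    "outside image bounds")
})

test_that("cohort tables have requested sizes and valid levels", {
  tab <- generate_cohort(c(non_met = 59, rapid_met = 22), seed = 3)
  expect_equal(unname(table(tab$cohort)[c("non_met", "rapid_met")]),
               c(59L, 22L), ignore_attr = TRUE)
  one <- generate_cohort(c(rapid_met = 1), seed = 3)
  expect_equal(nrow(one), 1L)
  expect_true(one$diameter_class %in% c("<10", "10-19.9", "20-29.9", ">=30"))
  expect_true(one$clark %in% c("2-4", "5", "unknown"))
  expect_identical(generate_cohort(c(non_met = 10), seed = 9),
                   generate_cohort(c(non_met = 10), seed = 9))
})

test_that("cohort marginals converge to the published proportions", {
  n <- 10000
  tab <- generate_cohort(c(rapid_met = n, non_met = n), seed = 42)
  rapid <- tab[tab$cohort == "rapid_met", ]
  nonm <- tab[tab$cohort == "non_met", ]
  # 3-sigma multinomial bounds around the published fractions
  check <- function(x, level, p) {
    tol <- 3 * sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(x == level) - p), tol)
  }
  check(rapid$diameter_class, ">=30", 12 / 22)   # 54.5%
  check(rapid$clark, "5", 15 / 22)
  check(nonm$diameter_class, "<10", 22 / 59)
  check(nonm$ai_pred, "met", 14 / 59)
  check(rapid$ai_pred, "met", 14 / 22)
})

test_that("survival generator censors at the cap and keeps DSS events a subset of OS events", {
  tab <- data.frame(tumor_id = sprintf("t%03d", 1:300),
                    cohort = rep(c("non_met", "rapid_met"), each = 150))
  recs <- generate_survival(tab, seed = 5)
  expect_true(all(recs$time_days <= 1826))
  os <- recs[recs$endpoint == "OS", ]
  dss <- recs[recs$endpoint == "DSS", ]
  expect_true(all(dss$tumor_id[dss$event] %in% os$tumor_id[os$event]))
  expect_identical(recs, generate_survival(tab, seed = 5))

  tiny <- generate_survival(tab, hazards_by_stratum = c(non_met = 1e-12,
                                                        rapid_met = 1e-12),
                            seed = 5)
  expect_true(all(!tiny$event))
  expect_true(all(tiny$time_days == 1826))
  km <- km_estimate(tiny$time_days[tiny$endpoint == "OS"],
                    tiny$event[tiny$endpoint == "OS"])
  expect_equal(survival_at(km, 1826), 1, ignore_attr = TRUE)

  expect_error(generate_survival(tab, hazards_by_stratum = c(non_met = 0,
                                                             rapid_met = 1)),
               "positive")
})

test_that("five-year survival ordering follows the hazard ordering", {
  tab <- data.frame(tumor_id = sprintf("t%03d", 1:1000),
                    cohort = rep(c("lo", "hi"), each = 500))
  lam <- c(lo = 1e-4, hi = 1e-3) # hazard ratio 10
  recs <- generate_survival(tab, hazards_by_stratum = lam,
                            dss_flip_fraction = c(lo = 0, hi = 0), seed = 2)
  cur <- km_by_stratum(recs, endpoint = "OS")
  s5 <- vapply(cur, survival_at, numeric(1), t_days = 1826)
  expect_gt(s5[["lo"]], s5[["hi"]])
  # close to the closed-form exponential survival
  expect_lt(abs(s5[["lo"]] - exp(-lam["lo"] * 1826)), 0.06)
  expect_lt(abs(s5[["hi"]] - exp(-lam["hi"] * 1826)), 0.06)
})

test_that("bundled fixtures match the published counts and denominators", {
  fx <- load_paper_fixtures()
  ai <- fx$table2$ai_prediction
  expect_equal(ai$cases[ai$levels == "met"], 14)
  expect_equal(ai$cases[ai$levels == "non_met"], 8)
  expect_equal(ai$controls[ai$levels == "met"], 14)
  expect_equal(ai$controls[ai$levels == "non_met"], 45)
  expect_equal(fx$table2$ai_rfm$cases, c(0, 5, 9, 5))
  expect_equal(fx$table2$ai_rfm$controls, c(32, 20, 4, 0))

  denominators <- list(
    gender = c(22, 59), grade = c(22, 56), diameter = c(22, 59),
    diameter_ge20 = c(22, 59), clark = c(19, 56),
    invasion_beyond_fat = c(21, 59), ajcc8 = c(21, 59), bwh = c(21, 57),
    pathologist_prediction = c(17, 50), ai_prediction = c(22, 59),
    pathologist_clark = c(17, 48), ai_clark = c(19, 56),
    conventional_rfm = c(19, 56), pathologist_rfm = c(16, 48),
    ai_rfm = c(19, 56))
  for (nm in names(denominators)) {
    cc <- fx$table2[[nm]]
    expect_equal(c(sum(cc$cases), sum(cc$controls)), denominators[[nm]],
                 info = nm)
  }
  expect_equal(fx$ai_confusion, list(tp = 14, fn = 8, fp = 14, tn = 45))
})
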
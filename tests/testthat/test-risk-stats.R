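test_that("odds ratios reproduce the published 2x2 cross-products", {
  o <- odds_ratio(14, 8, 14, 45) # AI prediction
  expect_equal(round(o$or, 2), 5.63, tolerance = 0.005)
  expect_equal(odds_ratio(15, 4, 12, 44)$or, 13.75) # Clark 5
  expect_equal(odds_ratio(12, 2, 6, 22)$or, 22)     # diameter >= 30 vs < 10

  sym <- odds_ratio(1, 1, 1, 1)
  expect_equal(sym$or, 1)
  expect_true(sym$ci_low < 1 && sym$ci_high > 1)

  z <- odds_ratio(8, 0, 33, 23)
  expect_false(z$estimable)
  expect_true(is.na(z$or))
  expect_error(odds_ratio(-1, 2, 3, 4), "non-negative")
})

test_that("reciprocal odds ratios multiply to one", {
  set.seed(5)
  for (i in 1:25) {
    cnt <- sample(1:40, 4, replace = TRUE)
    o1 <- odds_ratio(cnt[1], cnt[2], cnt[3], cnt[4])
    o2 <- odds_ratio(cnt[2], cnt[1], cnt[4], cnt[3])
    expect_equal(o1$or * o2$or, 1, tolerance = 1e-12)
  }
})

test_that("ordinal AUROCs reproduce the published concordances", {
  expect_equal(round(ordinal_auc(c(0, 5, 9, 5), c(32, 20, 4, 0)), 3), 0.917)
  expect_equal(round(ordinal_auc(c(2, 8, 9), c(43, 10, 3)), 3), 0.862)
  expect_equal(round(ordinal_auc(c(4, 15), c(44, 12)), 3), 0.788)
  expect_equal(ordinal_auc(c(3, 3, 3), c(6, 6, 6)), 0.5) # identical shapes
  expect_error(ordinal_auc(c(0, 0), c(1, 2)), "at least one")
})

test_that("ordinal AUROC equals the brute-force pair count on random tables", {
  set.seed(6)
  for (i in 1:40) {
    k <- sample(2:6, 1)
    cases <- rpois(k, 3); controls <- rpois(k, 3)
    if (sum(cases) == 0) cases[1] <- 1
    if (sum(controls) == 0) controls[k] <- 1
    expect_equal(ordinal_auc(cases, controls),
                 brute_force_ordinal_auc(cases, controls), tolerance = 1e-12)
  }
})

test_that("collapsing single-class ordinal levels leaves the AUROC unchanged", {
  # the two lowest levels hold controls only: merging them cannot change
  # any case-control pair ordering
  full <- ordinal_auc(c(0, 0, 5, 9), c(30, 2, 4, 0))
  collapsed <- ordinal_auc(c(0, 5, 9), c(32, 4, 0))
  expect_equal(full, collapsed, tolerance = 1e-12)
})

test_that("risk-factor counting models tabulate profiles correctly", {
  # profiles engineered to reproduce the published AI-RFM rows
  mk <- function(n, k, case) {
    if (n == 0) return(NULL)
    data.frame(is_case = case,
               ai_met = rep(k >= 1, n), clark5 = rep(k >= 2, n),
               diam_ge30 = rep(k >= 3, n))
  }
  cases_by_rf <- c(0, 5, 9, 5); controls_by_rf <- c(32, 20, 4, 0)
  profiles <- do.call(rbind, c(
    lapply(0:3, function(k) mk(cases_by_rf[k + 1], k, TRUE)),
    lapply(0:3, function(k) mk(controls_by_rf[k + 1], k, FALSE))))
  rfm <- build_rfm(profiles, c("ai_met", "clark5", "diam_ge30"))
  expect_equal(rfm$cases, cases_by_rf)
  expect_equal(rfm$controls, controls_by_rf)
  expect_equal(round(ordinal_auc(rfm), 3), 0.917)

  # tumors missing a selected factor are excluded from that model only
  profiles$clark5[1] <- NA
  rfm2 <- build_rfm(profiles, c("ai_met", "clark5", "diam_ge30"))
  expect_equal(sum(rfm2$cases) + sum(rfm2$controls), nrow(profiles) - 1)

  expect_error(build_rfm(profiles, character(0)), "no risk factors")
  expect_error(build_rfm(profiles, "nonexistent"), "unknown factor")

  allf <- data.frame(is_case = c(TRUE, FALSE), a = FALSE, b = FALSE)
  rfm0 <- build_rfm(allf, c("a", "b"))
  expect_equal(rfm0$cases, c(1, 0, 0))
  expect_equal(rfm0$controls, c(1, 0, 0))
})

test_that("logistic regression matches the published reference-coded ORs", {
  fx <- load_paper_fixtures()
  diam <- fit_logistic(fx$table2$diameter)
  expect_equal(diam$or[diam$level == ">=30"], 22.00, tolerance = 1e-6)
  expect_equal(round(diam$or[diam$level == "20-29.9"], 2), 7.86, tolerance = 0.005)
  ajcc <- fit_logistic(fx$table2$ajcc8)
  expect_equal(round(ajcc$or[ajcc$level == "T3"], 2), 36.67, tolerance = 0.005)

  # binary predictor: logistic OR equals the 2x2 cross-product exactly
  ai <- fit_logistic(fx$table2$ai_prediction)
  expect_equal(ai$or, odds_ratio(14, 8, 14, 45)$or, tolerance = 1e-6)

  # zero-cell level flagged not estimable (complete separation)
  airfm <- fit_logistic(fx$table2$ai_rfm)
  expect_false(all(airfm$estimable))

  # null consistency: predictor independent of outcome
  set.seed(9)
  n <- 4000
  pred <- sample(c("a", "b", "c"), n, replace = TRUE)
  out <- rbinom(n, 1, 0.3)
  nul <- fit_logistic(out, pred, reference_level = "a")
  expect_true(all(abs(log(nul$or)) < 0.35))
})

test_that("correlation matrices are pairwise-complete with flagged degeneracies", {
  x <- rnorm(50)
  m <- pearson_correlation_matrix(data.frame(a = x, b = -x, c = x + rnorm(50)))
  expect_equal(unname(m["a", "a"]), 1)
  expect_equal(unname(m["a", "b"]), -1)
  expect_true(all(abs(m) <= 1 + 1e-12))
  expect_equal(m, t(m))

  set.seed(10)
  n <- 10000
  z <- rnorm(n)
  u <- 0.3 * z + sqrt(1 - 0.09) * rnorm(n)
  m2 <- pearson_correlation_matrix(data.frame(z = z, u = u))
  expect_lt(abs(m2["z", "u"] - 0.3), 0.03)

  expect_warning(m3 <- pearson_correlation_matrix(data.frame(a = x, k = rep(1, 50))),
                 "zero-variance")
  expect_true(is.na(m3["a", "k"]))
})

test_that("association tests pick Fisher for sparse 2x2 and Pearson otherwise", {
  flat <- association_test(matrix(c(10, 10, 10, 10), 2, 2))
  expect_equal(flat$p_value, 1)
  expect_equal(flat$test_used, "chisq")

  sparse <- association_test(matrix(c(1, 9, 9, 1), 2, 2))
  expect_equal(sparse$test_used, "fisher")
  # exact hypergeometric two-sided oracle
  probs <- dhyper(0:10, 10, 10, 10)
  obs <- dhyper(1, 10, 10, 10)
  expect_equal(sparse$p_value, sum(probs[probs <= obs + 1e-7]), tolerance = 1e-9)

  # published perineural-invasion row: Fisher p = 1.000
  peri <- association_test(contingency_counts(c("absent", "present"),
                                              c(22, 0), c(58, 1)))
  expect_equal(peri$test_used, "fisher")
  expect_equal(round(peri$p_value, 3), 1)

  wide <- association_test(matrix(c(20, 10, 15, 15, 10, 20), 2, 3))
  expect_equal(wide$test_used, "chisq")
  expect_error(association_test(matrix(c(0, 0, 5, 5), 2, 2)), "degenerate")
})
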
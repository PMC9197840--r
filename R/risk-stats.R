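#' Ordered case/control counts for one risk variable
#'
#' Container for a 2 x k table of case (rapidly metastatic) and control
#' (non-metastatic) counts over the ordered levels of a predictor, the
#' common currency of the risk tables: odds ratios come from its 2 x 2
#' sub-tables and ordinal AUROCs from the level ordering.
#'
#' @param levels character vector of ordered levels (low to high risk).
#' @param cases,controls non-negative integer counts per level.
#' @param reference reference level for odds ratios (default the first).
#' @return Object of class `contingency_counts`.
#' @export
contingency_counts <- function(levels, cases, controls, reference = levels[1]) {
  stopifnot(length(levels) == length(cases),
            length(levels) == length(controls),
            all(cases >= 0), all(controls >= 0),
            reference %in% levels)
  structure(list(levels = as.character(levels),
                 cases = as.numeric(cases), controls = as.numeric(controls),
                 reference = reference),
            class = "contingency_counts")
}

#' @export
print.contingency_counts <- function(x, ...) {
  m <- rbind(cases = x$cases, controls = x$controls)
  colnames(m) <- x$levels
  print(m)
  invisible(x)
}

#' Unadjusted odds ratio with Woolf 95% confidence interval
#'
#' For the 2 x 2 table with `a` exposed cases, `b` unexposed cases, `c`
#' exposed controls and `d` unexposed controls: `OR = (a d) / (b c)`, with
#' the log-scale (Woolf) interval
#' `exp(log OR +- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))` and a Wald p-value.
#' Any zero cell makes the ratio not estimable (reported as `NA`, matching
#' the published tables' NA rows, rather than continuity-corrected).
#'
#' @param a,b,c,d non-negative counts (exposed/unexposed cases, then
#'   exposed/unexposed controls).
#' @return Object of class `odds_ratio_result`: `or`, `ci_low`, `ci_high`,
#'   `p_value`, `estimable`.
#' @export
odds_ratio <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(c(a, b, c, d) == 0)) {
    return(structure(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          p_value = NA_real_, estimable = FALSE),
                     class = "odds_ratio_result"))
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- log(or) / se
  structure(list(or = or,
                 ci_low = exp(log(or) - 1.96 * se),
                 ci_high = exp(log(or) + 1.96 * se),
                 p_value = 2 * stats::pnorm(-abs(z)),
                 estimable = TRUE),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  if (!x$estimable) cat("OR not estimable (zero cell)\n")
  else cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), p = %.4g\n",
                   round_half_up(x$or, 2), round_half_up(x$ci_low, 2),
                   round_half_up(x$ci_high, 2), x$p_value))
  invisible(x)
}

#' Concordance AUROC of an ordinal predictor from grouped counts
#'
#' Treats the level index as the score of every tumor in that level and
#' computes the tie-corrected concordance `(W + T/2) / (n1 n0)`, where `W`
#' counts case-control pairs with the case at a strictly higher level and
#' `T` pairs tied on level. This is the AUROC of the ordinal predictor.
#'
#' @param x a [contingency_counts()], or a numeric vector of case counts if
#'   `controls` is given.
#' @param controls control counts per level (when `x` is a plain vector).
#' @return AUROC in `[0, 1]`.
#' @export
ordinal_auc <- function(x, controls = NULL) {
  if (inherits(x, "contingency_counts")) {
    cases <- x$cases; controls <- x$controls
  } else cases <- x
  stopifnot(length(cases) == length(controls))
  n1 <- sum(cases); n0 <- sum(controls)
  if (n1 == 0 || n0 == 0) stop("need at least one case and one control", call. = FALSE)
  below <- cumsum(c(0, controls[-length(controls)]))
  W <- sum(cases * below)
  T <- sum(cases * controls)
  (W + T / 2) / (n1 * n0)
}

#' Per-tumor risk-factor profiles and counting models
#'
#' A risk-factor model (RFM) counts, per tumor, how many of a selected set
#' of binary risk factors are present (e.g. AI prediction metastatic,
#' Clark's level 5, diameter >= 30 mm for the AI-RFM) and uses that count
#' as an ordinal predictor. Tumors missing any selected factor are excluded
#' from that model, which is why published denominators differ between
#' models.
#'
#' @param profiles `data.frame` with one row per tumor, a logical `is_case`
#'   column and logical (NA allowed) risk-factor columns.
#' @param selected_factors character vector naming the factor columns.
#' @return A [contingency_counts()] over the risk-factor count `0..m`.
#' @export
build_rfm <- function(profiles, selected_factors) {
  if (length(selected_factors) == 0)
    stop("no risk factors selected", call. = FALSE)
  missing_cols <- setdiff(selected_factors, names(profiles))
  if (length(missing_cols) > 0)
    stop("unknown factor name(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  stopifnot("is_case" %in% names(profiles))
  fm <- as.matrix(profiles[, selected_factors, drop = FALSE])
  keep <- stats::complete.cases(fm)
  fm <- fm[keep, , drop = FALSE]
  is_case <- profiles$is_case[keep]
  rf <- rowSums(fm)
  m <- length(selected_factors)
  contingency_counts(
    levels = as.character(0:m),
    cases = tabulate(rf[is_case] + 1L, nbins = m + 1L),
    controls = tabulate(rf[!is_case] + 1L, nbins = m + 1L)
  )
}

#' Risk-factor profiles from a cohort table
#'
#' Derives the standard binary risk factors (AI metastatic, Clark's level
#' 5, diameter >= 30 mm, pathologist metastatic, high grade (3)) from a
#' cohort table as produced by [generate_cohort()]; unknown /
#' cannot-be-assessed entries become `NA`.
#'
#' @param cohort_table cohort `data.frame`.
#' @return `data.frame` of logical risk-factor columns plus `is_case`.
#' @export
risk_factor_profiles <- function(cohort_table) {
  na_if_level <- function(x, na_levels, true_level) {
    out <- x == true_level
    out[x %in% na_levels] <- NA
    out
  }
  data.frame(
    tumor_id = cohort_table$tumor_id,
    is_case = cohort_table$cohort == "rapid_met",
    ai_met = cohort_table$ai_pred == "met",
    clark5 = na_if_level(cohort_table$clark, "unknown", "5"),
    diam_ge30 = cohort_table$diameter_class == ">=30",
    pathologist_met = na_if_level(cohort_table$pathologist_pred,
                                  "cannot_assess", "met"),
    high_grade = na_if_level(cohort_table$grade, "unknown", "3"),
    stringsAsFactors = FALSE
  )
}

#' Reference-coded logistic regression for one categorical predictor
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares
#' via [stats::glm()]) of a binary outcome on a single categorical
#' predictor, dummy-coded against a stated reference level; per-level odds
#' ratios with Wald 95% intervals. For a single categorical predictor these
#' ORs equal the corresponding 2 x 2 cross-product ratios. Complete
#' separation is flagged and the affected levels reported not estimable.
#'
#' @param outcome logical/0-1 vector (or a [contingency_counts()], in which
#'   case `predictor` is ignored and the grouped counts are expanded).
#' @param predictor factor/character vector of levels.
#' @param reference_level reference level (default: first level).
#' @return `data.frame` with one row per non-reference level: `level`,
#'   `or`, `ci_low`, `ci_high`, `p_value`, `estimable`.
#' @export
fit_logistic <- function(outcome, predictor = NULL, reference_level = NULL) {
  if (inherits(outcome, "contingency_counts")) {
    cc <- outcome
    predictor <- rep(rep(cc$levels, 2), times = c(cc$cases, cc$controls))
    outcome <- rep(c(1, 0), times = c(sum(cc$cases), sum(cc$controls)))
    reference_level <- reference_level %||% cc$reference
  }
  outcome <- as.numeric(outcome)
  stopifnot(all(outcome %in% c(0, 1)), length(outcome) == length(predictor))
  lev <- unique(as.character(predictor))
  reference_level <- reference_level %||% lev[1]
  stopifnot(reference_level %in% lev)
  f <- stats::relevel(factor(predictor), ref = reference_level)
  fit <- suppressWarnings(stats::glm(outcome ~ f, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  rows <- grep("^f", rownames(sm))
  est <- sm[rows, 1]; se <- sm[rows, 2]; p <- sm[rows, 4]
  # complete separation: divergent coefficients / exploding standard errors
  sep <- abs(est) > 15 | se > 100
  data.frame(level = sub("^f", "", rownames(sm)[rows]),
             or = ifelse(sep, NA_real_, exp(est)),
             ci_low = ifelse(sep, NA_real_, exp(est - 1.96 * se)),
             ci_high = ifelse(sep, NA_real_, exp(est + 1.96 * se)),
             p_value = ifelse(sep, NA_real_, p),
             estimable = !sep,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise-complete Pearson correlation matrix
#'
#' @param variable_table `data.frame` of numeric / ordinal-coded columns;
#'   missing values are handled pairwise.
#' @return Symmetric correlation matrix with unit diagonal; entries
#'   involving a zero-variance column are `NA` (flagged by a warning).
#' @export
pearson_correlation_matrix <- function(variable_table) {
  x <- as.matrix(variable_table)
  stopifnot(is.numeric(x))
  m <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  zero_var <- apply(x, 2, function(v) stats::var(v, na.rm = TRUE) == 0)
  if (any(zero_var, na.rm = TRUE))
    warning("zero-variance column(s): ",
            paste(colnames(x)[which(zero_var)], collapse = ", "))
  diag(m) <- 1
  m
}

#' Two-sided association test for a 2 x k count table
#'
#' Uses Fisher's exact test for a 2 x 2 table with any expected cell at or
#' below 5, and the (uncorrected) Pearson chi-squared test otherwise — the
#' usual clinical-table convention for sparse tables.
#'
#' @param counts a [contingency_counts()] or a 2 x k matrix (rows =
#'   cases/controls).
#' @return List with `p_value`, `test_used` (`"fisher"`/`"chisq"`) and
#'   `statistic` (chi-squared only).
#' @export
association_test <- function(counts) {
  m <- if (inherits(counts, "contingency_counts"))
    rbind(counts$cases, counts$controls) else as.matrix(counts)
  stopifnot(nrow(m) == 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: empty row or column", call. = FALSE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (ncol(m) == 2 && any(expected <= 5)) {
    list(p_value = stats::fisher.test(m)$p.value, test_used = "fisher",
         statistic = NA_real_)
  } else {
    ch <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(p_value = ch$p.value, test_used = "chisq",
         statistic = unname(ch$statistic))
  }
}

#' Published-style risk table from contingency fixtures
#'
#' For each fixture: the ordinal AUROC over its levels and, per
#' non-reference level, the unadjusted odds ratio against the reference
#' level — the layout of the published risk analysis.
#'
#' @param fixtures named list of [contingency_counts()] (e.g.
#'   `load_paper_fixtures()$table2`).
#' @return `data.frame` with `variable`, `level`, `or`, `ci_low`,
#'   `ci_high`, `or_p`, `auroc`.
#' @export
risk_table <- function(fixtures) {
  rows <- lapply(names(fixtures), function(nm) {
    cc <- fixtures[[nm]]
    auc <- ordinal_auc(cc)
    ref <- match(cc$reference, cc$levels)
    other <- setdiff(seq_along(cc$levels), ref)
    do.call(rbind, lapply(other, function(i) {
      o <- odds_ratio(cc$cases[i], cc$cases[ref], cc$controls[i], cc$controls[ref])
      data.frame(variable = nm, level = cc$levels[i], or = o$or,
                 ci_low = o$ci_low, ci_high = o$ci_high, or_p = o$p_value,
                 auroc = auc, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
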
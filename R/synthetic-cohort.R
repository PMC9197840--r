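# Per-cohort marginal distributions of the clinicopathological variables for
# the published study cohorts (non-metastatic n = 59, rapid metastasis n = 22).
# The slowly metastatic cohort is not tabulated per-variable in the source
# cohorts' table and reuses the non-metastatic marginals.
cohort_marginals <- function() {
  list(
    sex = list(levels = c("male", "female"),
               non_met = c(37, 22), rapid_met = c(17, 5)),
    grade = list(levels = c("1", "2", "3", "unknown"),
                 non_met = c(32, 18, 6, 3), rapid_met = c(8, 10, 4, 0)),
    diameter_class = list(levels = c("<10", "10-19.9", "20-29.9", ">=30"),
                          non_met = c(22, 24, 7, 6), rapid_met = c(2, 3, 5, 12)),
    clark = list(levels = c("2-4", "5", "unknown"),
                 non_met = c(44, 12, 3), rapid_met = c(4, 15, 3)),
    perineural_invasion = list(levels = c("no", "yes"),
                               non_met = c(58, 1), rapid_met = c(22, 0)),
    lymphovascular_invasion = list(levels = c("no", "yes"),
                                   non_met = c(58, 1), rapid_met = c(20, 2)),
    invasion_beyond_fat = list(levels = c("no", "yes", "unknown"),
                               non_met = c(49, 10, 0), rapid_met = c(8, 13, 1)),
    ajcc8 = list(levels = c("T1", "T2", "T3", "T4", "unknown"),
                 non_met = c(44, 3, 9, 3, 0), rapid_met = c(2, 3, 15, 1, 1)),
    bwh = list(levels = c("T1", "T2a", "T2b", "T3", "unknown"),
               non_met = c(36, 11, 7, 3, 2), rapid_met = c(1, 6, 13, 1, 1)),
    ai_pred = list(levels = c("non_met", "met"),
                   non_met = c(45, 14), rapid_met = c(8, 14)),
    pathologist_pred = list(levels = c("non_met", "met", "cannot_assess"),
                            non_met = c(40, 10, 9), rapid_met = c(7, 10, 5))
  )
}

#' Generate a synthetic clinicopathological cohort table
#'
#' Samples one row per tumor with each categorical variable drawn from the
#' published per-cohort marginal frequencies (diameter class, Clark's level,
#' grade, staging, invasion flags, AI and pathologist predictions), so the
#' empirical proportions converge to the published ones as `n` grows.
#' Variables are sampled independently within cohort: the generator emulates
#' the marginal, not the joint, distribution. Survival columns are filled by
#' [generate_survival()] with per-cohort exponential hazards.
#'
#' @param n_per_cohort named integer vector with entries `non_met`,
#'   `rapid_met` and optionally `slow_met`.
#' @param seed integer master seed.
#' @param hazards_by_stratum,dss_flip_fraction,follow_up_cap_days passed to
#'   [generate_survival()].
#' @return A `data.frame` with one row per tumor: identifiers, cohort,
#'   `age_years`, `sex`, the Table-style categorical variables, and
#'   `os_days`/`os_event`/`dss_days`/`dss_event`.
#' @examples
#' tab <- generate_cohort(c(non_met = 59, rapid_met = 22), seed = 1)
#' table(tab$cohort)
#' @export
generate_cohort <- function(n_per_cohort = c(non_met = 59, rapid_met = 22),
                            seed = 1L,
                            hazards_by_stratum = default_survival_hazards(),
                            dss_flip_fraction = default_dss_flip(),
                            follow_up_cap_days = 1826L) {
  stopifnot(all(n_per_cohort >= 1), !is.null(names(n_per_cohort)))
  bad <- setdiff(names(n_per_cohort), c("non_met", "rapid_met", "slow_met"))
  if (length(bad) > 0) stop("unknown cohort name(s): ", paste(bad, collapse = ", "))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(derive_seed(seed, "cohort"))

  marg <- cohort_marginals()
  rows <- lapply(names(n_per_cohort), function(cohort) {
    n <- n_per_cohort[[cohort]]
    src <- if (cohort == "rapid_met") "rapid_met" else "non_met"
    out <- data.frame(
      tumor_id = sprintf("%s_%03d", cohort, seq_len(n)),
      cohort = cohort,
      age_years = pmin(93L, pmax(46L, as.integer(round(
        stats::rnorm(n, mean = if (cohort == "rapid_met") 74 else 79, sd = 9))))),
      stringsAsFactors = FALSE
    )
    for (v in names(marg)) {
      p <- marg[[v]][[src]]
      out[[v]] <- sample(marg[[v]]$levels, n, replace = TRUE, prob = p / sum(p))
    }
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  surv <- generate_survival(tab, hazards_by_stratum = hazards_by_stratum,
                            follow_up_cap_days = follow_up_cap_days,
                            dss_flip_fraction = dss_flip_fraction,
                            seed = derive_seed(seed, "survival"))
  os <- surv[surv$endpoint == "OS", ]
  dss <- surv[surv$endpoint == "DSS", ]
  tab$os_days <- os$time_days[match(tab$tumor_id, os$tumor_id)]
  tab$os_event <- os$event[match(tab$tumor_id, os$tumor_id)]
  tab$dss_days <- dss$time_days[match(tab$tumor_id, dss$tumor_id)]
  tab$dss_event <- dss$event[match(tab$tumor_id, dss$tumor_id)]
  tab
}

#' Default per-cohort exponential hazards (per day)
#'
#' Chosen so the synthetic overall-survival pattern matches the published
#' ordering: rapid-metastasis median OS near 1.2 years, slow metastasis near
#' 3.4 years, and high (about 70%) 5-year OS for the non-metastatic cohort.
#'
#' @return Named numeric vector of hazards per day.
#' @export
default_survival_hazards <- function() {
  c(non_met = -log(0.70) / 1826,
    rapid_met = log(2) / 438,   # median 1.2 y
    slow_met = log(2) / 1242)  # median 3.4 y
}

#' Default fraction of OS events flipped to censored to derive DSS
#'
#' Disease-specific survival is derived from overall survival by flipping a
#' per-cohort fraction of death events to censored (death from other causes).
#' Non-metastatic patients never die of the disease; nearly all rapid-cohort
#' deaths are disease-related.
#'
#' @return Named numeric vector of flip fractions in `[0, 1]`.
#' @export
default_dss_flip <- function() {
  c(non_met = 1.0, rapid_met = 0.1, slow_met = 0.2)
}

#' Generate synthetic right-censored survival records
#'
#' Draws exponential event times per stratum, censors administratively at the
#' follow-up cap (default 1826 days, i.e. five years from primary diagnosis),
#' and derives the disease-specific endpoint from the overall one by flipping
#' a per-stratum fraction of events to censored, so DSS events are a subset
#' of OS events and the two endpoints share event times.
#'
#' @param cohort_table `data.frame` with columns `tumor_id` and `cohort`
#'   (the stratum).
#' @param hazards_by_stratum named positive numeric vector, hazard per day
#'   for every stratum present.
#' @param follow_up_cap_days administrative censoring time in days.
#' @param dss_flip_fraction named numeric vector in `[0, 1]` per stratum.
#' @param seed integer seed; output is deterministic given it.
#' @return A long `data.frame` of survival records: `tumor_id`, `stratum`,
#'   `time_days`, `event`, `endpoint` (`"OS"`/`"DSS"`).
#' @export
generate_survival <- function(cohort_table,
                              hazards_by_stratum = default_survival_hazards(),
                              follow_up_cap_days = 1826L,
                              dss_flip_fraction = default_dss_flip(),
                              seed = 1L) {
  stopifnot(all(c("tumor_id", "cohort") %in% names(cohort_table)))
  strata <- unique(cohort_table$cohort)
  missing_h <- setdiff(strata, names(hazards_by_stratum))
  if (length(missing_h) > 0)
    stop("no hazard given for stratum: ", paste(missing_h, collapse = ", "))
  if (any(hazards_by_stratum[strata] <= 0))
    stop("hazards must be strictly positive")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)

  lam <- hazards_by_stratum[cohort_table$cohort]
  raw <- stats::rexp(nrow(cohort_table), rate = lam)
  os_event <- raw <= follow_up_cap_days
  os_days <- as.integer(ceiling(pmin(raw, follow_up_cap_days)))

  flip_p <- dss_flip_fraction[cohort_table$cohort]
  flip_p[is.na(flip_p)] <- 0
  flip <- stats::runif(nrow(cohort_table)) < flip_p
  dss_event <- os_event & !flip
  dss_days <- os_days

  rbind(
    data.frame(tumor_id = cohort_table$tumor_id, stratum = cohort_table$cohort,
               time_days = os_days, event = os_event, endpoint = "OS",
               stringsAsFactors = FALSE),
    data.frame(tumor_id = cohort_table$tumor_id, stratum = cohort_table$cohort,
               time_days = dss_days, event = dss_event, endpoint = "DSS",
               stringsAsFactors = FALSE)
  )
}

#' Load the bundled published contingency-count fixtures
#'
#' Returns, verbatim from the published risk tables, the case/control counts
#' per ordered predictor level for every variable and risk-factor model
#' (AI prediction, pathologist prediction, Clark's level, diameter, invasion
#' beyond fat, AJCC-8, BWH, the two-way AI/pathologist + Clark combinations,
#' and the conventional, pathologist and AI risk-factor counting models),
#' plus the slide-level AI-prediction confusion counts. Cases are rapidly
#' metastatic primary tumors, controls non-metastatic ones; unknown levels
#' are already excluded, so denominators differ per variable.
#'
#' @return A list with elements `table2` (named list of
#'   [contingency_counts()] objects), `table1` (perineural and
#'   lymphovascular counts), and `ai_confusion` (list `tp`, `fn`, `fp`,
#'   `tn`).
#' @examples
#' fx <- load_paper_fixtures()
#' fx$table2$ai_prediction
#' @export
load_paper_fixtures <- function() {
  path <- system.file("extdata", "table2_counts.json", package = "metrisk",
                      mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  as_cc <- function(x) contingency_counts(x$levels, x$cases, x$controls,
                                          reference = x$reference)
  list(
    table2 = lapply(raw$table2, as_cc),
    table1 = lapply(raw$table1[c("perineural_invasion",
                                 "lymphovascular_invasion")], as_cc),
    ai_confusion = raw$table1$ai_confusion
  )
}
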
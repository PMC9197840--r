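# Independent oracles used across tests; deliberately brute-force and simple
# so they share no code with the implementation they check.

# All-pairs concordance AUROC on raw scores.
brute_force_auc <- function(scores, labels) {
  cs <- scores[as.logical(labels)]
  ct <- scores[!as.logical(labels)]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# All-pairs concordance from grouped ordinal counts.
brute_force_ordinal_auc <- function(cases, controls) {
  s <- rep(seq_along(cases), times = cases)
  t <- rep(seq_along(controls), times = controls)
  brute_force_auc(c(s, t), c(rep(TRUE, length(s)), rep(FALSE, length(t))))
}

# Hand product-limit estimator (events precede censorings at ties).
hand_km <- function(time, event) {
  ev_times <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = ev_times, surv = NA_real_)
  for (i in seq_along(ev_times)) {
    tj <- ev_times[i]
    n_j <- sum(time >= tj)
    d_j <- sum(time == tj & event)
    s <- s * (1 - d_j / n_j)
    out$surv[i] <- s
  }
  out
}

# Random score grid with a random validity pattern (at least one valid cell).
random_score_grid <- function(nr, nc, slide_id = "g") {
  sc <- matrix(runif(nr * nc, -50, 50), nr, nc)
  valid <- matrix(runif(nr * nc) < 0.8, nr, nc)
  if (!any(valid)) valid[1, 1] <- TRUE
  sc[!valid] <- NA
  structure(list(slide_id = slide_id, scores = sc, valid = valid),
            class = "score_grid")
}

# Small fully-synthetic tile set with separable features, for classifier
# tests that should not pay for image rendering.
toy_tile_set <- function(n_slides_per_class = 6, tiles_per_slide = 8,
                         effect = 2, seed = 1) {
  set.seed(seed)
  rows <- list(); feats <- list()
  i <- 0
  for (cls in c("non_met", "rapid_met")) {
    for (s in seq_len(n_slides_per_class)) {
      i <- i + 1
      sid <- sprintf("%s_%02d", cls, s)
      shift <- if (cls == "rapid_met") effect else 0
      f <- matrix(rnorm(tiles_per_slide * 5, mean = shift), tiles_per_slide, 5)
      k <- floor(sqrt(tiles_per_slide))
      rows[[i]] <- data.frame(
        slide_id = sid, patient_id = sid,
        row = (seq_len(tiles_per_slide) - 1) %/% k,
        col = (seq_len(tiles_per_slide) - 1) %% k,
        is_valid = TRUE, is_tumor = TRUE,
        label = cls, cohort = cls, scan_batch = "A",
        stringsAsFactors = FALSE)
      feats[[i]] <- f
    }
  }
  list(tiles = do.call(rbind, rows), features = do.call(rbind, feats))
}
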
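#' Shift and scale a probability to the tile score range
#'
#' Maps a metastasis probability `p` in `[0, 1]` to the tile score
#' `100 * p - 50` in `[-50, 50]`: the probability is scaled to `[0, 100]`
#' and shifted so that 0 is the decision threshold. The map is affine and
#' invertible ([unshift_scale()]).
#'
#' @param p numeric probabilities in `[0, 1]`.
#' @return Scores in `[-50, 50]`.
#' @export
shift_scale <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  100 * p - 50
}

#' @rdname shift_scale
#' @param s scores in `[-50, 50]`.
#' @export
unshift_scale <- function(s) (s + 50) / 100

#' Build a slide score grid from out-of-fold tile probabilities
#'
#' @param oof tile records of one slide with a `prob` column (from
#'   [train_cv()]); only valid tumor tiles carry scores.
#' @param n_rows,n_cols grid size; defaults to the bounding grid of the
#'   records.
#' @param cells `"valid_tumor"` (default: valid tumor tiles carry scores)
#'   or `"scored"` (any tile with a probability; used by front modes).
#' @return Object of class `score_grid`: list with `slide_id`, `scores`
#'   (matrix with `NA` at invalid cells) and `valid` (logical matrix).
#' @export
score_grid <- function(oof, n_rows = max(oof$row) + 1L, n_cols = max(oof$col) + 1L,
                       cells = c("valid_tumor", "scored")) {
  cells <- match.arg(cells)
  stopifnot(length(unique(oof$slide_id)) == 1L, "prob" %in% names(oof))
  sc <- matrix(NA_real_, n_rows, n_cols)
  valid <- matrix(FALSE, n_rows, n_cols)
  sel <- if (cells == "valid_tumor") oof$is_valid & oof$is_tumor else TRUE
  use <- oof[sel & !is.na(oof$prob), , drop = FALSE]
  sc[cbind(use$row + 1L, use$col + 1L)] <- shift_scale(use$prob)
  valid[cbind(use$row + 1L, use$col + 1L)] <- TRUE
  structure(list(slide_id = oof$slide_id[1], scores = sc, valid = valid),
            class = "score_grid")
}

#' @export
print.score_grid <- function(x, ...) {
  cat(sprintf("Score grid '%s': %d x %d tiles, %d valid\n", x$slide_id,
              nrow(x$scores), ncol(x$scores), sum(x$valid)))
  invisible(x)
}

#' Spatial median smoothing of a score grid
#'
#' A `window x window` forward window is moved along the grid: the value at
#' cell `(r, c)` is replaced by the median of the valid scores in rows
#' `[r, r + window)` and columns `[c, c + window)`, clipped at the grid
#' borders. An even number of values takes the arithmetic mean of the two
#' central order statistics. Cells whose window holds no valid score, and
#' invalid cells, are left unchanged. The default window of 2 follows the
#' published smoothing of prediction maps.
#'
#' @param grid a [score_grid()].
#' @param window window size (tiles), `>= 1`.
#' @return A smoothed `score_grid`.
#' @export
median_smooth <- function(grid, window = 2L) {
  stopifnot(inherits(grid, "score_grid"), window >= 1)
  sc <- grid$scores
  out <- sc
  nr <- nrow(sc); nc <- ncol(sc)
  for (r in seq_len(nr)) {
    rr <- r:min(nr, r + window - 1L)
    for (c in seq_len(nc)) {
      if (!grid$valid[r, c]) next
      cc <- c:min(nc, c + window - 1L)
      vals <- sc[rr, cc]
      vals <- vals[grid$valid[rr, cc]]
      if (length(vals) > 0) out[r, c] <- stats::median(vals)
    }
  }
  structure(list(slide_id = grid$slide_id, scores = out, valid = grid$valid),
            class = "score_grid")
}

#' Slide-level decision from a smoothed score grid
#'
#' The slide score is the arithmetic mean of the (smoothed) valid tile
#' scores; the slide is called metastatic when the mean score is strictly
#' above the decision threshold 0 ("mean" vote — the published
#' operationalization of the tile majority vote). A literal tile-count
#' majority is available as `vote = "count"` (ties and a mean of exactly 0
#' resolve to non-metastatic).
#'
#' @param grid a [score_grid()], normally after [median_smooth()].
#' @param true_label optional known label carried into the result.
#' @param vote `"mean"` (default) or `"count"`.
#' @return A one-row `data.frame`: `slide_id`, `mean_score`,
#'   `predicted_label`, `true_label`.
#' @export
slide_score <- function(grid, true_label = NA_character_,
                        vote = c("mean", "count")) {
  vote <- match.arg(vote)
  stopifnot(inherits(grid, "score_grid"))
  vals <- grid$scores[grid$valid]
  if (length(vals) == 0L) stop("no valid tiles on slide ", grid$slide_id, call. = FALSE)
  m <- mean(vals)
  pred_met <- if (vote == "mean") m > 0 else sum(vals > 0) > sum(vals <= 0)
  data.frame(slide_id = grid$slide_id, mean_score = m,
             predicted_label = if (pred_met) "met" else "non_met",
             true_label = true_label, stringsAsFactors = FALSE)
}

#' Tie-corrected AUROC
#'
#' Computes the concordance form of the area under the ROC curve,
#' `(W + T/2) / (n1 * n0)`, where `W` counts case-control pairs in which the
#' case scores strictly higher and `T` counts tied pairs — equivalently the
#' Wilcoxon rank-sum statistic with average ranks.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1): `TRUE` = case.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve with AUROC
#'
#' Sweeps the decision threshold over the distinct score values (ties
#' grouped), yielding a monotone curve from (0, 0) to (1, 1), plus the
#' tie-corrected [auroc()].
#'
#' @inheritParams auroc
#' @return Object of class `roc_points`: `data.frame` of `threshold`,
#'   `fpr`, `tpr` with attribute `auroc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  a <- auroc(scores, labels) # validates class presence
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- c(s[-length(s)] != s[-1], TRUE) # last index of each tied block
  tpr <- cumsum(y)[keep] / sum(labels)
  fpr <- cumsum(!y)[keep] / sum(!labels)
  out <- data.frame(threshold = c(Inf, s[keep]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  structure(out, auroc = a, class = c("roc_points", "data.frame"))
}

#' @export
plot.roc_points <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("ROC (AUROC = %.3f)", attr(x, "auroc")), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Sensitivity, specificity and accuracy of slide decisions
#'
#' @param decisions `data.frame` with `predicted_label` and `true_label`
#'   (values `"met"`-like vs `"non_met"`), or counts via `tp`, `fn`, `fp`,
#'   `tn`.
#' @param tp,fn,fp,tn optional confusion counts used instead of
#'   `decisions`.
#' @return List with exact fractions (`sensitivity`, `specificity`,
#'   `accuracy`), integer-rounded display percentages (`*_pct`) and the
#'   counts.
#' @export
confusion_summary <- function(decisions = NULL, tp = NULL, fn = NULL,
                              fp = NULL, tn = NULL) {
  if (!is.null(decisions)) {
    stopifnot(nrow(decisions) >= 1)
    pred <- decisions$predicted_label != "non_met"
    truth <- decisions$true_label != "non_met"
    tp <- sum(pred & truth); fn <- sum(!pred & truth)
    fp <- sum(pred & !truth); tn <- sum(!pred & !truth)
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / (tp + fn + fp + tn)
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       sensitivity = sens, specificity = spec, accuracy = acc,
       sensitivity_pct = round_half_up(100 * sens),
       specificity_pct = round_half_up(100 * spec),
       accuracy_pct = round_half_up(100 * acc))
}

#' Render a probability map of a slide
#'
#' Maps tile scores back onto the slide footprint with a diverging
#' blue-white-red palette over `[-50, 50]` (red = high metastasis score),
#' paints everything outside the annotation/valid tiles white, and embeds a
#' color legend strip along the bottom edge.
#'
#' @param grid a [score_grid()].
#' @param tile_px pixels per tile in the rendered map (default 16).
#' @param file optional PNG path; if given the map is written there.
#' @return The rendered `h x w x 3` array (0..255), invisibly if `file` is
#'   given.
#' @export
render_probability_map <- function(grid, tile_px = 16L, file = NULL) {
  stopifnot(inherits(grid, "score_grid"))
  pal <- grDevices::colorRamp(c("#2166AC", "#FFFFFF", "#B2182B"))
  nr <- nrow(grid$scores); nc <- ncol(grid$scores)
  h <- nr * tile_px; legend_h <- max(4L, tile_px %/% 2)
  img <- array(255, dim = c(h + legend_h, nc * tile_px, 3))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!grid$valid[r, c]) next
    col <- pal((grid$scores[r, c] + 50) / 100)
    rr <- ((r - 1) * tile_px + 1):(r * tile_px)
    cc <- ((c - 1) * tile_px + 1):(c * tile_px)
    for (ch in 1:3) img[rr, cc, ch] <- col[ch]
  }
  # legend: full score range left (blue, -50) to right (red, +50)
  leg <- pal(seq(0, 1, length.out = nc * tile_px))
  for (ch in 1:3) img[(h + 1):(h + legend_h), , ch] <-
    matrix(leg[, ch], legend_h, nc * tile_px, byrow = TRUE)
  if (!is.null(file)) {
    write_image_png(img, file)
    return(invisible(img))
  }
  img
}
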
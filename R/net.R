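# Compact residual dense network for tile classification, trained with
# binary cross-entropy and Adam. The trunk is a stack of identity-skip
# blocks  z <- z + relu(z W1 + b1) W2 + b2  over the pooled tile features;
# the head follows the published design: one hidden dense layer under heavy
# (inverted) dropout, then a single sigmoid unit. All weights are authored
# here so the trainer is fully deterministic given its seed.

net_init <- function(p, config) {
  h <- config$hidden; hh <- config$head_width
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  blocks <- lapply(seq_len(config$n_blocks), function(i)
    list(W1 = he(h, h), b1 = numeric(h), W2 = he(h, h) * 0.1, b2 = numeric(h)))
  list(Win = he(p, h), bin = numeric(h), blocks = blocks,
       Wh = he(h, hh), bh = numeric(hh), Wo = he(hh, 1), bo = 0)
}

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass; when `dropout_mask` is supplied (training) the head hidden
# layer uses inverted dropout. Returns intermediates for backprop.
net_forward <- function(par, X, dropout_mask = NULL) {
  z <- relu(sweep(X %*% par$Win, 2, par$bin, "+"))
  acts <- vector("list", length(par$blocks))
  for (i in seq_along(par$blocks)) {
    b <- par$blocks[[i]]
    a <- relu(sweep(z %*% b$W1, 2, b$b1, "+"))
    acts[[i]] <- list(zin = z, a = a)
    z <- z + sweep(a %*% b$W2, 2, b$b2, "+")
  }
  hh <- relu(sweep(z %*% par$Wh, 2, par$bh, "+"))
  hd <- if (is.null(dropout_mask)) hh else hh * dropout_mask
  logit <- drop(hd %*% par$Wo) + par$bo
  list(z0 = NULL, z = z, acts = acts, hh = hh, hd = hd,
       logit = logit, prob = sigmoid(logit))
}

# Gradient structure mirrors the parameter structure exactly (same field
# order and shapes) so flattened gradients align with flattened parameters.
net_gradients <- function(par, X, y, w, fw, dropout_mask) {
  dlogit <- matrix(w * (fw$prob - y) / sum(w), ncol = 1) # BCE, sample weights
  gWo <- t(fw$hd) %*% dlogit
  gbo <- sum(dlogit)
  dhd <- dlogit %*% t(par$Wo)
  if (!is.null(dropout_mask)) dhd <- dhd * dropout_mask
  dhh <- dhd * (fw$hh > 0)
  gWh <- t(fw$z) %*% dhh
  gbh <- colSums(dhh)
  dz <- dhh %*% t(par$Wh)
  gblocks <- vector("list", length(par$blocks))
  for (i in rev(seq_along(par$blocks))) {
    b <- par$blocks[[i]]; ac <- fw$acts[[i]]
    gW2 <- t(ac$a) %*% dz
    gb2 <- colSums(dz)
    da <- (dz %*% t(b$W2)) * (ac$a > 0)
    gblocks[[i]] <- list(W1 = t(ac$zin) %*% da, b1 = colSums(da),
                         W2 = gW2, b2 = gb2)
    dz <- dz + da %*% t(b$W1) # skip connection adds identity gradient
  }
  z0pre <- sweep(X %*% par$Win, 2, par$bin, "+")
  dz0 <- dz * (z0pre > 0)
  list(Win = t(X) %*% dz0, bin = colSums(dz0), blocks = gblocks,
       Wh = gWh, bh = gbh, Wo = gWo, bo = gbo)
}

# Flatten/unflatten parameter lists so Adam state stays a plain vector pair.
par_unlist <- function(par) unlist(par, use.names = FALSE)
par_relist <- function(v, skeleton) relist_num(v, skeleton)
relist_num <- function(v, skel) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    k <- length(x)
    out <- v[(pos + 1L):(pos + k)]
    pos <<- pos + k
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }
  walk(skel)
}

bce_loss <- function(prob, y, w) {
  eps <- 1e-12
  -sum(w * (y * log(prob + eps) + (1 - y) * log(1 - prob + eps))) / sum(w)
}

net_train <- function(X, y, config, weights = NULL) {
  stopifnot(nrow(X) == length(y))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(config$seed)
  if (is.null(weights)) weights <- rep(1, length(y))
  par <- net_init(ncol(X), config)
  theta <- par_unlist(par)
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
  loss_hist <- numeric(config$epochs)
  n <- nrow(X)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]; wb <- weights[idx]
      mask <- if (config$dropout > 0)
        matrix(stats::rbinom(length(idx) * config$head_width, 1, 1 - config$dropout),
               length(idx), config$head_width) / (1 - config$dropout)
      else NULL
      fw <- net_forward(par, Xb, mask)
      if (!all(is.finite(fw$logit)))
        stop("non-finite activations during training (epoch ", ep, ")", call. = FALSE)
      g <- net_gradients(par, Xb, yb, wb, fw, mask)
      gv <- par_unlist(g)
      if (config$weight_decay > 0) gv <- gv + config$weight_decay * theta
      t <- t + 1L
      m <- b1 * m + (1 - b1) * gv
      v <- b2 * v + (1 - b2) * gv^2
      theta <- theta - config$lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
      par <- par_relist(theta, par)
    }
    fw_all <- net_forward(par, X)
    loss_hist[ep] <- bce_loss(fw_all$prob, y, weights)
    if (!is.finite(loss_hist[ep]))
      stop("non-finite training loss at epoch ", ep, call. = FALSE)
  }
  list(par = par, loss = loss_hist)
}
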
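# Minimal dense/convolutional/recurrent network engine: forward and
# backpropagation in plain matrix code with the Adam optimizer. Sized for the
# small 1-D radiomic-vector models this package trains; gradients are
# verified against numerical differentiation in the test suite.

.adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.hard_sigmoid <- function(z) pmin(pmax(0.2 * z + 0.5, 0), 1)
.hard_sigmoid_grad <- function(z) ifelse(z > -2.5 & z < 2.5, 0.2, 0)
.sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- 1-D convolution primitives (batch x length x channels arrays) --------

.im2col <- function(X, k) {
  # X: B x L x C -> (B*Lout) x (k*C)
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  Lout <- L - k + 1L
  out <- matrix(0, B * Lout, k * C)
  for (dk in seq_len(k)) {
    sl <- X[, dk:(dk + Lout - 1L), , drop = FALSE]
    out[, ((dk - 1L) * C + 1L):(dk * C)] <- matrix(sl, B * Lout, C)
  }
  out
}

.col2im <- function(M, k, B, L, C) {
  Lout <- L - k + 1L
  X <- array(0, c(B, L, C))
  for (dk in seq_len(k)) {
    sl <- array(M[, ((dk - 1L) * C + 1L):(dk * C)], c(B, Lout, C))
    X[, dk:(dk + Lout - 1L), ] <- X[, dk:(dk + Lout - 1L), , drop = FALSE] + sl
  }
  X
}

.conv_forward <- function(X, W, b) {
  # W: (k*Cin) x Cout with attr k
  k <- attr(W, "k")
  d <- dim(X); B <- d[1]; L <- d[2]
  Lout <- L - k + 1L
  Xc <- .im2col(X, k)
  Y <- sweep(Xc %*% W, 2, b, `+`)
  list(out = array(Y, c(B, Lout, ncol(W))), Xc = Xc, dims = d)
}

.conv_backward <- function(dY, cache, W) {
  k <- attr(W, "k")
  d <- cache$dims
  dYm <- matrix(dY, nrow(cache$Xc), ncol(W))
  dW <- crossprod(cache$Xc, dYm)
  attr(dW, "k") <- k
  db <- colSums(dYm)
  dXc <- dYm %*% t(W)
  dX <- .col2im(dXc, k, d[1], d[2], d[3])
  list(dX = dX, dW = dW, db = db)
}

.pool_forward <- function(X, size = 2L) {
  d <- dim(X); Lout <- d[2] %/% size
  out <- X[, (seq_len(Lout) - 1L) * size + 1L, , drop = FALSE]
  amax <- array(1L, dim(out))
  if (size > 1L) for (s in 2:size) {
    sl <- X[, (seq_len(Lout) - 1L) * size + s, , drop = FALSE]
    upd <- sl > out
    out[upd] <- sl[upd]
    amax[upd] <- s
  }
  list(out = out, amax = amax, dims = d, size = size)
}

.pool_backward <- function(dY, cache) {
  d <- cache$dims; size <- cache$size; Lout <- d[2] %/% size
  dX <- array(0, d)
  for (s in seq_len(size)) {
    m <- (cache$amax == s) * dY
    dX[, (seq_len(Lout) - 1L) * size + s, ] <- m
  }
  dX
}

# ---- CNN definition -------------------------------------------------------

.init_cnn <- function(input_len, spec) {
  fl <- spec$filters; ks <- spec$kernels
  cin <- 1L; L <- input_len
  params <- list()
  for (i in 1:3) {
    sdv <- sqrt(2 / (ks[i] * cin))
    W <- matrix(stats::rnorm(ks[i] * cin * fl[i], 0, sdv), ks[i] * cin, fl[i])
    attr(W, "k") <- ks[i]
    params[[paste0("Wc", i)]] <- W
    params[[paste0("bc", i)]] <- rep(0.01, fl[i])  # small positive: avoids dead ReLU units
    L <- (L - ks[i] + 1L) %/% spec$pool
    cin <- fl[i]
  }
  flat <- L * cin
  params$Wd1 <- matrix(stats::rnorm(flat * spec$dense, 0, sqrt(2 / flat)),
                       flat, spec$dense)
  params$bd1 <- rep(0.01, spec$dense)
  params$Wd2 <- matrix(stats::rnorm(spec$dense, 0, sqrt(2 / spec$dense)),
                       spec$dense, 1)
  params$bd2 <- numeric(1)
  list(params = params, input_len = input_len, spec = spec, flat = flat)
}

.cnn_forward <- function(net, X, train = FALSE) {
  p <- net$params; sp <- net$spec
  B <- nrow(X)
  A <- array(X, c(B, ncol(X), 1L))
  caches <- list()
  drop_sites <- c(FALSE, TRUE, TRUE)  # dropout after conv 2 and 3
  for (i in 1:3) {
    cv <- .conv_forward(A, p[[paste0("Wc", i)]], p[[paste0("bc", i)]])
    Z <- cv$out
    R <- pmax(Z, 0)
    mask <- NULL
    if (train && drop_sites[i] && sp$dropout > 0) {
      mask <- array(stats::rbinom(length(R), 1, 1 - sp$dropout) /
                      (1 - sp$dropout), dim(R))
      R <- R * mask
    }
    pl <- .pool_forward(R, sp$pool)
    caches[[i]] <- list(conv = cv, Z = Z, mask = mask, pool = pl)
    A <- pl$out
  }
  flat <- matrix(A, B, net$flat)
  Z1 <- sweep(flat %*% p$Wd1, 2, p$bd1, `+`)
  H1 <- pmax(Z1, 0)
  m1 <- NULL
  if (train && sp$dropout > 0) {
    m1 <- matrix(stats::rbinom(length(H1), 1, 1 - sp$dropout) /
                   (1 - sp$dropout), nrow(H1), ncol(H1))
    H1 <- H1 * m1
  }
  Z2 <- sweep(H1 %*% p$Wd2, 2, p$bd2, `+`)
  out <- .sigmoid(Z2)
  list(out = as.numeric(out),
       cache = list(caches = caches, flat = flat, Z1 = Z1, H1 = H1, m1 = m1,
                    B = B))
}

.cnn_backward <- function(net, fw, y) {
  p <- net$params; cc <- fw$cache
  B <- cc$B
  dZ2 <- matrix((fw$out - y) / B, B, 1)       # BCE + sigmoid
  g <- list()
  g$Wd2 <- crossprod(cc$H1, dZ2); g$bd2 <- colSums(dZ2)
  dH1 <- dZ2 %*% t(p$Wd2)
  if (!is.null(cc$m1)) dH1 <- dH1 * cc$m1
  dZ1 <- dH1 * (cc$Z1 > 0)
  g$Wd1 <- crossprod(cc$flat, dZ1); g$bd1 <- colSums(dZ1)
  dflat <- dZ1 %*% t(p$Wd1)
  dA <- array(dflat, dim(cc$caches[[3]]$pool$out))
  for (i in 3:1) {
    ci <- cc$caches[[i]]
    dR <- .pool_backward(dA, ci$pool)
    if (!is.null(ci$mask)) dR <- dR * ci$mask
    dZ <- dR * (ci$Z > 0)
    bk <- .conv_backward(dZ, ci$conv, p[[paste0("Wc", i)]])
    g[[paste0("Wc", i)]] <- bk$dW
    g[[paste0("bc", i)]] <- bk$db
    dA <- bk$dX
  }
  g[names(net$params)]
}

# ---- LSTM definition ------------------------------------------------------

.init_lstm <- function(n_maps, spec) {
  H <- spec$hidden
  params <- list()
  for (m in seq_len(n_maps)) {
    params[[paste0("Wx", m)]] <- matrix(stats::rnorm(4 * H, 0, 0.2), 1, 4 * H)
    params[[paste0("Wh", m)]] <- matrix(stats::rnorm(H * 4 * H, 0, 1 / sqrt(H)),
                                        H, 4 * H)
    params[[paste0("bl", m)]] <- numeric(4 * H)
  }
  cat_dim <- n_maps * H
  params$Wd1 <- matrix(stats::rnorm(cat_dim * spec$dense, 0, sqrt(1 / cat_dim)),
                       cat_dim, spec$dense)
  params$bd1 <- numeric(spec$dense)
  params$Wd2 <- matrix(stats::rnorm(spec$dense, 0, sqrt(1 / spec$dense)),
                       spec$dense, 1)
  params$bd2 <- numeric(1)
  list(params = params, n_maps = n_maps, spec = spec)
}

.lstm_branch_forward <- function(Xseq, Wx, Wh, b, H, drop_in = NULL,
                                 drop_rec = NULL) {
  # Xseq: B x T (scalar sequence)
  B <- nrow(Xseq); T <- ncol(Xseq)
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  steps <- vector("list", T)
  for (t in seq_len(T)) {
    xt <- Xseq[, t, drop = FALSE]
    if (!is.null(drop_in)) xt <- xt * drop_in
    hd <- if (!is.null(drop_rec)) h * drop_rec else h
    z <- xt %*% Wx + hd %*% Wh
    z <- sweep(z, 2, b, `+`)
    zi <- z[, 1:H, drop = FALSE]; zf <- z[, (H + 1):(2 * H), drop = FALSE]
    zo <- z[, (2 * H + 1):(3 * H), drop = FALSE]
    zg <- z[, (3 * H + 1):(4 * H), drop = FALSE]
    i <- .hard_sigmoid(zi); f <- .hard_sigmoid(zf); o <- .hard_sigmoid(zo)
    g <- tanh(zg)
    c_prev <- cst
    cst <- f * c_prev + i * g
    tc <- tanh(cst)
    h_new <- o * tc
    steps[[t]] <- list(xt = xt, hd = hd, zi = zi, zf = zf, zo = zo, zg = zg,
                       i = i, f = f, o = o, g = g, c_prev = c_prev, c = cst,
                       tc = tc)
    h <- h_new
  }
  list(h = h, steps = steps)
}

.lstm_branch_backward <- function(dh_T, cache, Wx, Wh, H, drop_in = NULL,
                                  drop_rec = NULL) {
  T <- length(cache$steps)
  dWx <- matrix(0, nrow(Wx), ncol(Wx)); dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4 * H)
  dh <- dh_T; dc <- matrix(0, nrow(dh_T), H)
  for (t in rev(seq_len(T))) {
    s <- cache$steps[[t]]
    do_ <- dh * s$tc
    dtc <- dh * s$o
    dc <- dc + dtc * (1 - s$tc^2)
    di <- dc * s$g; df <- dc * s$c_prev; dg <- dc * s$i
    dzi <- di * .hard_sigmoid_grad(s$zi)
    dzf <- df * .hard_sigmoid_grad(s$zf)
    dzo <- do_ * .hard_sigmoid_grad(s$zo)
    dzg <- dg * (1 - s$g^2)
    dz <- cbind(dzi, dzf, dzo, dzg)
    dWx <- dWx + crossprod(s$xt, dz)
    dWh <- dWh + crossprod(s$hd, dz)
    db <- db + colSums(dz)
    dhd <- dz %*% t(Wh)
    if (!is.null(drop_rec)) dhd <- dhd * drop_rec
    dh <- dhd
    dc <- dc * s$f
  }
  list(dWx = dWx, dWh = dWh, db = db)
}

.lstm_forward <- function(net, X, train = FALSE) {
  p <- net$params; sp <- net$spec
  H <- sp$hidden; nm <- net$n_maps; T <- sp$seq_len
  B <- nrow(X)
  hs <- list(); caches <- list(); drops <- list()
  for (m in seq_len(nm)) {
    Xseq <- X[, ((m - 1) * T + 1):(m * T), drop = FALSE]
    di <- dr <- NULL
    if (train && sp$dropout > 0) {
      di <- matrix(stats::rbinom(B, 1, 1 - sp$dropout) / (1 - sp$dropout), B, 1)
      dr <- matrix(stats::rbinom(B * H, 1, 1 - sp$dropout) / (1 - sp$dropout),
                   B, H)
    }
    br <- .lstm_branch_forward(Xseq, p[[paste0("Wx", m)]],
                               p[[paste0("Wh", m)]], p[[paste0("bl", m)]], H,
                               di, dr)
    hs[[m]] <- br$h; caches[[m]] <- br; drops[[m]] <- list(di = di, dr = dr)
  }
  cat_h <- do.call(cbind, hs)
  Z1 <- sweep(cat_h %*% p$Wd1, 2, p$bd1, `+`)
  H1 <- .sigmoid(Z1)
  m1 <- NULL
  if (train && sp$dropout > 0) {
    m1 <- matrix(stats::rbinom(length(H1), 1, 1 - sp$dropout) /
                   (1 - sp$dropout), nrow(H1), ncol(H1))
    H1 <- H1 * m1
  }
  Z2 <- sweep(H1 %*% p$Wd2, 2, p$bd2, `+`)
  out <- .sigmoid(Z2)
  list(out = as.numeric(out),
       cache = list(caches = caches, drops = drops, cat_h = cat_h, Z1 = Z1,
                    H1 = H1, m1 = m1, B = B))
}

.lstm_backward <- function(net, fw, y) {
  p <- net$params; sp <- net$spec; cc <- fw$cache
  H <- sp$hidden; nm <- net$n_maps
  B <- cc$B
  dZ2 <- matrix((fw$out - y) / B, B, 1)
  g <- list()
  g$Wd2 <- crossprod(cc$H1, dZ2); g$bd2 <- colSums(dZ2)
  dH1 <- dZ2 %*% t(p$Wd2)
  if (!is.null(cc$m1)) dH1 <- dH1 * cc$m1
  s1 <- .sigmoid(cc$Z1)
  dZ1 <- dH1 * s1 * (1 - s1)
  g$Wd1 <- crossprod(cc$cat_h, dZ1); g$bd1 <- colSums(dZ1)
  dcat <- dZ1 %*% t(p$Wd1)
  for (m in seq_len(nm)) {
    dh <- dcat[, ((m - 1) * H + 1):(m * H), drop = FALSE]
    bk <- .lstm_branch_backward(dh, cc$caches[[m]], p[[paste0("Wx", m)]],
                                p[[paste0("Wh", m)]], H,
                                cc$drops[[m]]$di, cc$drops[[m]]$dr)
    g[[paste0("Wx", m)]] <- bk$dWx
    g[[paste0("Wh", m)]] <- bk$dWh
    g[[paste0("bl", m)]] <- bk$db
  }
  g[names(net$params)]
}

# ---- shared training loop -------------------------------------------------

.nn_train <- function(net, forward, backward, x, y01, spec) {
  n <- nrow(x)
  set.seed(spec$seed)
  val_n <- max(2L, round((spec$val_frac %||% 0.2) * n))
  # stratified holdout
  pos <- which(y01 == 1); neg <- which(y01 == 0)
  vn_pos <- max(1L, round(val_n * length(pos) / n))
  vid <- c(sample(pos, min(vn_pos, length(pos))),
           sample(neg, min(val_n - vn_pos, length(neg))))
  tid <- setdiff(seq_len(n), vid)
  bs <- min(spec$batch_size %||% 28L, length(tid))
  state <- .adam_init(net$params)
  best <- list(acc = -1, params = net$params, epoch = 0L)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_accuracy = numeric(0))
  for (ep in seq_len(spec$epochs)) {
    ord <- sample(tid)   # reshuffle each epoch
    losses <- c()
    for (s in seq(1, length(ord), by = bs)) {
      bidx <- ord[s:min(s + bs - 1, length(ord))]
      fw <- forward(net, x[bidx, , drop = FALSE], train = TRUE)
      p <- pmin(pmax(fw$out, 1e-12), 1 - 1e-12)
      losses <- c(losses, -mean(y01[bidx] * log(p) +
                                  (1 - y01[bidx]) * log(1 - p)))
      grads <- backward(net, fw, y01[bidx])
      up <- .adam_step(net$params, grads, state, lr = spec$lr,
                       beta1 = spec$beta1 %||% 0.9,
                       beta2 = spec$beta2 %||% 0.999,
                       eps = spec$eps %||% 1e-8)
      net$params <- up$params; state <- up$state
    }
    pv <- forward(net, x[vid, , drop = FALSE], train = FALSE)$out
    acc <- mean((pv > 0.5) == (y01[vid] == 1))
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses),
                                         val_accuracy = acc))
    if (acc > best$acc) best <- list(acc = acc, params = net$params, epoch = ep)
  }
  net$params <- best$params   # best-validation-epoch weights retained
  list(net = net, history = history, val_accuracy = best$acc,
       best_epoch = best$epoch)
}

#' Train the 1-D convolutional network
#'
#' Nine hidden layers: three 1-D convolution layers (ReLU) each followed by
#' max pooling, a flatten layer, and two dense layers (ReLU then a single
#' sigmoid output unit). Dropout 0.2 is applied after the second and third
#' convolution layers and after the first dense layer. Binary cross-entropy
#' loss, Adam optimizer, stratified 80/20 train/validation split with
#' reshuffling every epoch; the weights of the best validation epoch are
#' retained (no early stopping).
#'
#' @param x feature matrix (428 or 856 columns).
#' @param y labels ("IDHwt"/"IDHmut").
#' @param spec [model_spec()] of kind "CNN1D".
#' @return `trained_model` with `fit` (network), `history`, `val_accuracy`.
#' @export
train_cnn1d <- function(x, y, spec = model_spec("CNN1D")) {
  stopifnot(spec$kind == "CNN1D")
  x <- as.matrix(x)
  if (!ncol(x) %in% c(428L, 856L) && is.null(spec$allow_any_length))
    stop("CNN1D expects a 428- or 856-feature vector")
  y01 <- as.integer(as.character(y) == "IDHmut")
  set.seed(spec$seed)
  net <- .init_cnn(ncol(x), spec)
  tr <- .nn_train(net, .cnn_forward, .cnn_backward, x, y01, spec)
  structure(list(fit = list(type = "cnn", net = tr$net),
                 spec = spec, features = colnames(x),
                 cv_accuracy = tr$val_accuracy, history = tr$history,
                 architecture = cnn_architecture(spec)),
            class = "trained_model")
}

#' Train the LSTM network
#'
#' One LSTM layer per biomarker map — the serial direction of each layer is
#' occupied by that map's 107 radiomic features — so a 428-feature vector
#' uses four LSTM layers and the 856-feature physio-metabolic combination
#' uses eight, followed by two dense layers (sigmoid activations, single
#' output unit). Gates use the hard sigmoid, cell updates tanh; forward and
#' recurrent dropout are 0.2. Adam (lr 0.001, beta1 0.9, beta2 0.999,
#' epsilon 1e-8), training batch 28, stratified 80/20 split, per-epoch
#' shuffling, best-validation-epoch weights retained.
#'
#' @inheritParams train_cnn1d
#' @param spec [model_spec()] of kind "LSTM".
#' @return `trained_model`.
#' @export
train_lstm <- function(x, y, spec = model_spec("LSTM")) {
  stopifnot(spec$kind == "LSTM")
  x <- as.matrix(x)
  if (ncol(x) %% spec$seq_len != 0L)
    stop("feature count is not divisible by the 107-step sequence length")
  n_maps <- ncol(x) %/% spec$seq_len
  y01 <- as.integer(as.character(y) == "IDHmut")
  set.seed(spec$seed)
  net <- .init_lstm(n_maps, spec)
  tr <- .nn_train(net, .lstm_forward, .lstm_backward, x, y01, spec)
  structure(list(fit = list(type = "lstm", net = tr$net),
                 spec = spec, features = colnames(x),
                 cv_accuracy = tr$val_accuracy, history = tr$history,
                 architecture = lstm_architecture(n_maps, spec)),
            class = "trained_model")
}

nn_predict <- function(fit, x) {
  if (fit$type == "cnn") .cnn_forward(fit$net, x, train = FALSE)$out
  else .lstm_forward(fit$net, x, train = FALSE)$out
}

#' Layer sequence of the 1-D CNN (architecture audit)
#' @param spec [model_spec()] of kind "CNN1D".
#' @return Character vector of layer types; dropout sites in an attribute.
#' @export
cnn_architecture <- function(spec = model_spec("CNN1D")) {
  layers <- c("conv", "pool", "conv", "pool", "conv", "pool", "flatten",
              "dense", "dense")
  attr(layers, "dropout_after") <- c("conv2", "conv3", "dense1")
  layers
}

#' Layer sequence of the LSTM model (architecture audit)
#' @param n_maps number of 107-feature map blocks in the input vector.
#' @param spec [model_spec()] of kind "LSTM".
#' @return Character vector: `n_maps` LSTM layers then two dense layers.
#' @export
lstm_architecture <- function(n_maps, spec = model_spec("LSTM")) {
  c(rep("lstm", n_maps), "dense", "dense")
}
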
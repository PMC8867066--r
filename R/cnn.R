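#' Training configuration for the binary fruit classifier
#'
#' Defaults mirror the reference protocol (224 x 224 inputs, Adam with
#' learning rate 1e-5, batch size 30, 50 epochs, flip/90-degree-rotation
#' augmentation, checkpoint at minimum validation loss). The test profile
#' (`cnn_test_config()`) shrinks this to desk scale: 64 x 64 inputs,
#' learning rate 1e-3, 30 epochs (a from-scratch network needs more than a
#' handful of epochs of Adam steps at this data size; pretrained backbones
#' do not).
#'
#' @param input_size square input side in pixels.
#' @param augment use horizontal/vertical flips and 90-degree rotations.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param splits train/validation/prediction fractions (sum to 1).
#' @param channels convolution channel widths for the three blocks.
#' @return object of class `train_config`.
#' @export
train_config <- function(input_size = 224L, augment = TRUE,
                         learning_rate = 1e-5, batch_size = 30L,
                         epochs = 50L, splits = c(0.7, 0.15, 0.15),
                         channels = c(8L, 16L, 32L)) {
  stopifnot(abs(sum(splits) - 1) < 1e-8, epochs >= 1, length(channels) == 3)
  structure(list(input_size = as.integer(input_size), augment = augment,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), splits = splits,
                 channels = as.integer(channels)),
            class = "train_config")
}

#' @rdname train_config
#' @export
cnn_test_config <- function() {
  train_config(input_size = 64L, learning_rate = 1e-3, epochs = 30L)
}

# leaky rectifier (slope 0.05): avoids dead units in the small from-scratch
# network, which otherwise occasionally stalls at chance under unlucky
# initializations
.lrelu <- function(x) pmax(x, 0) + 0.05 * pmin(x, 0)
.lrelu_grad <- function(x) ifelse(x > 0, 1, 0.05)

# ---- tensor helpers ---------------------------------------------------------
# batches are arrays [H, W, C, N]

.im2col_index <- function(H, W, C, k = 3L) {
  # index map into the zero-padded [H+2, W+2, C] volume, one column per
  # output pixel, k*k*C rows (pad = 1, stride 1)
  Hp <- H + 2L; Wp <- W + 2L
  off <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+"))          # k*k
  off <- as.vector(outer(off, (0:(C - 1L)) * Hp * Wp, "+"))            # k*k*C
  base <- as.vector(outer(seq_len(H), (seq_len(W) - 1L) * Hp, "+"))    # H*W
  matrix(rep(base, each = length(off)) + rep(off, times = length(base)),
         nrow = length(off))
}

.pad_batch <- function(A) {
  d <- dim(A)
  P <- array(0, dim = c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  P[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- A
  P
}

# conv 3x3, pad 1, stride 1: W [Cout, 9*Cin], b [Cout]
.conv_forward <- function(A, Wt, b, idx) {
  d <- dim(A); H <- d[1]; Wd <- d[2]; Cin <- d[3]; N <- d[4]
  P <- .pad_batch(A)
  vol <- (H + 2L) * (Wd + 2L) * Cin
  Pv <- as.vector(P)
  cols <- matrix(0, nrow(idx), H * Wd * N)
  for (n in seq_len(N)) {
    cols[, ((n - 1L) * H * Wd + 1L):(n * H * Wd)] <-
      Pv[idx + (n - 1L) * vol]
  }
  out <- Wt %*% cols + b                      # [Cout, H*W*N]
  list(out = array(aperm(array(out, dim = c(nrow(Wt), H, Wd, N)),
                         c(2, 3, 1, 4)),
                   dim = c(H, Wd, nrow(Wt), N)),
       cols = cols)
}

.conv_backward <- function(dOut, A, Wt, cols, idx) {
  d <- dim(A); H <- d[1]; Wd <- d[2]; Cin <- d[3]; N <- d[4]
  Cout <- nrow(Wt)
  dY <- matrix(aperm(dOut, c(3, 1, 2, 4)), nrow = Cout)  # [Cout, H*W*N]
  dW <- dY %*% t(cols)
  db <- rowSums(dY)
  dcols <- t(Wt) %*% dY                                   # [9Cin, H*W*N]
  vol <- (H + 2L) * (Wd + 2L) * Cin
  dP <- numeric(vol * N)
  hw <- H * Wd
  full_idx <- rep.int(as.vector(idx), N) +
    rep(0:(N - 1L) * vol, each = length(idx))
  dP <- cpp_index_accumulate(as.vector(dcols), full_idx, vol * N)
  dP <- array(dP, dim = c(H + 2L, Wd + 2L, Cin, N))
  list(dA = dP[2:(H + 1L), 2:(Wd + 1L), , , drop = FALSE],
       dW = dW, db = db)
}

.maxpool_forward <- function(A) {
  d <- dim(A)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  a <- A[i1, j1, , , drop = FALSE]; b <- A[i2, j1, , , drop = FALSE]
  cc <- A[i1, j2, , , drop = FALSE]; dd <- A[i2, j2, , , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  list(out = m,
       w = list(a == m, b == m & a != m,
                cc == m & a != m & b != m,
                dd == m & a != m & b != m & cc != m))
}

.maxpool_backward <- function(dOut, pool, d_in) {
  dA <- array(0, dim = d_in)
  i1 <- seq(1L, d_in[1], 2L); i2 <- seq(2L, d_in[1], 2L)
  j1 <- seq(1L, d_in[2], 2L); j2 <- seq(2L, d_in[2], 2L)
  dA[i1, j1, , ] <- dOut * pool$w[[1]]
  dA[i2, j1, , ] <- dOut * pool$w[[2]]
  dA[i1, j2, , ] <- dOut * pool$w[[3]]
  dA[i2, j2, , ] <- dOut * pool$w[[4]]
  dA
}

.init_params <- function(config) {
  ch <- config$channels
  s8 <- config$input_size %/% 8L
  flat <- s8 * s8 * ch[3]
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  list(
    W1 = matrix(he(27, ch[1] * 27), ch[1], 27), b1 = numeric(ch[1]),
    W2 = matrix(he(9 * ch[1], ch[2] * 9 * ch[1]), ch[2], 9 * ch[1]),
    b2 = numeric(ch[2]),
    W3 = matrix(he(9 * ch[2], ch[3] * 9 * ch[2]), ch[3], 9 * ch[2]),
    b3 = numeric(ch[3]),
    Wd1 = matrix(he(flat, 16 * flat), 16, flat), bd1 = numeric(16),
    Wd2 = matrix(he(16, 16), 1, 16), bd2 = 0)
}

# forward pass; returns logits and (optionally) every intermediate needed
# for the backward pass and Grad-CAM. Inputs are centered (x - 0.5).
.cnn_forward <- function(params, A, idxs, keep = FALSE) {
  A <- A - 0.5
  c1 <- .conv_forward(A, params$W1, params$b1, idxs[[1]])
  r1 <- .lrelu(c1$out)
  p1 <- .maxpool_forward(r1)
  c2 <- .conv_forward(p1$out, params$W2, params$b2, idxs[[2]])
  r2 <- .lrelu(c2$out)
  p2 <- .maxpool_forward(r2)
  c3 <- .conv_forward(p2$out, params$W3, params$b3, idxs[[3]])
  r3 <- .lrelu(c3$out)                        # last conv feature maps
  p3 <- .maxpool_forward(r3)
  d3p <- dim(p3$out)
  flat <- matrix(p3$out, d3p[1] * d3p[2] * d3p[3], d3p[4])
  h1 <- params$Wd1 %*% flat + params$bd1
  a1 <- .lrelu(h1)
  z <- as.numeric(params$Wd2 %*% a1 + params$bd2)
  if (!keep) return(list(logits = z, conv3 = r3))
  list(logits = z, conv3 = r3, cache = list(A = A, c1 = c1, r1 = r1, p1 = p1,
       c2 = c2, r2 = r2, p2 = p2, c3 = c3, r3 = r3, p3 = p3, flat = flat,
       h1 = h1, a1 = a1))
}

.cnn_backward <- function(params, fw, y, idxs) {
  cache <- fw$cache
  z <- fw$logits
  N <- length(z)
  pr <- 1 / (1 + exp(-z))
  dz <- matrix((pr - y) / N, 1)               # dL/dz for mean BCE
  dWd2 <- dz %*% t(cache$a1); dbd2 <- sum(dz)
  da1 <- t(params$Wd2) %*% dz
  dh1 <- da1 * .lrelu_grad(cache$h1)
  dWd1 <- dh1 %*% t(cache$flat); dbd1 <- rowSums(dh1)
  dflat <- t(params$Wd1) %*% dh1
  dp3 <- array(dflat, dim = dim(cache$p3$out))
  dr3 <- .maxpool_backward(dp3, cache$p3, dim(cache$r3))
  dc3 <- dr3 * .lrelu_grad(cache$c3$out)
  b3 <- .conv_backward(dc3, cache$p2$out, params$W3, cache$c3$cols, idxs[[3]])
  dp2 <- b3$dA
  dr2 <- .maxpool_backward(dp2, cache$p2, dim(cache$r2))
  dc2 <- dr2 * .lrelu_grad(cache$c2$out)
  b2 <- .conv_backward(dc2, cache$p1$out, params$W2, cache$c2$cols, idxs[[2]])
  dp1 <- b2$dA
  dr1 <- .maxpool_backward(dp1, cache$p1, dim(cache$r1))
  dc1 <- dr1 * .lrelu_grad(cache$c1$out)
  b1 <- .conv_backward(dc1, cache$A, params$W1, cache$c1$cols, idxs[[1]])
  list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db,
       W3 = b3$dW, b3 = b3$db, Wd1 = dWd1, bd1 = dbd1,
       Wd2 = dWd2, bd2 = dbd2)
}

.bce_loss <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

.augment_one <- function(img, op) {
  switch(op,
         img,
         img[rev(seq_len(dim(img)[1])), , , drop = FALSE],        # vflip
         img[, rev(seq_len(dim(img)[2])), , drop = FALSE],        # hflip
         aperm(img, c(2, 1, 3))[rev(seq_len(dim(img)[2])), , ,
                                drop = FALSE],                     # rot90
         img[rev(seq_len(dim(img)[1])), rev(seq_len(dim(img)[2])), ,
             drop = FALSE],                                        # rot180
         aperm(img, c(2, 1, 3))[, rev(seq_len(dim(img)[1])), ,
                                drop = FALSE])                     # rot270
}

.stack_batch <- function(images, rows, size, augment = FALSE) {
  N <- length(rows)
  A <- array(0, dim = c(size, size, 3, N))
  for (k in seq_len(N)) {
    img <- images[[rows[k]]]
    if (dim(img)[1] != size) img <- resize_image(img, size)
    if (augment) img <- .augment_one(img, sample.int(6L, 1L))
    A[, , , k] <- img
  }
  A
}

.adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Stratified train/validation/prediction split
#' @param labels 0/1 vector.
#' @param splits fractions summing to 1.
#' @return list of index vectors `train`, `validation`, `prediction`.
#' @export
split_dataset <- function(labels, splits = c(0.7, 0.15, 0.15)) {
  idx <- seq_along(labels)
  out <- list(train = integer(0), validation = integer(0),
              prediction = integer(0))
  for (cl in unique(labels)) {
    i <- sample(idx[labels == cl])
    n <- length(i)
    n_tr <- round(splits[1] * n); n_va <- round(splits[2] * n)
    out$train <- c(out$train, i[seq_len(n_tr)])
    out$validation <- c(out$validation, i[n_tr + seq_len(n_va)])
    out$prediction <- c(out$prediction, i[seq(n_tr + n_va + 1, n)])
  }
  out
}

#' Train the small CNN binary classifier
#'
#' A from-scratch three-block convolutional network (3x3 convolutions,
#' ReLU, 2x2 max pooling for the first two blocks, global average pooling
#' and a small dense head) trained with Adam on binary cross-entropy, with
#' flip/rotation augmentation. The returned checkpoint is the parameter set
#' at the epoch of minimum validation loss.
#'
#' @param images list of H x W x 3 arrays in \[0, 1\].
#' @param labels 0/1 vector (1 = positive class).
#' @param config a [train_config()].
#' @param split optional precomputed [split_dataset()] result.
#' @return object of class `cnn_model`: `params` (best checkpoint),
#'   `history` (per-epoch train/validation loss), `best_epoch`, `config`,
#'   `split`.
#' @export
train_classifier <- function(images, labels, config = cnn_test_config(),
                             split = NULL) {
  stopifnot(length(images) == length(labels), all(labels %in% 0:1))
  if (is.null(split)) split <- split_dataset(labels, config$splits)
  for (part in c("train", "validation")) {
    if (length(unique(labels[split[[part]]])) < 2)
      stop("stratification error: ", part, " split contains a single class")
  }
  size <- config$input_size
  ch <- config$channels
  idxs <- list(.im2col_index(size, size, 3L),
               .im2col_index(size %/% 2L, size %/% 2L, ch[1]),
               .im2col_index(size %/% 4L, size %/% 4L, ch[2]))
  params <- .init_params(config)
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  tr <- split$train; va <- split$validation
  Aval <- .stack_batch(images, va, size)
  yval <- labels[va]
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        validation_loss = numeric(0))
  best <- list(loss = Inf, params = params, epoch = 0L)
  tglob <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tl <- 0
    for (bt in batches) {
      A <- .stack_batch(images, bt, size, augment = config$augment)
      fw <- .cnn_forward(params, A, idxs, keep = TRUE)
      tl <- tl + .bce_loss(fw$logits, labels[bt]) * length(bt)
      grads <- .cnn_backward(params, fw, labels[bt], idxs)
      tglob <- tglob + 1L
      upd <- .adam_step(params, grads, state, config$learning_rate, tglob)
      params <- upd$params; state <- upd$state
    }
    vl <- .bce_loss(.cnn_forward(params, Aval, idxs)$logits, yval)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = tl / length(tr),
                                         validation_loss = vl))
    if (vl < best$loss) best <- list(loss = vl, params = params, epoch = ep)
  }
  structure(list(params = best$params, history = history,
                 best_epoch = best$epoch, config = config, split = split,
                 idxs = idxs),
            class = "cnn_model")
}

#' Predicted probability of the positive class
#' @param object a `cnn_model`.
#' @param images list of H x W x 3 arrays.
#' @param ... unused.
#' @export
predict.cnn_model <- function(object, images, ...) {
  size <- object$config$input_size
  n <- length(images)
  probs <- numeric(n)
  chunk <- 32L
  for (s in seq(1, n, chunk)) {
    rows <- s:min(s + chunk - 1L, n)
    A <- .stack_batch(images, rows, size)
    z <- .cnn_forward(object$params, A, object$idxs)$logits
    probs[rows] <- 1 / (1 + exp(-z))
  }
  probs
}

#' Evaluate the classifier on a prediction set
#'
#' @param model a `cnn_model`.
#' @param images list of images.
#' @param labels 0/1 vector; both classes must be present.
#' @return list: `confusion` (2x2 matrix at the 0.5 threshold), `accuracy`,
#'   `auc` (rank-statistic ROC-AUC), `scores`.
#' @export
evaluate_classifier <- function(model, images, labels) {
  if (length(unique(labels)) < 2)
    stop("AUC undefined: prediction set contains a single class")
  scores <- predict.cnn_model(model, images)
  pred <- as.integer(scores >= 0.5)
  confusion <- table(factor(pred, levels = 0:1),
                     factor(labels, levels = 0:1),
                     dnn = c("predicted", "observed"))
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(confusion = confusion, accuracy = mean(pred == labels), auc = auc,
       scores = scores)
}
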
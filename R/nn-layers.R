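# Internal layer primitives for the CNN-GRU classifier: 1-D convolution via
# im2col, non-overlapping max pooling, the GRU recurrence of gru_step()
# vectorised over a batch, dense layers, and softmax cross-entropy. All in
# double precision; forward functions return caches consumed by the matching
# backward functions.

## ---- 1-D convolution (stride 1, zero-padded "same" output) ----

conv1d_forward <- function(X, W, b, kernel) {
  d <- dim(X); B <- d[1L]; L <- d[2L]; Cin <- d[3L]
  p <- (kernel - 1L) %/% 2L
  Lp <- L + kernel - 1L
  Xp <- array(0, c(B, Lp, Cin))
  Xp[, (p + 1L):(p + L), ] <- X
  cols <- matrix(0, B * L, kernel * Cin)
  for (o in seq_len(kernel)) {
    cols[, ((o - 1L) * Cin + 1L):(o * Cin)] <-
      matrix(Xp[, o:(o + L - 1L), , drop = FALSE], B * L, Cin)
  }
  Y <- cols %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(out = array(Y, c(B, L, ncol(W))), cols = cols,
       dims = c(B = B, L = L, Cin = Cin, k = kernel, p = p, Lp = Lp))
}

conv1d_backward <- function(dY, cache, W) {
  d <- cache$dims
  B <- d[["B"]]; L <- d[["L"]]; Cin <- d[["Cin"]]
  k <- d[["k"]]; p <- d[["p"]]; Lp <- d[["Lp"]]
  f <- ncol(W)
  dYm <- matrix(dY, B * L, f)
  dW <- crossprod(cache$cols, dYm)
  db <- colSums(dYm)
  dcols <- tcrossprod(dYm, W)
  dXp <- array(0, c(B, Lp, Cin))
  for (o in seq_len(k)) {
    sl <- o:(o + L - 1L)
    dXp[, sl, ] <- dXp[, sl, , drop = FALSE] +
      array(dcols[, ((o - 1L) * Cin + 1L):(o * Cin)], c(B, L, Cin))
  }
  list(dX = dXp[, (p + 1L):(p + L), , drop = FALSE], dW = dW, db = db)
}

## ---- ReLU ----

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, mask = mask)
}

relu_backward <- function(dY, cache) dY * cache$mask

## ---- max pooling, width 2, stride 2 (odd tail sample dropped) ----

maxpool2_forward <- function(X) {
  d <- dim(X); L <- d[2L]
  Lo <- L %/% 2L
  if (Lo < 1L) stop("architecture infeasible")
  A <- X[, seq(1L, 2L * Lo, 2L), , drop = FALSE]
  B2 <- X[, seq(2L, 2L * Lo, 2L), , drop = FALSE]
  mask <- A >= B2  # ties take the earlier sample
  list(out = pmax(A, B2), mask = mask, L_in = L)
}

maxpool2_backward <- function(dY, cache) {
  d <- dim(dY); B <- d[1L]; Lo <- d[2L]; C <- d[3L]
  dX <- array(0, c(B, cache$L_in, C))
  dX[, seq(1L, 2L * Lo, 2L), ] <- dY * cache$mask
  dX[, seq(2L, 2L * Lo, 2L), ] <- dY * !cache$mask
  dX
}

## ---- GRU layer over a sequence (batch-vectorised gru_step) ----

gru_layer_forward <- function(X, w) {
  d <- dim(X); B <- d[1L]; Tn <- d[2L]; Cin <- d[3L]
  H <- length(w$br)
  h <- matrix(0, B, H)
  H_all <- array(0, c(B, Tn, H))
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- matrix(X[, t, ], B, Cin)
    r <- sigmoid(x %*% w$Wxr + h %*% w$Whr + rep(w$br, each = B))
    z <- sigmoid(x %*% w$Wxz + h %*% w$Whz + rep(w$bz, each = B))
    rh <- r * h
    hb <- tanh(x %*% w$Wxh + rh %*% w$Whh + rep(w$bh, each = B))
    h_new <- z * h + (1 - z) * hb
    steps[[t]] <- list(x = x, h_prev = h, r = r, z = z, rh = rh, hb = hb)
    h <- h_new
    H_all[, t, ] <- h
  }
  list(out = H_all, h_final = h, steps = steps, dims = d)
}

gru_layer_backward <- function(dH_all, dh_final, cache, w) {
  d <- cache$dims; B <- d[1L]; Tn <- d[2L]; Cin <- d[3L]
  H <- length(w$br)
  g <- lapply(w[1:6], function(m) matrix(0, nrow(m), ncol(m)))
  names(g) <- names(w)[1:6]
  dbr <- numeric(H); dbz <- numeric(H); dbh <- numeric(H)
  dX <- array(0, c(B, Tn, Cin))
  dh <- if (is.null(dh_final)) matrix(0, B, H) else dh_final
  for (t in rev(seq_len(Tn))) {
    s <- cache$steps[[t]]
    dht <- dh + if (is.null(dH_all)) 0 else matrix(dH_all[, t, ], B, H)
    dz <- dht * (s$h_prev - s$hb)
    dhb <- dht * (1 - s$z)
    dh_prev <- dht * s$z
    dah <- dhb * (1 - s$hb^2)
    g$Wxh <- g$Wxh + crossprod(s$x, dah)
    g$Whh <- g$Whh + crossprod(s$rh, dah)
    dbh <- dbh + colSums(dah)
    drh <- tcrossprod(dah, w$Whh)
    dr <- drh * s$h_prev
    dh_prev <- dh_prev + drh * s$r
    dar <- dr * s$r * (1 - s$r)
    daz <- dz * s$z * (1 - s$z)
    g$Wxr <- g$Wxr + crossprod(s$x, dar)
    g$Whr <- g$Whr + crossprod(s$h_prev, dar)
    dbr <- dbr + colSums(dar)
    g$Wxz <- g$Wxz + crossprod(s$x, daz)
    g$Whz <- g$Whz + crossprod(s$h_prev, daz)
    dbz <- dbz + colSums(daz)
    dX[, t, ] <- tcrossprod(dar, w$Wxr) + tcrossprod(daz, w$Wxz) +
      tcrossprod(dah, w$Wxh)
    dh <- dh_prev + tcrossprod(dar, w$Whr) + tcrossprod(daz, w$Whz)
  }
  c(g, list(br = dbr, bz = dbz, bh = dbh, dX = dX))
}

## ---- dense ----

dense_forward <- function(X, W, b) {
  list(out = X %*% W + rep(b, each = nrow(X)), X = X)
}

dense_backward <- function(dY, cache, W) {
  list(dX = tcrossprod(dY, W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

## ---- softmax cross-entropy ----

softmax_xent <- function(Z, y) {
  # y: 0-based integer labels
  P <- softmax_rows(Z)
  B <- nrow(Z)
  idx <- cbind(seq_len(B), y + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  dZ <- P
  dZ[idx] <- dZ[idx] - 1
  list(loss = loss, prob = P, dZ = dZ / B)
}
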
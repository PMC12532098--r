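# Neural-network primitives with hand-written backpropagation.
#
# Feature maps are stored as dense matrices X of shape (NB*H*W, C): one row
# per pixel, ordered sample-major then image-row-major (within an image the
# column index w varies fastest). All spatial structure (3x3 convolution
# neighborhoods, 2x2 pooling, nearest upsampling, window partitions for
# shifted-window attention) is encoded in integer index tables precomputed
# per (H, W, NB) and memoized, so every layer reduces to BLAS matrix products
# plus indexed gathers/scatters. Every forward returns the cache its backward
# needs; backwards return the input gradient and parameter gradients.

.geom_cache <- new.env(parent = emptyenv())

img_to_rows <- function(img) as.vector(t(img))
rows_to_img <- function(v, H, W) t(matrix(v, W, H))

# ---- geometry tables ------------------------------------------------------

geom_key <- function(...) paste(..., sep = "|")

# (NB*H*W x 9) neighbor table for 3x3 conv, zero padding via index NBHW+1.
conv_nbr <- function(H, W, NB) {
  key <- geom_key("nbr", H, W, NB)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  n <- rep(seq_len(NB), each = H * W)
  h <- rep(rep(seq_len(H), each = W), times = NB)
  w <- rep(rep(seq_len(W), times = H), times = NB)
  T <- NB * H * W
  out <- matrix(T + 1L, T, 9L)
  k <- 0L
  for (dh in -1:1) for (dw in -1:1) {
    k <- k + 1L
    hh <- h + dh; ww <- w + dw
    ok <- hh >= 1L & hh <= H & ww >= 1L & ww <= W
    out[ok, k] <- (n[ok] - 1L) * (H * W) + (hh[ok] - 1L) * W + ww[ok]
  }
  .geom_cache[[key]] <- out
  out
}

# 2x2 mean-pool children: (NB*(H/2)*(W/2) x 4) rows of the fine grid.
pool_idx <- function(H, W, NB) {
  key <- geom_key("pool", H, W, NB)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  H2 <- H %/% 2L; W2 <- W %/% 2L
  n <- rep(seq_len(NB), each = H2 * W2)
  h2 <- rep(rep(seq_len(H2), each = W2), times = NB)
  w2 <- rep(rep(seq_len(W2), times = H2), times = NB)
  base <- function(dh, dw) (n - 1L) * (H * W) + (2L * h2 - 2L + dh) * W + (2L * w2 - 1L + dw)
  out <- cbind(base(0L, 0L), base(0L, 1L), base(1L, 0L), base(1L, 1L))
  .geom_cache[[key]] <- out
  out
}

# nearest-neighbor upsample: fine row -> coarse row (length NB*H*W, H/W fine).
up_idx <- function(H, W, NB) {
  key <- geom_key("up", H, W, NB)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  H2 <- H %/% 2L; W2 <- W %/% 2L
  n <- rep(seq_len(NB), each = H * W)
  h <- rep(rep(seq_len(H), each = W), times = NB)
  w <- rep(rep(seq_len(W), times = H), times = NB)
  out <- (n - 1L) * (H2 * W2) + ((h + 1L) %/% 2L - 1L) * W2 + (w + 1L) %/% 2L
  .geom_cache[[key]] <- out
  out
}

# Window partition for (shifted-)window attention. Returns the permutation
# `perm` grouping rows into consecutive w^2-token windows (sample-major, then
# window-major), and per-spatial-window additive masks (NULL when unshifted:
# the cyclic shift makes tokens from opposite image edges share a window, and
# the mask stops attention across those seams).
win_part <- function(H, W, NB, win, shift) {
  key <- geom_key("win", H, W, NB, win, shift)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  nh <- H %/% win; nw <- W %/% win
  # token source position for each (window, local) slot on the rolled grid
  wi <- rep(rep(seq_len(nh) - 1L, each = nw), each = win * win)
  wj <- rep(rep(seq_len(nw) - 1L, times = nh), each = win * win)
  lr <- rep(rep(seq_len(win) - 1L, each = win), times = nh * nw)
  lc <- rep(rep(seq_len(win) - 1L, times = win), times = nh * nw)
  h <- (wi * win + lr + shift) %% H + 1L
  w <- (wj * win + lc + shift) %% W + 1L
  per_sample <- (h - 1L) * W + w
  perm <- as.integer(outer(per_sample, (seq_len(NB) - 1L) * (H * W), `+`))
  masks <- NULL
  if (shift > 0) {
    seg <- function(x, n) ifelse(x <= n - win, 0L, ifelse(x <= n - shift, 1L, 2L))
    id <- seg(h, H) * 3L + seg(w, W)
    masks <- vector("list", nh * nw)
    for (g in seq_len(nh * nw)) {
      ids <- id[((g - 1L) * win * win + 1L):(g * win * win)]
      m <- outer(ids, ids, `!=`) * -1e9
      masks[[g]] <- m
    }
  }
  out <- list(perm = perm, n_spatial = nh * nw, masks = masks, win2 = win * win)
  .geom_cache[[key]] <- out
  out
}

# ---- primitives -----------------------------------------------------------

add_rowvec <- function(X, v) X + rep(v, each = nrow(X))

silu_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(out = x * s, cache = list(x = x, s = s))
}
silu_bwd <- function(dy, cache) {
  s <- cache$s
  dy * (s * (1 + cache$x * (1 - s)))
}

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(out = add_rowvec(xhat * rep(g, each = nrow(X)), b),
       cache = list(xhat = xhat, inv = inv, g = g))
}
ln_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  dxhat <- dy * rep(cache$g, each = nrow(dy))
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

conv3_fwd <- function(X, W, b, nbr) {
  Xa <- rbind(X, 0)
  cols <- do.call(cbind, lapply(seq_len(9), function(k) Xa[nbr[, k], , drop = FALSE]))
  list(out = add_rowvec(cols %*% W, b), cache = list(cols = cols, W = W, Cin = ncol(X)))
}
conv3_bwd <- function(dy, cache, nbr) {
  Cin <- cache$Cin
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  # input gradient = correlation of dy with the 180-degree-flipped kernel:
  # dX[p] = sum_k dY[p - off_k] %*% t(W_k); offset -off_k is column 10-k of
  # the neighbor table, so this is 9 gathers + 9 small matmuls (no scatter).
  T <- nrow(dy)
  Ya <- rbind(dy, 0)
  W <- cache$W
  dx <- matrix(0, T, Cin)
  for (k in seq_len(9)) {
    rows_k <- ((k - 1L) * Cin + 1L):(k * Cin)
    dx <- dx + tcrossprod(Ya[nbr[, 10L - k], , drop = FALSE], W[rows_k, , drop = FALSE])
  }
  list(dx = dx, dW = dW, db = db)
}

pool_fwd <- function(X, pidx) {
  (X[pidx[, 1], , drop = FALSE] + X[pidx[, 2], , drop = FALSE] +
     X[pidx[, 3], , drop = FALSE] + X[pidx[, 4], , drop = FALSE]) / 4
}
pool_bwd <- function(dy, pidx, T_fine) {
  dX <- matrix(0, T_fine, ncol(dy))
  q <- dy / 4
  for (k in seq_len(4)) dX[pidx[, k], ] <- dX[pidx[, k], ] + q
  dX
}

upsample_fwd <- function(X, uidx) X[uidx, , drop = FALSE]
upsample_bwd <- function(dy, uidx) {
  out <- rowsum(dy, uidx, reorder = TRUE)
  dimnames(out) <- NULL
  out
}

# Shifted-window multi-head self-attention.
wmsa_fwd <- function(X, p, wp, heads) {
  C <- ncol(X)
  d <- C %/% heads
  Xp <- X[wp$perm, , drop = FALSE]
  qkv <- add_rowvec(Xp %*% p$Wqkv, p$bqkv)
  w2 <- wp$win2
  n_win <- nrow(X) %/% w2
  O <- matrix(0, nrow(X), C)
  A_store <- vector("list", n_win * heads)
  for (g in seq_len(n_win)) {
    rg <- ((g - 1L) * w2 + 1L):(g * w2)
    mask <- if (is.null(wp$masks)) NULL else wp$masks[[(g - 1L) %% wp$n_spatial + 1L]]
    for (hh in seq_len(heads)) {
      cq <- ((hh - 1L) * d + 1L):(hh * d)
      Q <- qkv[rg, cq, drop = FALSE]
      K <- qkv[rg, C + cq, drop = FALSE]
      V <- qkv[rg, 2L * C + cq, drop = FALSE]
      S <- tcrossprod(Q, K) / sqrt(d)
      if (!is.null(mask)) S <- S + mask
      S <- S - S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
      E <- exp(S)
      A <- E / rowSums(E)
      O[rg, cq] <- A %*% V
      A_store[[(g - 1L) * heads + hh]] <- A
    }
  }
  out_p <- add_rowvec(O %*% p$Wo, p$bo)
  Y <- matrix(0, nrow(X), C)
  Y[wp$perm, ] <- out_p
  list(out = Y, cache = list(Xp = Xp, qkv = qkv, O = O, A = A_store, d = d))
}
wmsa_bwd <- function(dy, cache, p, wp, heads) {
  C <- ncol(dy)
  d <- cache$d
  w2 <- wp$win2
  dout_p <- dy[wp$perm, , drop = FALSE]
  dWo <- crossprod(cache$O, dout_p)
  dbo <- colSums(dout_p)
  dO <- tcrossprod(dout_p, p$Wo)
  qkv <- cache$qkv
  dqkv <- matrix(0, nrow(dy), 3L * C)
  n_win <- nrow(dy) %/% w2
  for (g in seq_len(n_win)) {
    rg <- ((g - 1L) * w2 + 1L):(g * w2)
    for (hh in seq_len(heads)) {
      cq <- ((hh - 1L) * d + 1L):(hh * d)
      A <- cache$A[[(g - 1L) * heads + hh]]
      Q <- qkv[rg, cq, drop = FALSE]
      K <- qkv[rg, C + cq, drop = FALSE]
      V <- qkv[rg, 2L * C + cq, drop = FALSE]
      dOh <- dO[rg, cq, drop = FALSE]
      dV <- crossprod(A, dOh)
      dA <- tcrossprod(dOh, V)
      dS <- A * (dA - rowSums(dA * A))
      dqkv[rg, cq] <- dS %*% K / sqrt(d)
      dqkv[rg, C + cq] <- crossprod(dS, Q) / sqrt(d)
      dqkv[rg, 2L * C + cq] <- dV
    }
  }
  dWqkv <- crossprod(cache$Xp, dqkv)
  Xp_grad <- tcrossprod(dqkv, p$Wqkv)
  dX <- matrix(0, nrow(dy), C)
  dX[wp$perm, ] <- Xp_grad
  list(dx = dX, dWqkv = dWqkv, dbqkv = colSums(dqkv), dWo = dWo, dbo = dbo)
}
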
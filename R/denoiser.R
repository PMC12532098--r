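#' Conditional denoiser: small U-net with shifted-window attention
#'
#' The denoiser \eqn{f_\theta(x_t, y, t)} predicts the clean image from the
#' noisy state, the corrupted image and the time step. Topology: `x_t` and
#' `y` enter concatenated on the channel axis; an encoder/decoder U-net with
#' residual convolution blocks; at the configured levels the attention
#' positions are occupied by pairs of shifted-window (Swin-style) transformer
#' blocks (regular + shifted window multi-head self-attention, each followed
#' by an MLP); the integer step t enters through a sinusoidal embedding and a
#' small MLP whose output is projected to a per-channel bias inside every
#' residual block. The final 3x3 convolution is zero-initialized and its
#' output is added to `y`, so an untrained network predicts `y` (a sensible
#' prior) and training learns the correction. All weights are
#' resolution-agnostic: the same network runs on any image side compatible
#' with the level count and window size.
#'
#' @param base_channels channels at the finest level.
#' @param channel_multipliers integer vector, one entry per level.
#' @param swin_window window side (pixels) for window attention.
#' @param swin_heads attention heads (must divide the channel count at the
#'   attention levels).
#' @param time_embed_dim sinusoidal time-embedding width.
#' @param levels_with_swin levels (1 = finest) that get the attention pair;
#'   default: coarsest level only.
#' @param image_size representative image side used for build-time
#'   compatibility checks (the network itself is size-agnostic).
#' @return a `"rsmoco_denoiser_config"` list.
#' @export
denoiser_config <- function(base_channels = 16L, channel_multipliers = c(1L, 2L),
                            swin_window = 4L, swin_heads = 2L,
                            time_embed_dim = 32L, levels_with_swin = NULL,
                            image_size = 64L) {
  L <- length(channel_multipliers)
  if (is.null(levels_with_swin)) levels_with_swin <- L
  cfg <- list(base_channels = as.integer(base_channels),
              channel_multipliers = as.integer(channel_multipliers),
              swin_window = as.integer(swin_window),
              swin_heads = as.integer(swin_heads),
              time_embed_dim = as.integer(time_embed_dim),
              levels_with_swin = as.integer(levels_with_swin),
              image_size = as.integer(image_size))
  class(cfg) <- "rsmoco_denoiser_config"
  validate_denoiser_cfg(cfg, cfg$image_size)
  cfg
}

validate_denoiser_cfg <- function(cfg, side) {
  L <- length(cfg$channel_multipliers)
  if (side %% 2^(L - 1) != 0) {
    stop_config("image side ", side, " is not divisible by 2^(levels-1) = ", 2^(L - 1))
  }
  ch <- cfg$base_channels * cfg$channel_multipliers
  for (l in cfg$levels_with_swin) {
    if (l < 1 || l > L) stop_config("levels_with_swin entry ", l, " out of range")
    side_l <- side %/% 2^(l - 1)
    if (side_l %% cfg$swin_window != 0) {
      stop_config("swin_window ", cfg$swin_window, " does not divide the level-", l,
                  " feature side ", side_l)
    }
    if (ch[l] %% cfg$swin_heads != 0) {
      stop_config("swin_heads must divide the channel count at attention levels")
    }
    if (cfg$swin_window < 2) stop_config("swin_window must be >= 2")
  }
  if (cfg$time_embed_dim < 4 || cfg$time_embed_dim %% 2 != 0) {
    stop_config("time_embed_dim must be an even integer >= 4")
  }
  invisible(TRUE)
}

# ---- parameter initialization --------------------------------------------

init_res_params <- function(p, prefix, C, Dt, mk, zeros) {
  p[[paste0(prefix, ".ln1.g")]] <- rep(1, C)
  p[[paste0(prefix, ".ln1.b")]] <- rep(0, C)
  p[[paste0(prefix, ".conv1.W")]] <- mk(9L * C, C, sqrt(2 / (9 * C)))
  p[[paste0(prefix, ".conv1.b")]] <- rep(0, C)
  p[[paste0(prefix, ".t.W")]] <- mk(Dt, C, sqrt(1 / Dt))
  p[[paste0(prefix, ".t.b")]] <- rep(0, C)
  p[[paste0(prefix, ".ln2.g")]] <- rep(1, C)
  p[[paste0(prefix, ".ln2.b")]] <- rep(0, C)
  p[[paste0(prefix, ".conv2.W")]] <- zeros(9L * C, C)
  p[[paste0(prefix, ".conv2.b")]] <- rep(0, C)
  p
}

init_swin_params <- function(p, prefix, C, mk, zeros) {
  p[[paste0(prefix, ".ln1.g")]] <- rep(1, C)
  p[[paste0(prefix, ".ln1.b")]] <- rep(0, C)
  p[[paste0(prefix, ".Wqkv")]] <- mk(C, 3L * C, sqrt(1 / C))
  p[[paste0(prefix, ".bqkv")]] <- rep(0, 3L * C)
  p[[paste0(prefix, ".Wo")]] <- zeros(C, C)
  p[[paste0(prefix, ".bo")]] <- rep(0, C)
  p[[paste0(prefix, ".ln2.g")]] <- rep(1, C)
  p[[paste0(prefix, ".ln2.b")]] <- rep(0, C)
  p[[paste0(prefix, ".mlp.W1")]] <- mk(C, 2L * C, sqrt(2 / C))
  p[[paste0(prefix, ".mlp.b1")]] <- rep(0, 2L * C)
  p[[paste0(prefix, ".mlp.W2")]] <- zeros(2L * C, C)
  p[[paste0(prefix, ".mlp.b2")]] <- rep(0, C)
  p
}

#' Build (initialize) a denoiser
#'
#' @param cfg a [denoiser_config()].
#' @param rng_seed integer seed; the same seed yields identical initial
#'   parameters.
#' @return an object of class `"rsmoco_denoiser"` with elements `cfg`,
#'   `params` (named list of weight arrays), `schedule` (`NULL` until
#'   trained) and `n_params`.
#' @export
build_denoiser <- function(cfg = denoiser_config(), rng_seed = 0L) {
  stopifnot(inherits(cfg, "rsmoco_denoiser_config"))
  rng <- rng_stream(rng_seed, "init")
  mk <- function(nr, nc, sd) matrix(rng$rnorm(nr * nc, sd = sd), nr, nc)
  zeros <- function(nr, nc) matrix(0, nr, nc)
  ch <- cfg$base_channels * cfg$channel_multipliers
  L <- length(ch)
  Dt <- cfg$time_embed_dim
  p <- list()
  p[["time.W1"]] <- mk(Dt, Dt, sqrt(1 / Dt))
  p[["time.b1"]] <- rep(0, Dt)
  p[["time.W2"]] <- mk(Dt, Dt, sqrt(1 / Dt))
  p[["time.b2"]] <- rep(0, Dt)
  p[["conv_in.W"]] <- mk(18L, ch[1], sqrt(2 / 18))
  p[["conv_in.b"]] <- rep(0, ch[1])
  for (l in seq_len(L)) {
    p <- init_res_params(p, paste0("enc", l, ".res"), ch[l], Dt, mk, zeros)
    if (l %in% cfg$levels_with_swin) {
      p <- init_swin_params(p, paste0("enc", l, ".s1"), ch[l], mk, zeros)
      p <- init_swin_params(p, paste0("enc", l, ".s2"), ch[l], mk, zeros)
    }
    if (l < L) {
      p[[paste0("down", l, ".W")]] <- mk(9L * ch[l], ch[l + 1], sqrt(2 / (9 * ch[l])))
      p[[paste0("down", l, ".b")]] <- rep(0, ch[l + 1])
    }
  }
  p <- init_res_params(p, "mid.res", ch[L], Dt, mk, zeros)
  for (l in rev(seq_len(L - 1))) {
    p[[paste0("up", l, ".W")]] <- mk(9L * (ch[l + 1] + ch[l]), ch[l], sqrt(2 / (9 * (ch[l + 1] + ch[l]))))
    p[[paste0("up", l, ".b")]] <- rep(0, ch[l])
    p <- init_res_params(p, paste0("dec", l, ".res"), ch[l], Dt, mk, zeros)
    if (l %in% cfg$levels_with_swin) {
      p <- init_swin_params(p, paste0("dec", l, ".s1"), ch[l], mk, zeros)
      p <- init_swin_params(p, paste0("dec", l, ".s2"), ch[l], mk, zeros)
    }
  }
  p[["out.ln.g"]] <- rep(1, ch[1])
  p[["out.ln.b"]] <- rep(0, ch[1])
  p[["out.W"]] <- zeros(9L * ch[1], 1L)
  p[["out.b"]] <- rep(0, 1L)
  structure(list(cfg = cfg, params = p, schedule = NULL,
                 n_params = sum(vapply(p, length, 1L))),
            class = "rsmoco_denoiser")
}

#' @export
print.rsmoco_denoiser <- function(x, ...) {
  cat(sprintf("rsmoco denoiser: %d levels, base %d channels, %s parameters%s\n",
              length(x$cfg$channel_multipliers), x$cfg$base_channels,
              format(x$n_params, big.mark = ","),
              if (is.null(x$schedule)) " (untrained)" else " (trained)"))
  invisible(x)
}

# ---- forward / backward ---------------------------------------------------

sin_embed <- function(t_vec, Dt) {
  half <- Dt %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / (half - 1))
  ang <- outer(t_vec, freqs)
  cbind(sin(ang), cos(ang))
}

res_fwd <- function(X, p, prefix, temb, nbr, sid) {
  g <- function(nm) p[[paste0(prefix, ".", nm)]]
  l1 <- ln_fwd(X, g("ln1.g"), g("ln1.b"))
  s1 <- silu_fwd(l1$out)
  c1 <- conv3_fwd(s1$out, g("conv1.W"), g("conv1.b"), nbr)
  tb <- add_rowvec(temb %*% g("t.W"), g("t.b"))
  h <- c1$out + tb[sid, , drop = FALSE]
  l2 <- ln_fwd(h, g("ln2.g"), g("ln2.b"))
  s2 <- silu_fwd(l2$out)
  c2 <- conv3_fwd(s2$out, g("conv2.W"), g("conv2.b"), nbr)
  list(out = X + c2$out, cache = list(l1 = l1, s1 = s1, c1 = c1, l2 = l2, s2 = s2, c2 = c2))
}

res_bwd <- function(dout, cc, p, prefix, temb, nbr, sid, gr) {
  g <- function(nm) p[[paste0(prefix, ".", nm)]]
  put <- function(nm, v) gr[[paste0(prefix, ".", nm)]] <- v
  bc2 <- conv3_bwd(dout, cc$c2$cache, nbr)
  put("conv2.W", bc2$dW); put("conv2.b", bc2$db)
  ds2 <- silu_bwd(bc2$dx, cc$s2$cache)
  bl2 <- ln_bwd(ds2, cc$l2$cache)
  put("ln2.g", bl2$dg); put("ln2.b", bl2$db)
  dh <- bl2$dx
  dtb <- rowsum(dh, sid, reorder = TRUE)
  dimnames(dtb) <- NULL
  put("t.W", crossprod(temb, dtb)); put("t.b", colSums(dtb))
  dtemb <- tcrossprod(dtb, g("t.W"))
  bc1 <- conv3_bwd(dh, cc$c1$cache, nbr)
  put("conv1.W", bc1$dW); put("conv1.b", bc1$db)
  ds1 <- silu_bwd(bc1$dx, cc$s1$cache)
  bl1 <- ln_bwd(ds1, cc$l1$cache)
  put("ln1.g", bl1$dg); put("ln1.b", bl1$db)
  list(dx = dout + bl1$dx, dtemb = dtemb)
}

swin_fwd <- function(X, p, prefix, wp, heads) {
  g <- function(nm) p[[paste0(prefix, ".", nm)]]
  l1 <- ln_fwd(X, g("ln1.g"), g("ln1.b"))
  at <- wmsa_fwd(l1$out, list(Wqkv = g("Wqkv"), bqkv = g("bqkv"),
                              Wo = g("Wo"), bo = g("bo")), wp, heads)
  x2 <- X + at$out
  l2 <- ln_fwd(x2, g("ln2.g"), g("ln2.b"))
  m1 <- add_rowvec(l2$out %*% g("mlp.W1"), g("mlp.b1"))
  sm <- silu_fwd(m1)
  m2 <- add_rowvec(sm$out %*% g("mlp.W2"), g("mlp.b2"))
  list(out = x2 + m2,
       cache = list(l1 = l1, at = at, l2 = l2, sm = sm, l2out = l2$out))
}

swin_bwd <- function(dout, cc, p, prefix, wp, heads, gr) {
  g <- function(nm) p[[paste0(prefix, ".", nm)]]
  put <- function(nm, v) gr[[paste0(prefix, ".", nm)]] <- v
  put("mlp.W2", crossprod(cc$sm$out, dout)); put("mlp.b2", colSums(dout))
  dsm <- tcrossprod(dout, g("mlp.W2"))
  dm1 <- silu_bwd(dsm, cc$sm$cache)
  put("mlp.W1", crossprod(cc$l2out, dm1)); put("mlp.b1", colSums(dm1))
  dl2in <- tcrossprod(dm1, g("mlp.W1"))
  bl2 <- ln_bwd(dl2in, cc$l2$cache)
  put("ln2.g", bl2$dg); put("ln2.b", bl2$db)
  dx2 <- dout + bl2$dx
  bat <- wmsa_bwd(dx2, cc$at$cache, list(Wqkv = g("Wqkv"), Wo = g("Wo")), wp, heads)
  put("Wqkv", bat$dWqkv); put("bqkv", bat$dbqkv)
  put("Wo", bat$dWo); put("bo", bat$dbo)
  bl1 <- ln_bwd(bat$dx, cc$l1$cache)
  put("ln1.g", bl1$dg); put("ln1.b", bl1$db)
  dx2 + bl1$dx
}

# Full network pass. Xin: (NB*H*W, 2) matrix of (x_t, y) rows; t_vec length NB.
# Returns pred rows (NB*H*W, 1); with want_cache also the cache for backward.
net_forward <- function(model, Xin, t_vec, H, W, NB, want_cache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  validate_denoiser_cfg(cfg, H)
  if (W != H) validate_denoiser_cfg(cfg, W)
  ch <- cfg$base_channels * cfg$channel_multipliers
  L <- length(ch)
  win <- cfg$swin_window
  heads <- cfg$swin_heads
  Hl <- H %/% 2^(seq_len(L) - 1)
  Wl <- W %/% 2^(seq_len(L) - 1)
  nbr <- lapply(seq_len(L), function(l) conv_nbr(Hl[l], Wl[l], NB))
  sid <- lapply(seq_len(L), function(l) rep(seq_len(NB), each = Hl[l] * Wl[l]))
  cc <- list(enc = vector("list", L), dec = vector("list", L))

  e0 <- sin_embed(t_vec, cfg$time_embed_dim)
  ta <- add_rowvec(e0 %*% p[["time.W1"]], p[["time.b1"]])
  ts <- silu_fwd(ta)
  temb <- add_rowvec(ts$out %*% p[["time.W2"]], p[["time.b2"]])
  ci <- conv3_fwd(Xin, p[["conv_in.W"]], p[["conv_in.b"]], nbr[[1]])
  X <- ci$out
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    rb <- res_fwd(X, p, paste0("enc", l, ".res"), temb, nbr[[l]], sid[[l]])
    X <- rb$out
    sw <- NULL
    if (l %in% cfg$levels_with_swin) {
      wp1 <- win_part(Hl[l], Wl[l], NB, win, 0L)
      wp2 <- win_part(Hl[l], Wl[l], NB, win, win %/% 2L)
      s1 <- swin_fwd(X, p, paste0("enc", l, ".s1"), wp1, heads)
      s2 <- swin_fwd(s1$out, p, paste0("enc", l, ".s2"), wp2, heads)
      X <- s2$out
      sw <- list(s1 = s1, s2 = s2)
    }
    skips[[l]] <- X
    dn <- NULL
    if (l < L) {
      pidx <- pool_idx(Hl[l], Wl[l], NB)
      Xp <- pool_fwd(X, pidx)
      dn <- conv3_fwd(Xp, p[[paste0("down", l, ".W")]], p[[paste0("down", l, ".b")]], nbr[[l + 1]])
      X <- dn$out
    }
    cc$enc[[l]] <- list(res = rb$cache, swin = sw, down = dn)
  }
  mid <- res_fwd(X, p, "mid.res", temb, nbr[[L]], sid[[L]])
  X <- mid$out
  for (l in rev(seq_len(L - 1))) {
    uidx <- up_idx(Hl[l], Wl[l], NB)
    Xu <- upsample_fwd(X, uidx)
    Xc <- cbind(Xu, skips[[l]])
    uc <- conv3_fwd(Xc, p[[paste0("up", l, ".W")]], p[[paste0("up", l, ".b")]], nbr[[l]])
    X <- uc$out
    rb <- res_fwd(X, p, paste0("dec", l, ".res"), temb, nbr[[l]], sid[[l]])
    X <- rb$out
    sw <- NULL
    if (l %in% cfg$levels_with_swin) {
      wp1 <- win_part(Hl[l], Wl[l], NB, win, 0L)
      wp2 <- win_part(Hl[l], Wl[l], NB, win, win %/% 2L)
      s1 <- swin_fwd(X, p, paste0("dec", l, ".s1"), wp1, heads)
      s2 <- swin_fwd(s1$out, p, paste0("dec", l, ".s2"), wp2, heads)
      X <- s2$out
      sw <- list(s1 = s1, s2 = s2)
    }
    cc$dec[[l]] <- list(up = uc, res = rb$cache, swin = sw, nch_up = ncol(Xu))
  }
  lo <- ln_fwd(X, p[["out.ln.g"]], p[["out.ln.b"]])
  so <- silu_fwd(lo$out)
  oc <- conv3_fwd(so$out, p[["out.W"]], p[["out.b"]], nbr[[1]])
  pred <- Xin[, 2, drop = FALSE] + oc$out     # residual head on y
  if (!want_cache) return(list(pred = pred))
  cc$ts <- ts; cc$e0 <- e0; cc$temb <- temb; cc$ci <- ci
  cc$mid <- mid$cache; cc$lo <- lo; cc$so <- so; cc$oc <- oc
  cc$geom <- list(nbr = nbr, sid = sid, Hl = Hl, Wl = Wl, NB = NB)
  list(pred = pred, cache = cc)
}

# Backward pass: dpred is (T, 1). Returns named list of parameter gradients.
net_backward <- function(model, cc, dpred) {
  cfg <- model$cfg
  p <- model$params
  ch <- cfg$base_channels * cfg$channel_multipliers
  L <- length(ch)
  win <- cfg$swin_window
  heads <- cfg$swin_heads
  nbr <- cc$geom$nbr; sid <- cc$geom$sid
  Hl <- cc$geom$Hl; Wl <- cc$geom$Wl; NB <- cc$geom$NB
  temb <- cc$temb
  gr <- new.env(parent = emptyenv())

  boc <- conv3_bwd(dpred, cc$oc$cache, nbr[[1]])
  gr[["out.W"]] <- boc$dW; gr[["out.b"]] <- boc$db
  dso <- silu_bwd(boc$dx, cc$so$cache)
  blo <- ln_bwd(dso, cc$lo$cache)
  gr[["out.ln.g"]] <- blo$dg; gr[["out.ln.b"]] <- blo$db
  dX <- blo$dx
  dtemb <- matrix(0, NB, cfg$time_embed_dim)
  dskip <- vector("list", L)
  for (l in seq_len(L - 1)) {
    dc <- cc$dec[[l]]
    if (!is.null(dc$swin)) {
      wp1 <- win_part(Hl[l], Wl[l], NB, win, 0L)
      wp2 <- win_part(Hl[l], Wl[l], NB, win, win %/% 2L)
      dX <- swin_bwd(dX, dc$swin$s2$cache, p, paste0("dec", l, ".s2"), wp2, heads, gr)
      dX <- swin_bwd(dX, dc$swin$s1$cache, p, paste0("dec", l, ".s1"), wp1, heads, gr)
    }
    rb <- res_bwd(dX, dc$res, p, paste0("dec", l, ".res"), temb, nbr[[l]], sid[[l]], gr)
    dtemb <- dtemb + rb$dtemb
    buc <- conv3_bwd(rb$dx, dc$up$cache, nbr[[l]])
    gr[[paste0("up", l, ".W")]] <- buc$dW; gr[[paste0("up", l, ".b")]] <- buc$db
    nu <- dc$nch_up
    dXu <- buc$dx[, seq_len(nu), drop = FALSE]
    dskip[[l]] <- buc$dx[, (nu + 1):ncol(buc$dx), drop = FALSE]
    uidx <- up_idx(Hl[l], Wl[l], NB)
    # decoder levels are traversed fine-to-coarse here (reverse of forward),
    # so dX now belongs to the output of the next-coarser stage (mid at l+1==L)
    dX <- upsample_bwd(dXu, uidx)
  }
  rbm <- res_bwd(dX, cc$mid, p, "mid.res", temb, nbr[[L]], sid[[L]], gr)
  dtemb <- dtemb + rbm$dtemb
  dX <- rbm$dx
  for (l in rev(seq_len(L))) {
    ec <- cc$enc[[l]]
    if (l < L) {
      bdn <- conv3_bwd(dX, ec$down$cache, nbr[[l + 1]])
      gr[[paste0("down", l, ".W")]] <- bdn$dW; gr[[paste0("down", l, ".b")]] <- bdn$db
      pidx <- pool_idx(Hl[l], Wl[l], NB)
      dX <- pool_bwd(bdn$dx, pidx, NB * Hl[l] * Wl[l])
      dX <- dX + dskip[[l]]
    }
    if (!is.null(ec$swin)) {
      wp1 <- win_part(Hl[l], Wl[l], NB, win, 0L)
      wp2 <- win_part(Hl[l], Wl[l], NB, win, win %/% 2L)
      dX <- swin_bwd(dX, ec$swin$s2$cache, p, paste0("enc", l, ".s2"), wp2, heads, gr)
      dX <- swin_bwd(dX, ec$swin$s1$cache, p, paste0("enc", l, ".s1"), wp1, heads, gr)
    }
    rb <- res_bwd(dX, ec$res, p, paste0("enc", l, ".res"), temb, nbr[[l]], sid[[l]], gr)
    dtemb <- dtemb + rb$dtemb
    dX <- rb$dx
  }
  bci <- conv3_bwd(dX, cc$ci$cache, nbr[[1]])
  gr[["conv_in.W"]] <- bci$dW; gr[["conv_in.b"]] <- bci$db
  gr[["time.W2"]] <- crossprod(cc$ts$out, dtemb); gr[["time.b2"]] <- colSums(dtemb)
  dts <- tcrossprod(dtemb, p[["time.W2"]])
  dta <- silu_bwd(dts, cc$ts$cache)
  gr[["time.W1"]] <- crossprod(cc$e0, dta); gr[["time.b1"]] <- colSums(dta)
  as.list(gr)
}

#' Evaluate the denoiser
#'
#' Deterministic forward pass \eqn{\hat{x}_0 = f_\theta(x_t, y, t)}.
#'
#' @param model an `rsmoco_denoiser`.
#' @param x_t noisy state: H x W matrix or H x W x B array.
#' @param y corrupted image(s), same shape.
#' @param t integer step (scalar, or length-B vector for a batch). Must lie in
#'   `1..n_steps` of the model's schedule when the model has been trained.
#' @return array of the same shape as `x_t`.
#' @export
denoise <- function(model, x_t, y, t) {
  stopifnot(inherits(model, "rsmoco_denoiser"))
  if (!is.null(model$schedule)) {
    if (any(t < 1 | t > model$schedule$n_steps)) {
      stop_contract("t outside the trained schedule 1..", model$schedule$n_steps)
    }
  } else if (any(t < 1)) {
    stop_contract("t must be >= 1")
  }
  single <- is.matrix(x_t)
  if (single) {
    x_t <- array(x_t, dim = c(dim(x_t), 1L))
    y <- array(y, dim = dim(x_t))
  }
  check_same_shape(x_t, y, "x_t and y")
  d <- dim(x_t)
  H <- d[1]; W <- d[2]; NB <- d[3]
  t_vec <- rep_len(as.numeric(t), NB)
  xr <- as.numeric(vapply(seq_len(NB), function(i) img_to_rows(x_t[, , i]), numeric(H * W)))
  yr <- as.numeric(vapply(seq_len(NB), function(i) img_to_rows(y[, , i]), numeric(H * W)))
  fw <- net_forward(model, cbind(xr, yr, deparse.level = 0), t_vec, H, W, NB,
                    want_cache = FALSE)
  out <- array(0, dim = d)
  for (i in seq_len(NB)) {
    out[, , i] <- rows_to_img(fw$pred[((i - 1) * H * W + 1):(i * H * W), 1], H, W)
  }
  if (single) out <- out[, , 1]
  out
}
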
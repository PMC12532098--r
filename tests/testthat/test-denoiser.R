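test_that("construction is seeded and shape/finiteness contracts hold", {
  cfg <- tiny_cfg(32L)
  a <- build_denoiser(cfg, rng_seed = 4)
  b <- build_denoiser(cfg, rng_seed = 4)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, build_denoiser(cfg, rng_seed = 5)$params))
  x_t <- matrix(runif(32 * 32), 32)
  y <- matrix(runif(32 * 32), 32)
  out <- denoise(a, x_t, y, 2)
  expect_identical(dim(out), dim(x_t))
  expect_true(all(is.finite(out)))
  # zero-initialized output head: the untrained denoiser predicts y
  expect_lt(max(abs(out - y)), 1e-12)
  expect_error(denoise(a, x_t, y, 0), class = "rsmoco_contract_error")
})

test_that("incompatible size/window configurations fail at build time", {
  expect_error(denoiser_config(8L, c(1L, 2L, 4L), image_size = 36L),
               class = "rsmoco_config_error")
  expect_error(denoiser_config(8L, c(1L, 2L), swin_window = 5L, image_size = 32L),
               class = "rsmoco_config_error")
  expect_error(denoiser_config(9L, c(1L, 2L), swin_heads = 4L, image_size = 32L),
               class = "rsmoco_config_error")
})

test_that("evaluation is deterministic and resolution-robust", {
  den <- build_denoiser(tiny_cfg(32L), rng_seed = 1)
  # perturb all weights so the network is not the identity map on y
  set.seed(2)
  den$params <- lapply(den$params, function(w) w + stats::rnorm(length(w), sd = 0.02))
  for (side in c(32L, 64L)) {
    x_t <- matrix(runif(side * side), side)
    y <- matrix(runif(side * side), side)
    o1 <- denoise(den, x_t, y, 3)
    o2 <- denoise(den, x_t, y, 3)
    expect_identical(o1, o2)
    expect_identical(dim(o1), c(side, side))
    expect_true(all(is.finite(o1)))
    expect_gt(max(abs(o1 - y)), 0)
  }
  # batched input matches per-slice evaluation
  xb <- array(runif(32 * 32 * 3), c(32, 32, 3))
  yb <- array(runif(32 * 32 * 3), c(32, 32, 3))
  ob <- denoise(den, xb, yb, c(1, 2, 4))
  for (i in 1:3) {
    expect_equal(ob[, , i], denoise(den, xb[, , i], yb[, , i], c(1, 2, 4)[i]),
                 tolerance = 1e-12)
  }
})

test_that("backpropagation matches finite differences everywhere", {
  cfg <- denoiser_config(base_channels = 4L, channel_multipliers = c(1L, 2L),
                         swin_window = 2L, swin_heads = 2L, time_embed_dim = 8L,
                         levels_with_swin = c(1L, 2L), image_size = 8L)
  den <- build_denoiser(cfg, rng_seed = 7)
  set.seed(42)
  den$params <- lapply(den$params, function(w) w + stats::rnorm(length(w), sd = 0.05))
  H <- 8L; W <- 8L; NB <- 2L
  xt <- matrix(rnorm(H * W * NB))
  yb <- matrix(rnorm(H * W * NB))
  tv <- c(1, 3)
  target <- rnorm(H * W * NB)
  loss_of <- function(m) {
    fw <- rsmoco:::net_forward(m, cbind(xt, yb), tv, H, W, NB)
    d <- fw$pred[, 1] - target
    mean(d^2)
  }
  fw <- rsmoco:::net_forward(den, cbind(xt, yb), tv, H, W, NB, want_cache = TRUE)
  d <- fw$pred[, 1] - target
  gr <- rsmoco:::net_backward(den, fw$cache, matrix(2 * d / length(d), ncol = 1))
  expect_setequal(names(gr), names(den$params))
  h <- 1e-5
  set.seed(1)
  for (nm in names(den$params)) {
    for (j in sample(length(den$params[[nm]]), min(2, length(den$params[[nm]])))) {
      m2 <- den; m2$params[[nm]][j] <- m2$params[[nm]][j] + h
      m3 <- den; m3$params[[nm]][j] <- m3$params[[nm]][j] - h
      num <- (loss_of(m2) - loss_of(m3)) / (2 * h)
      ana <- gr[[nm]][j]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("the tiny backbone can overfit a 4-sample dataset", {
  # capacity check: loss must fall below 10% of its initial value within
  # 2000 iterations; run at 16x16 to stay fast on one CPU
  cfg <- denoiser_config(base_channels = 8L, channel_multipliers = c(1L, 2L),
                         swin_window = 4L, swin_heads = 2L, time_embed_dim = 16L,
                         image_size = 16L)
  den <- build_denoiser(cfg, rng_seed = 2)
  set.seed(6)
  mk_pair <- function(seed) {
    set.seed(seed)
    base <- matrix(runif(16), 4)[rep(1:4, each = 4), rep(1:4, each = 4)]
    x <- (base + 0.2 * matrix(runif(256), 16))
    x <- x / max(x)
    list(x = x, y = pmin(pmax(x + 0.25 * matrix(stats::rnorm(256), 16), 0), 1))
  }
  pairs <- lapply(1:4, mk_pair)
  sch <- build_schedule()
  m <- train_denoiser(pairs, den, sch,
                      train_config(iterations = 2000L, batch_size = 4L,
                                   lr_start = 1e-3, lr_min = 1e-4,
                                   warmup_steps = 50L, seed = 9))
  init <- mean(utils::head(m$loss_trace, 10))
  final <- mean(utils::tail(m$loss_trace, 50))
  expect_lt(final, 0.10 * init)
})
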
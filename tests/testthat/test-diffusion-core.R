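test_that("forward step matches the transition kernel", {
  sch <- build_schedule()
  x <- matrix(runif(64), 8)
  z <- matrix(0, 8, 8)
  # no residual, no noise: identity
  expect_identical(forward_step(x, z, sch, 2, z)$x_t, x)
  # hand-evaluated scalar case: alpha_t = 0.3, gamma = 2, eps = 1
  s2 <- sched_manual(0.3, 0.6)      # alpha_1 = 0.3
  out <- forward_step(matrix(0), matrix(1), s2, 1, matrix(1))
  expect_equal(out$x_t[1], 0.3 + 2 * sqrt(0.3), tolerance = 1e-14)
  expect_error(forward_step(x, z[, 1:4], sch, 1, z), class = "rsmoco_contract_error")
  expect_error(forward_step(x, z, sch, 5, z), class = "rsmoco_contract_error")
})

test_that("composing noiseless forward steps telescopes to the marginal", {
  set.seed(9)
  for (N in c(4L, 7L)) {
    sch <- build_schedule(n_steps = N)
    x <- matrix(runif(36), 6)
    y <- matrix(runif(36), 6)
    r <- y - x
    z <- matrix(0, 6, 6)
    cur <- x
    var_acc <- 0
    for (t in seq_len(N)) {
      cur <- forward_step(cur, r, sch, t, z)$x_t
      var_acc <- var_acc + sch$gamma^2 * sched_alpha(sch, t)
      marg <- forward_marginal(x, y, sch, t, z)$x_t
      expect_lt(max(abs(cur - marg)), 1e-12)
      expect_lt(abs(var_acc - sch$gamma^2 * sched_beta(sch, t)), 1e-12)
    }
    expect_lt(max(abs(cur - (x + sched_beta(sch, N) * r))), 1e-12)
  }
})

test_that("forward marginal has the stated mean, variance and endpoints", {
  sch <- build_schedule()
  x <- matrix(runif(64), 8)
  y <- matrix(runif(64), 8)
  z <- matrix(0, 8, 8)
  expect_identical(forward_marginal(x, y, sch, 0, z)$x_t, x)
  expect_identical(forward_marginal(x, x, sch, 3, z)$x_t, x)
  xn <- forward_marginal(x, y, sch, 4, z)$x_t
  expect_lt(max(abs(xn - (x + 0.999 * (y - x)))), 1e-12)
  # Monte-Carlo moments at t = 2 (scaled-down version of the 1e5-draw check)
  set.seed(31)
  n <- 2e4
  b2 <- sched_beta(sch, 2)
  draws <- vapply(seq_len(n), function(i) {
    forward_marginal(matrix(0.2), matrix(0.9), sch, 2,
                     matrix(rnorm(1)))$x_t[1]
  }, 1)
  mu <- 0.2 + b2 * 0.7
  sd_th <- sch$gamma * sqrt(b2)
  expect_lt(abs(mean(draws) - mu), 4 * sd_th / sqrt(n))
  se_var <- sd_th^2 * sqrt(2 / (n - 1))
  expect_lt(abs(stats::var(draws) - sd_th^2), 4 * se_var)
})

test_that("posterior parameters match hand evaluation and degenerate at t = 1", {
  s <- sched_manual(0.2, 0.5)       # beta_{t-1} = 0.2, beta_t = 0.5, alpha = 0.3
  pp <- posterior_params(matrix(1), matrix(0), s, 2)
  expect_equal(pp$mean[1], 0.4, tolerance = 1e-14)
  expect_equal(pp$variance, 0.48, tolerance = 1e-14)
  x <- matrix(runif(16), 4)
  p1 <- posterior_params(matrix(runif(16), 4), x, s, 1)
  expect_identical(p1$mean, x)
  expect_identical(p1$variance, 0)
  expect_error(posterior_params(x, x, s, 0), class = "rsmoco_contract_error")
})

test_that("posterior agrees with the grid-integration Gaussian-product oracle", {
  set.seed(77)
  for (i in 1:100) {
    beta_prev <- runif(1, 0.01, 0.6)
    beta_t <- runif(1, beta_prev + 0.05, 0.99)
    gam <- runif(1, 0.5, 3)
    s <- sched_manual(beta_prev, beta_t, gamma = gam)
    x <- rnorm(1); y <- rnorm(1); x_t <- rnorm(1)
    cl <- posterior_params(matrix(x_t), matrix(x), s, 2)
    or <- grid_posterior_oracle(x_t, x, y, beta_prev, beta_t, gam)
    expect_lt(abs(cl$mean[1] - or$mean), 1e-8)
    expect_lt(abs(cl$variance - or$variance), 1e-8)
  }
})

test_that("model-side mean substitutes the denoiser estimate", {
  s <- sched_manual(0.2, 0.5)
  x_t <- matrix(1)
  expect_equal(predict_mean(x_t, matrix(2), s, 2)$mean[1], 0.4 + 1.2, tolerance = 1e-14)
  x <- matrix(runif(9), 3)
  xt2 <- matrix(runif(9), 3)
  expect_identical(predict_mean(xt2, x, s, 2), posterior_params(xt2, x, s, 2))
  expect_identical(predict_mean(xt2, x, s, 1)$mean, x)
})

test_that("loss implements the stated 1:1 mean-per-pixel convention", {
  x <- matrix(runif(4), 2)
  expect_identical(diffusion_loss(x, x), 0)
  two <- matrix(c(0.5, 0.5), 1)
  zero <- matrix(0, 1, 2)
  expect_equal(diffusion_loss(two, zero), 0.75, tolerance = 1e-14)
  expect_equal(diffusion_loss(two, zero, mode = "l2"), 0.25, tolerance = 1e-14)
  set.seed(5)
  for (i in 1:20) {
    a <- matrix(rnorm(16), 4)
    b <- matrix(rnorm(16), 4)
    expect_gt(diffusion_loss(a, b), 0)
  }
})

test_that("reverse sampling is exact under the oracle denoiser", {
  sch <- build_schedule()
  set.seed(12)
  for (seed in c(1L, 99L, 123456L)) {
    x <- matrix(runif(64), 8)
    y <- matrix(runif(64), 8)
    calls <- 0L
    oracle <- function(x_t, yy, t) { calls <<- calls + 1L; x }
    out <- sample_reverse(y, oracle, sch, rng_seed = seed)
    expect_lt(max(abs(out - x)), 1e-6)
    expect_identical(attr(out, "n_denoiser_calls"), 4L)
    expect_identical(calls, 4L)
  }
})

test_that("reverse sampling is deterministic given the seed", {
  sch <- build_schedule()
  y <- matrix(runif(64), 8)
  f <- function(x_t, yy, t) 0.9 * x_t
  a <- sample_reverse(y, f, sch, rng_seed = 42)
  b <- sample_reverse(y, f, sch, rng_seed = 42)
  c2 <- sample_reverse(y, f, sch, rng_seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c2))
})

test_that("training decreases the loss, is seed-reproducible, and lr 0 is a no-op", {
  sch <- build_schedule()
  ds <- build_dataset(12, size = 32L, preset = severity_preset("moderate"), seed = 4)
  den <- build_denoiser(tiny_cfg(32L), rng_seed = 3)
  m <- train_denoiser(ds$pairs, den, sch,
                      train_config(iterations = 500L, batch_size = 2L, seed = 8))
  expect_true(all(is.finite(m$loss_trace)))
  expect_lt(mean(utils::tail(m$loss_trace, 100)), mean(utils::head(m$loss_trace, 100)))
  # seeded determinism (short runs)
  t1 <- train_denoiser(ds$pairs, den, sch,
                       train_config(iterations = 20L, batch_size = 2L, seed = 5))
  t2 <- train_denoiser(ds$pairs, den, sch,
                       train_config(iterations = 20L, batch_size = 2L, seed = 5))
  expect_identical(t1$loss_trace, t2$loss_trace)
  expect_identical(t1$params, t2$params)
  # zero learning rate leaves parameters unchanged
  t0 <- train_denoiser(ds$pairs, den, sch,
                       train_config(iterations = 1L, batch_size = 2L,
                                    lr_start = 0, lr_min = 0, warmup_steps = 0L, seed = 5))
  expect_identical(t0$params, den$params)
  expect_error(train_denoiser(list(), den, sch), class = "rsmoco_config_error")
})
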
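# RAdam optimizer and the diffusion training loop.

# Rectified Adam update. State holds first/second moments per parameter and
# the step counter; the variance-rectification term switches to plain SGD
# with momentum while the adaptive variance estimate is still unreliable.
radam_init <- function(params) {
  list(step = 0L,
       m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0))
}

radam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  t <- state$step
  rho_inf <- 2 / (1 - beta2) - 1
  rho_t <- rho_inf - 2 * t * beta2^t / (1 - beta2^t)
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    if (rho_t > 4) {
      vhat <- sqrt(state$v[[nm]] / (1 - beta2^t))
      r <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                  ((rho_inf - 4) * (rho_inf - 2) * rho_t))
      params[[nm]] <- params[[nm]] - lr * r * mhat / (vhat + eps)
    } else {
      params[[nm]] <- params[[nm]] - lr * mhat
    }
  }
  list(params = params, state = state)
}

# Linear warm-up to lr_start, then cosine annealing down to lr_min.
lr_at <- function(iter, total, lr_start, lr_min, warmup) {
  if (warmup > 0 && iter <= warmup) return(lr_start * iter / warmup)
  frac <- (iter - warmup) / max(1, total - warmup)
  lr_min + 0.5 * (lr_start - lr_min) * (1 + cos(pi * min(1, frac)))
}

#' Default training configuration
#'
#' Optimizer family and learning-rate schedule follow the reference training
#' recipe (rectified Adam, cosine annealing from 2e-4 to 2e-5 with warm-up),
#' with iteration counts scaled down to desk size.
#'
#' @param iterations number of gradient steps.
#' @param batch_size samples per step.
#' @param lr_start,lr_min initial and final learning rate of the cosine
#'   schedule.
#' @param warmup_steps linear warm-up length.
#' @param loss_mode `"l1l2"` (default) or `"l2"` (ablation).
#' @param seed master seed for all training randomness.
#' @return a list of class `"rsmoco_train_config"`.
#' @export
train_config <- function(iterations = 1000L, batch_size = 4L,
                         lr_start = 2e-4, lr_min = 2e-5,
                         warmup_steps = 50L,
                         loss_mode = c("l1l2", "l2"), seed = 0L) {
  loss_mode <- match.arg(loss_mode)
  if (iterations < 1 || batch_size < 1) stop_config("iterations and batch_size must be >= 1")
  if (lr_start < 0 || lr_min < 0 || lr_min > lr_start) stop_config("need 0 <= lr_min <= lr_start")
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 lr_start = lr_start, lr_min = lr_min,
                 warmup_steps = as.integer(warmup_steps),
                 loss_mode = loss_mode, seed = as.integer(seed)),
            class = "rsmoco_train_config")
}

#' Train the denoiser (diffusion training loop)
#'
#' Stochastic training of \eqn{f_\theta}: each iteration draws a batch of
#' paired samples, a per-sample step \eqn{t \sim U\{1..N\}}, forms
#' \eqn{x_t} from the forward marginal with fresh unit-normal noise, and takes
#' a rectified-Adam step on the gradient of the combined
#' \eqn{\ell_1+\ell_2} loss (or \eqn{\ell_2} alone in the ablation mode)
#' between \eqn{f_\theta(x_t, y, t)} and the clean image.
#'
#' Randomness is split into independent streams (data order, step draws,
#' forward noise) derived from `config$seed`, so a run is exactly
#' reproducible.
#'
#' @param dataset list of paired samples (`rsmoco_pair`, or any list with
#'   elements `x` and `y` as equal-size matrices). All images must share one
#'   size.
#' @param denoiser an `rsmoco_denoiser` from [build_denoiser()].
#' @param sched an `rsmoco_schedule`.
#' @param config a [train_config()].
#' @return the trained `rsmoco_denoiser` with the schedule and config
#'   attached, plus `loss_trace` (numeric, one entry per iteration).
#' @export
train_denoiser <- function(dataset, denoiser, sched, config = train_config()) {
  stopifnot(inherits(denoiser, "rsmoco_denoiser"), inherits(sched, "rsmoco_schedule"))
  if (!inherits(config, "rsmoco_train_config")) stop_config("config must come from train_config()")
  if (length(dataset) == 0) stop_config("dataset is empty")
  H <- nrow(dataset[[1]]$x); W <- ncol(dataset[[1]]$x)
  xs <- lapply(dataset, function(s) img_to_rows(s$x))
  ys <- lapply(dataset, function(s) img_to_rows(s$y))
  n <- length(dataset)
  NB <- config$batch_size
  HW <- H * W
  st_data <- rng_stream(config$seed, "data-order")
  st_t <- rng_stream(config$seed, "t-draws")
  st_eps <- rng_stream(config$seed, "forward-noise")
  params <- denoiser$params
  model <- denoiser
  state <- radam_init(params)
  trace <- numeric(config$iterations)
  gam <- sched$gamma
  for (it in seq_len(config$iterations)) {
    idx <- st_data$sample_int(n, NB, replace = n < NB)
    t_vec <- st_t$sample_int(sched$n_steps, NB, replace = TRUE)
    xb <- unlist(xs[idx], use.names = FALSE)
    yb <- unlist(ys[idx], use.names = FALSE)
    bvec <- rep(sched$beta[t_vec + 1], each = HW)
    eps <- st_eps$rnorm(NB * HW)
    xt <- xb + bvec * (yb - xb) + gam * sqrt(bvec) * eps
    model$params <- params
    fw <- net_forward(model, cbind(xt, yb, deparse.level = 0),
                      as.numeric(t_vec), H, W, NB, want_cache = TRUE)
    d <- fw$pred[, 1] - xb
    Tn <- length(d)
    loss <- mean(d^2)
    dpred <- 2 * d / Tn
    if (config$loss_mode == "l1l2") {
      loss <- loss + mean(abs(d))
      dpred <- dpred + sign(d) / Tn
    }
    if (!is.finite(loss)) {
      stop_config("non-finite loss at iteration ", it,
                  " (lr too high or degenerate data); aborting")
    }
    trace[it] <- loss
    grads <- net_backward(model, fw$cache, matrix(dpred, ncol = 1))
    lr <- lr_at(it, config$iterations, config$lr_start, config$lr_min, config$warmup_steps)
    up <- radam_step(params, grads, state, lr)
    params <- up$params
    state <- up$state
  }
  model$params <- params
  model$schedule <- sched
  model$train_config <- config
  model$loss_trace <- trace
  model
}

#' Save / load a trained denoiser checkpoint
#'
#' The checkpoint embeds the weights, the full schedule hyperparameters and a
#' snapshot of the training configuration, so sampling can be reproduced from
#' the file alone.
#'
#' @param model a trained `rsmoco_denoiser`.
#' @param path file path (`.rds`).
#' @return `save_checkpoint`: `path`, invisibly; `load_checkpoint`: the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "rsmoco_denoiser"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "rsmoco_denoiser")) stop_io("not a denoiser checkpoint: ", path)
  m
}
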
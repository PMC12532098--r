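#' Residual-shifting forward and reverse diffusion
#'
#' The forward chain perturbs the motion-free image `x` toward the corrupted
#' image `y` by injecting fractions of the residual \eqn{r = y - x}:
#' one step draws from \eqn{N(x_{t-1} + \alpha_t r, \gamma^2 \alpha_t I)} and
#' the marginal at step t is \eqn{N(x + \beta_t r, \gamma^2 \beta_t I)}.
#' Because \eqn{\beta_N \to 1}, the terminal state is (almost) centered on `y`,
#' which is what lets the learned reverse chain succeed in very few steps.
#'
#' @name diffusion
NULL

#' One forward diffusion step
#'
#' Computes \eqn{x_t = x_{t-1} + \alpha_t r + \gamma\sqrt{\alpha_t}\,\epsilon},
#' a draw from the transition kernel
#' \eqn{q(x_t | x_{t-1}, y) = N(x_{t-1} + \alpha_t r, \gamma^2\alpha_t I)}.
#'
#' @param x_prev array, the state \eqn{x_{t-1}}.
#' @param r array, the residual `y - x` (same shape).
#' @param sched an `rsmoco_schedule`.
#' @param t integer step in `1..n_steps`.
#' @param eps unit-normal draw of the same shape (pass zeros for the mean).
#' @return list with `x_t` (array) and `t`.
#' @export
forward_step <- function(x_prev, r, sched, t, eps) {
  stopifnot(inherits(sched, "rsmoco_schedule"))
  if (length(t) != 1 || t < 1 || t > sched$n_steps) stop_contract("t out of range 1..", sched$n_steps)
  check_same_shape(x_prev, r, "x_prev and r")
  check_same_shape(x_prev, eps, "x_prev and eps")
  a <- sched_alpha(sched, t)
  list(x_t = x_prev + a * r + sched$gamma * sqrt(a) * eps, t = as.integer(t))
}

#' Forward marginal at step t
#'
#' Computes \eqn{x_t = x + \beta_t (y - x) + \gamma\sqrt{\beta_t}\,\epsilon},
#' a draw from \eqn{q(x_t | x, y) = N(x + \beta_t r, \gamma^2\beta_t I)}.
#' `t = 0` returns `x` exactly.
#'
#' @param x motion-free image array.
#' @param y motion-corrupted image array (same shape).
#' @inheritParams forward_step
#' @return list with `x_t` and `t`.
#' @export
forward_marginal <- function(x, y, sched, t, eps) {
  stopifnot(inherits(sched, "rsmoco_schedule"))
  if (length(t) != 1 || t < 0 || t > sched$n_steps) stop_contract("t out of range 0..", sched$n_steps)
  check_same_shape(x, y, "x and y")
  check_same_shape(x, eps, "x and eps")
  b <- sched_beta(sched, t)
  list(x_t = x + b * (y - x) + sched$gamma * sqrt(b) * eps, t = as.integer(t))
}

#' Closed-form reverse posterior q(x_{t-1} | x_t, x, y)
#'
#' With the Gaussian kernel and marginal above, the exact reverse posterior is
#' \deqn{q(x_{t-1} | x_t, x, y) = N\!\left(
#'   \frac{\beta_{t-1}}{\beta_t} x_t + \frac{\alpha_t}{\beta_t} x,\;
#'   \gamma^2 \frac{\beta_{t-1}}{\beta_t}\alpha_t I\right).}
#' The residual cancels, so the posterior depends on `y` only through `x_t`.
#' At `t = 1` (\eqn{\beta_0 = 0}) it collapses to a point mass at `x`.
#'
#' @param x_t array, current state.
#' @param x array, clean image (same shape).
#' @inheritParams forward_step
#' @return list with `mean` (array) and `variance` (non-negative scalar).
#' @export
posterior_params <- function(x_t, x, sched, t) {
  stopifnot(inherits(sched, "rsmoco_schedule"))
  if (length(t) != 1 || t < 1 || t > sched$n_steps) {
    stop_contract("t out of range 1..", sched$n_steps, " (t = 0 has no predecessor)")
  }
  check_same_shape(x_t, x, "x_t and x")
  bt <- sched_beta(sched, t)
  btm1 <- sched_beta(sched, t - 1)
  at <- sched_alpha(sched, t)
  list(mean = (btm1 / bt) * x_t + (at / bt) * x,
       variance = sched$gamma^2 * (btm1 / bt) * at)
}

#' Model-side reverse mean
#'
#' Same functional form as [posterior_params()] with the clean image replaced
#' by the denoiser estimate \eqn{\hat{x}_0 = f_\theta(x_t, y, t)}:
#' \eqn{\mu_\theta = (\beta_{t-1}/\beta_t) x_t + (\alpha_t/\beta_t)\hat{x}_0}.
#' The variance is not learned; it is fixed to the posterior variance
#' \eqn{\Sigma_q}.
#'
#' @param x0_hat array, denoiser output.
#' @inheritParams posterior_params
#' @return list with `mean` and `variance`.
#' @export
predict_mean <- function(x_t, x0_hat, sched, t) {
  posterior_params(x_t, x0_hat, sched, t)
}

#' Training loss
#'
#' Mean-per-pixel squared error plus mean-per-pixel absolute error with equal
#' weights (`mode = "l1l2"`, the default); `mode = "l2"` drops the absolute
#' term and is provided for the ablation harness. The mean (rather than sum)
#' reduction keeps the loss magnitude independent of image resolution.
#'
#' @param x0_hat array, denoiser output.
#' @param x array, clean target (same shape).
#' @param mode `"l1l2"` or `"l2"`.
#' @return non-negative scalar.
#' @export
diffusion_loss <- function(x0_hat, x, mode = c("l1l2", "l2")) {
  mode <- match.arg(mode)
  check_same_shape(x0_hat, x, "x0_hat and x")
  d <- x0_hat - x
  l <- mean(d^2)
  if (mode == "l1l2") l <- l + mean(abs(d))
  l
}

#' Few-step reverse sampling (motion correction)
#'
#' Implements the reverse chain: initialize
#' \eqn{x_N = y + \gamma\sqrt{\beta_N}\,\epsilon_0}, then for
#' \eqn{t = N, \ldots, 1} compute
#' \eqn{\mu_\theta = (\beta_{t-1}/\beta_t) x_t + (\alpha_t/\beta_t)
#'  f_\theta(x_t, y, t)} and
#' \eqn{x_{t-1} = \mu_\theta + \gamma\sqrt{\beta_{t-1}\alpha_t/\beta_t}\,
#'  \epsilon}, with \eqn{\epsilon = 0} at `t = 1` so the final update is
#' deterministic. Exactly `n_steps` denoiser evaluations are performed; the
#' count is attached as attribute `"n_denoiser_calls"`.
#'
#' @param y corrupted image array (or array with a trailing batch dim matching
#'   what `denoiser` accepts; the stock denoiser takes a single H x W slice or
#'   an H x W x B batch).
#' @param denoiser either an object accepted by [denoise()] (a trained
#'   `rsmoco_denoiser`) or a plain function `f(x_t, y, t)` returning an array
#'   of the same shape (used e.g. for oracle tests).
#' @param sched an `rsmoco_schedule`. When `denoiser` is a trained model its
#'   stored schedule must have the same step count.
#' @param rng_seed integer seed for the sampler noise stream.
#' @return corrected image array `x_0` with attribute `n_denoiser_calls`.
#' @export
sample_reverse <- function(y, denoiser, sched, rng_seed = 0L) {
  stopifnot(inherits(sched, "rsmoco_schedule"))
  if (!all(is.finite(y))) stop_contract("y must be finite")
  f <- as_denoiser_fun(denoiser, sched)
  st <- rng_stream(rng_seed, "sampler")
  N <- sched$n_steps
  gam <- sched$gamma
  eps0 <- array(st$rnorm(length(y)), dim = dim(y))
  x_t <- y + gam * sqrt(sched_beta(sched, N)) * eps0
  n_calls <- 0L
  for (t in N:1) {
    x0_hat <- f(x_t, y, t)
    n_calls <- n_calls + 1L
    mu <- predict_mean(x_t, x0_hat, sched, t)
    if (t > 1) {
      eps <- array(st$rnorm(length(y)), dim = dim(y))
    } else {
      eps <- 0
    }
    x_t <- mu$mean + gam * sqrt(mu$variance / gam^2) * eps
  }
  attr(x_t, "n_denoiser_calls") <- n_calls
  x_t
}

# Normalize the denoiser argument to a function f(x_t, y, t).
as_denoiser_fun <- function(denoiser, sched) {
  if (is.function(denoiser)) return(denoiser)
  if (inherits(denoiser, "rsmoco_denoiser")) {
    if (!is.null(denoiser$schedule) &&
        denoiser$schedule$n_steps != sched$n_steps) {
      stop_config("denoiser was trained with n_steps = ",
                  denoiser$schedule$n_steps, " but sampling schedule has ",
                  sched$n_steps, "; cross-N sampling is unsupported")
    }
    return(function(x_t, y, t) denoise(denoiser, x_t, y, t))
  }
  stop_config("denoiser must be a function f(x_t, y, t) or an rsmoco_denoiser")
}
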
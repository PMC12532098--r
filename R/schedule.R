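#' Build the residual-shifting noise schedule
#'
#' Constructs the monotonically increasing shifting sequence \eqn{\{\beta_t\}}
#' and its first differences \eqn{\alpha_t = \beta_t - \beta_{t-1}} that drive
#' the residual-shifting diffusion. The forward process moves the clean image
#' `x` toward the corrupted image `y` by adding fractions of the residual
#' \eqn{r = y - x}: at step `t` the marginal is
#' \eqn{N(x + \beta_t r, \gamma^2 \beta_t I)}, so \eqn{\beta_1 \to 0} keeps the
#' first state close to `x` and \eqn{\beta_N \to 1} centers the terminal state
#' on `y`.
#'
#' Interior values follow a non-uniform geometric growth law
#' \deqn{\sqrt{\beta_t} = \sqrt{\beta_1}\,
#'   \exp\!\left(\tfrac12\left[\tfrac{t-1}{N-1}\right]^p
#'   \log\tfrac{\beta_N}{\beta_1}\right), \quad t = 1 \ldots N,}
#' which lands exactly on \eqn{\beta_1} and \eqn{\beta_N} at the endpoints.
#' Smaller `growth_p` front-loads the growth, i.e. produces larger
#' \eqn{\beta_t} (more residual and noise) at interior steps.
#'
#' Defaults follow the recommendation to keep \eqn{\gamma\sqrt{\beta_1}} small:
#' `beta1 = (0.04/gamma)^2` so that \eqn{\gamma\sqrt{\beta_1} = 0.04}, with
#' `gamma = 2`, `betaN = 0.999`, `growth_p = 0.3` and `n_steps = 4`.
#'
#' @param n_steps integer number of diffusion steps N (>= 2).
#' @param gamma positive noise-scaling factor \eqn{\gamma}.
#' @param growth_p positive growth-rate exponent p.
#' @param beta1 first shifting value; default `(0.04/gamma)^2`.
#' @param betaN last shifting value; default 0.999. Must satisfy
#'   `0 < beta1 < betaN < 1`.
#' @return An object of class `"rsmoco_schedule"`: a list with `n_steps`,
#'   `gamma`, `growth_p`, `beta` (numeric vector indexed t = 0..N, with
#'   `beta[1] == 0` representing \eqn{\beta_0 = 0}), `alpha` (t = 1..N), and
#'   `sqrt_beta1_times_gamma` recorded for audit.
#' @examples
#' sch <- build_schedule()
#' sched_beta(sch, 1)          # (0.04/2)^2 = 4e-4
#' sched_beta(sch, sch$n_steps) # 0.999
#' @export
build_schedule <- function(n_steps = 4L, gamma = 2, growth_p = 0.3,
                           beta1 = (0.04 / gamma)^2, betaN = 0.999) {
  if (!is.numeric(n_steps) || length(n_steps) != 1 || n_steps < 2 || n_steps != round(n_steps)) {
    stop_config("n_steps must be an integer >= 2 (got ", n_steps, ")")
  }
  if (!is.numeric(gamma) || gamma <= 0) stop_config("gamma must be > 0")
  if (!is.numeric(growth_p) || growth_p <= 0) stop_config("growth_p must be > 0")
  if (!(beta1 > 0 && beta1 < betaN && betaN < 1)) {
    stop_config("need 0 < beta1 < betaN < 1 (got beta1 = ", beta1, ", betaN = ", betaN, ")")
  }
  n_steps <- as.integer(n_steps)
  t <- seq_len(n_steps)
  frac <- ((t - 1) / (n_steps - 1))^growth_p
  sqrt_beta <- sqrt(beta1) * exp(0.5 * frac * log(betaN / beta1))
  beta <- c(0, sqrt_beta^2)             # beta[1] is beta_0 = 0
  # pin endpoints exactly (exp/log round-trip leaves ~1 ulp)
  beta[2] <- beta1
  beta[n_steps + 1] <- betaN
  alpha <- diff(beta)
  structure(
    list(n_steps = n_steps, gamma = gamma, growth_p = growth_p,
         beta1 = beta1, betaN = betaN,
         beta = beta, alpha = alpha,
         sqrt_beta1_times_gamma = gamma * sqrt(beta1)),
    class = "rsmoco_schedule"
  )
}

#' Query a schedule's shifting value
#'
#' @param sched an `rsmoco_schedule`.
#' @param t integer step in `0..n_steps` (for `sched_beta`) or `1..n_steps`
#'   (for `sched_alpha`).
#' @return numeric scalar \eqn{\beta_t} or \eqn{\alpha_t}.
#' @export
sched_beta <- function(sched, t) {
  stopifnot(inherits(sched, "rsmoco_schedule"))
  if (any(t < 0 | t > sched$n_steps)) stop_contract("t out of range 0..", sched$n_steps)
  sched$beta[t + 1]
}

#' @rdname sched_beta
#' @export
sched_alpha <- function(sched, t) {
  stopifnot(inherits(sched, "rsmoco_schedule"))
  if (any(t < 1 | t > sched$n_steps)) stop_contract("t out of range 1..", sched$n_steps)
  sched$alpha[t]
}

#' @export
print.rsmoco_schedule <- function(x, ...) {
  cat("Residual-shifting noise schedule\n")
  cat(sprintf("  N = %d, gamma = %g, p = %g, gamma*sqrt(beta1) = %g\n",
              x$n_steps, x$gamma, x$growth_p, x$sqrt_beta1_times_gamma))
  cat("  beta:", format(x$beta, digits = 6), "\n")
  cat("  alpha:", format(x$alpha, digits = 6), "\n")
  invisible(x)
}

#' Compare interior noise levels between two growth exponents
#'
#' Utility for the property suite: with all other hyperparameters equal, a
#' smaller growth exponent p yields a larger interior \eqn{\beta_t} (more
#' noise earlier in the chain). Returns `TRUE` iff \eqn{\beta_t} under
#' `p_small` strictly exceeds \eqn{\beta_t} under `p_large`.
#'
#' @param t interior step, `1 < t < n_steps` (endpoints are pinned and equal
#'   by construction, so comparing them is a contract violation).
#' @param p_small,p_large growth exponents with `p_small <= p_large`.
#' @inheritParams build_schedule
#' @return logical scalar.
#' @export
schedule_monotone_in_p <- function(t, p_small, p_large, n_steps = 4L, gamma = 2,
                                   beta1 = (0.04 / gamma)^2, betaN = 0.999) {
  if (t <= 1 || t >= n_steps) {
    stop_contract("t must be interior (1 < t < n_steps); endpoints are pinned")
  }
  if (p_small > p_large) stop_contract("need p_small <= p_large")
  bs <- build_schedule(n_steps, gamma, p_small, beta1, betaN)
  bl <- build_schedule(n_steps, gamma, p_large, beta1, betaN)
  sched_beta(bs, t) > sched_beta(bl, t)
}
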
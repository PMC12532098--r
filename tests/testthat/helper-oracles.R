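# Shared fixtures and independent oracles for the suite.

# Schedule with hand-chosen beta values: build_schedule with p = 1 and two
# steps gives beta = (0, beta1, betaN), so alpha and beta ratios are exact.
sched_manual <- function(beta_prev, beta_t, gamma = 2) {
  build_schedule(n_steps = 2L, gamma = gamma, growth_p = 1,
                 beta1 = beta_prev, betaN = beta_t)
}

# Independent oracle for the reverse posterior: numerically normalize
# q(x_t | x_{t-1}, y) * q(x_{t-1} | x, y) over a fine 1-D grid and return the
# moments of the resulting density in x_{t-1}.
grid_posterior_oracle <- function(x_t, x, y, beta_prev, beta_t, gamma) {
  alpha <- beta_t - beta_prev
  r <- y - x
  if (beta_prev == 0) return(list(mean = x, variance = 0))
  m_pr <- x + beta_prev * r
  sd_pr <- gamma * sqrt(beta_prev)
  sd_lik <- gamma * sqrt(alpha)
  lo <- min(m_pr, x_t - alpha * r) - 12 * max(sd_pr, sd_lik)
  hi <- max(m_pr, x_t - alpha * r) + 12 * max(sd_pr, sd_lik)
  g <- seq(lo, hi, length.out = 16001)
  logw <- stats::dnorm(x_t, g + alpha * r, sd_lik, log = TRUE) +
    stats::dnorm(g, m_pr, sd_pr, log = TRUE)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  mu <- sum(w * g)
  list(mean = mu, variance = sum(w * (g - mu)^2))
}

# Tiny denoiser configuration used across the slow tests.
tiny_cfg <- function(side = 32L, base = 8L) {
  denoiser_config(base_channels = base, channel_multipliers = c(1L, 2L),
                  swin_window = 4L, swin_heads = 2L, time_embed_dim = 16L,
                  image_size = side)
}

# Deterministic smooth test images (identical formula used when freezing
# cross-implementation oracle values).
formula_image <- function(n = 24L) {
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  (sin(0.35 * i) * cos(0.21 * j) + 1) / 2
}
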
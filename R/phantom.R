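#' Synthetic brain-like phantom slices
#'
#' Generates 2-D phantoms that stand in for T1-weighted brain slices at desk
#' scale: an elliptical "head" with a bright closed rim just inside its
#' boundary (emulating subcutaneous fat, so ghosting replicas appear outside
#' the head after k-space corruption), a mid-intensity interior with a few
#' random internal ellipses (soft-tissue structure) and smooth random texture.
#' Values are clamped to \[0, 1\] and the output is deterministic given the
#' seed.
#'
#' @param size pixels per side; >= 32 and divisible by 4.
#' @param n_inner_ellipses number of internal structures.
#' @param rim_intensity intensity of the fat-like rim, in (0, 1].
#' @param texture_sigma smoothing length (pixels) of the interior texture.
#' @param seed integer seed.
#' @return `size x size` matrix in \[0, 1\].
#' @export
make_phantom <- function(size = 64L, n_inner_ellipses = 4L, rim_intensity = 0.95,
                         texture_sigma = 2, seed = 0L) {
  if (size < 32 || size %% 4 != 0) stop_config("size must be >= 32 and divisible by 4")
  if (rim_intensity <= 0 || rim_intensity > 1) stop_config("rim_intensity must be in (0, 1]")
  rng <- rng_stream(seed, "phantom")
  s <- size
  r <- matrix(seq_len(s), s, s)
  c <- matrix(seq_len(s), s, s, byrow = TRUE)
  cy <- (s + 1) / 2; cx <- (s + 1) / 2
  a <- 0.42 * s; b <- 0.36 * s       # head semi-axes (rows, cols)
  rho <- sqrt(((r - cy) / a)^2 + ((c - cx) / b)^2)
  img <- matrix(0, s, s)
  interior <- rho < 0.88
  rim <- rho >= 0.88 & rho <= 1
  img[interior] <- 0.40
  img[rim] <- rim_intensity
  # internal elliptical structures with random geometry and contrast
  for (i in seq_len(n_inner_ellipses)) {
    ec <- cx + rng$runif(1, -0.35, 0.35) * b
    er <- cy + rng$runif(1, -0.35, 0.35) * a
    ea <- rng$runif(1, 0.06, 0.22) * s
    eb <- rng$runif(1, 0.06, 0.22) * s
    th <- rng$runif(1, 0, pi)
    dv <- rng$runif(1, -0.25, 0.35)
    ur <- (r - er) * cos(th) + (c - ec) * sin(th)
    uc <- -(r - er) * sin(th) + (c - ec) * cos(th)
    inside <- ((ur / ea)^2 + (uc / eb)^2) < 1 & interior
    img[inside] <- img[inside] + dv
  }
  # smooth texture: Gaussian-filtered white noise, interior only
  if (texture_sigma > 0) {
    noise <- matrix(rng$rnorm(s * s), s, s)
    tex <- gauss_blur(noise, texture_sigma)
    tex <- tex / max(1e-12, stats::sd(tex))
    img[interior] <- img[interior] + 0.05 * tex[interior]
  }
  pmin(pmax(img, 0), 1)
}

# Separable Gaussian blur with reflected edges (helper for phantom texture).
gauss_blur <- function(m, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  g <- exp(-0.5 * ((-rad):rad / sigma)^2)
  g <- g / sum(g)
  conv1 <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(rad)]), v, rev(v[(n - rad + 1):n]))
    stats::filter(vp, g, sides = 2)[(rad + 1):(rad + n)]
  }
  m2 <- apply(m, 2, conv1)
  t(apply(t(m2), 2, conv1))
}

#' Build a paired phantom dataset
#'
#' Generates `n` independent phantoms (disjoint sub-seeds) and corrupts each
#' once with the simulator, then splits deterministically into train/val/test
#' partitions by ratio. Regeneration with the same arguments is bit-identical.
#'
#' @param n number of paired samples.
#' @param size phantom side length (pixels).
#' @param preset an [severity_preset()].
#' @param seed master seed.
#' @param split numeric ratios `c(train, val, test)` summing to 1.
#' @param noise_sigma acquisition noise passed to [corrupt_slice()].
#' @return list with `pairs` (list of `rsmoco_pair`), and integer index
#'   vectors `train`, `val`, `test`.
#' @export
build_dataset <- function(n, size = 64L, preset = severity_preset("heavy"),
                          seed = 0L, split = c(0.8, 0.1, 0.1), noise_sigma = 0) {
  if (n < 1) stop_config("n must be >= 1")
  if (abs(sum(split) - 1) > 1e-9 || length(split) != 3) {
    stop_config("split must be three ratios summing to 1")
  }
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- (as.numeric(seed) * 1000003 + i) %% 2147483647
    ph <- make_phantom(size = size, seed = sub)
    pairs[[i]] <- corrupt_slice(ph, preset, rng_seed = sub + 1,
                                noise_sigma = noise_sigma)
  }
  n_train <- floor(split[1] * n)
  n_val <- floor(split[2] * n)
  idx <- seq_len(n)
  list(pairs = pairs,
       train = idx[seq_len(n_train)],
       val = if (n_val > 0) idx[n_train + seq_len(n_val)] else integer(0),
       test = if (n_train + n_val < n) idx[(n_train + n_val + 1):n] else integer(0))
}
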
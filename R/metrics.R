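#' Image quality metrics
#'
#' PSNR, SSIM, NMSE and pooled Pearson correlation as used to score motion
#' correction. All metrics assume images share a declared `data_range`
#' (default 1, matching slices normalized to \[0, 1\]).
#'
#' @name metrics
NULL

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in dB. Identical inputs have infinite
#' PSNR; the value is capped at 100 dB (documented sentinel).
#'
#' @param ref reference image (matrix/array).
#' @param est estimate, same shape.
#' @param data_range dynamic range of the data (default 1).
#' @return scalar dB.
#' @export
psnr <- function(ref, est, data_range = 1) {
  check_same_shape(ref, est, "ref and est")
  if (data_range <= 0) stop_config("data_range must be > 0")
  mse <- mean((ref - est)^2)
  min(100, 10 * log10(data_range^2 / max(mse, .Machine$double.xmin)))
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard 11x11 Gaussian window (sigma = 1.5),
#' K1 = 0.01, K2 = 0.03, Gaussian-weighted local moments and no sample-size
#' bias correction — the defaults of the common evaluation libraries. Local
#' statistics are taken over the valid (fully-overlapping) window positions.
#'
#' @inheritParams psnr
#' @return scalar in \[-1, 1\].
#' @export
ssim <- function(ref, est, data_range = 1) {
  check_same_shape(ref, est, "ref and est")
  win <- 11L
  if (nrow(ref) < win || ncol(ref) < win) {
    stop_contract("image smaller than the ", win, "x", win, " SSIM window")
  }
  sigma <- 1.5
  g <- exp(-0.5 * ((-(win %/% 2)):(win %/% 2) / sigma)^2)
  g <- g / sum(g)
  f <- function(m) conv2_valid_sep(m, g)
  mu1 <- f(ref); mu2 <- f(est)
  s11 <- f(ref * ref) - mu1^2
  s22 <- f(est * est) - mu2^2
  s12 <- f(ref * est) - mu1 * mu2
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

# Separable 'valid' correlation with a symmetric 1-D kernel g.
conv2_valid_sep <- function(m, g) {
  k <- length(g)
  H <- nrow(m); W <- ncol(m)
  # along rows (dimension 1)
  a <- matrix(0, H - k + 1, W)
  for (i in seq_len(k)) a <- a + g[i] * m[i:(H - k + i), , drop = FALSE]
  out <- matrix(0, H - k + 1, W - k + 1)
  for (j in seq_len(k)) out <- out + g[j] * a[, j:(W - k + j), drop = FALSE]
  out
}

#' Normalized mean squared error (percent)
#'
#' `100 * sum((est - ref)^2) / sum(ref^2)`. Undefined (raises) when the
#' reference is identically zero. Invariant under joint rescaling of both
#' images.
#'
#' @inheritParams psnr
#' @return scalar percent, >= 0.
#' @export
nmse <- function(ref, est) {
  check_same_shape(ref, est, "ref and est")
  denom <- sum(ref^2)
  if (denom == 0) stop_contract("NMSE undefined for an all-zero reference")
  100 * sum((est - ref)^2) / denom
}

#' Pooled pixel-wise Pearson correlation
#'
#' Correlation between reference and estimate over all pixels of all supplied
#' slices jointly (no brain mask).
#'
#' @param refs,ests lists of matrices (or single matrices).
#' @return scalar in \[-1, 1\].
#' @export
pearson_pooled <- function(refs, ests) {
  if (is.matrix(refs)) refs <- list(refs)
  if (is.matrix(ests)) ests <- list(ests)
  a <- unlist(lapply(refs, as.vector))
  b <- unlist(lapply(ests, as.vector))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)  # degenerate
  stats::cor(a, b)
}

#' Evaluate a set of (reference, estimate) pairs
#'
#' Computes PSNR, SSIM and NMSE per slice and aggregates each as
#' mean +/- standard deviation (population convention, n divisor), plus the
#' pooled Pearson correlation over all pixels.
#'
#' @param refs list of reference matrices.
#' @param ests list of estimate matrices, same length and shapes.
#' @param data_range declared dynamic range (default 1).
#' @return object of class `"rsmoco_report"`: list with `per_slice`
#'   (data.frame psnr/ssim/nmse), `summary` (mean and sd per metric) and
#'   `pearson_r`.
#' @export
evaluate_dataset <- function(refs, ests, data_range = 1) {
  if (length(refs) == 0) stop_config("empty collection")
  if (length(refs) != length(ests)) stop_config("refs and ests differ in length")
  per <- data.frame(
    psnr = mapply(function(r, e) psnr(r, e, data_range), refs, ests),
    ssim = mapply(function(r, e) ssim(r, e, data_range), refs, ests),
    nmse = mapply(nmse, refs, ests)
  )
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  summ <- lapply(per, function(v) list(mean = mean(v), sd = sd_pop(v)))
  structure(list(per_slice = per, summary = summ,
                 pearson_r = pearson_pooled(refs, ests), n = length(refs)),
            class = "rsmoco_report")
}

#' @export
print.rsmoco_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d slice(s):\n", x$n))
  cat(sprintf("  PSNR: %.2f +/- %.2f dB\n", x$summary$psnr$mean, x$summary$psnr$sd))
  cat(sprintf("  SSIM: %.4f +/- %.4f\n", x$summary$ssim$mean, x$summary$ssim$sd))
  cat(sprintf("  NMSE: %.3f +/- %.3f %%\n", x$summary$nmse$mean, x$summary$nmse$sd))
  cat(sprintf("  Pearson r (pooled): %.5f\n", x$pearson_r))
  invisible(x)
}

#' Serialize / restore an evaluation report as JSON
#'
#' @param report an `rsmoco_report`.
#' @param path file path; when `NULL`, `report_to_json` returns the JSON text.
#' @return `report_to_json`: path or JSON string; `report_from_json`: the
#'   restored report.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "rsmoco_report"))
  obj <- list(n = report$n, per_slice = report$per_slice,
              summary = report$summary, pearson_r = report$pearson_r)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    path
  }
}

#' @rdname report_to_json
#' @export
report_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(per_slice = as.data.frame(obj$per_slice),
                 summary = lapply(obj$summary, function(s) list(mean = s$mean, sd = s$sd)),
                 pearson_r = obj$pearson_r, n = obj$n),
            class = "rsmoco_report")
}
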
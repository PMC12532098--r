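# Centered 2-D discrete Fourier transforms and rigid in-plane transforms.
#
# Conventions fixed here and relied on everywhere else:
#  - k-space is stored centered (zero frequency at the matrix center);
#  - the phase-encode axis is array axis 1 (rows), so one "line" is one row;
#  - the unitary 1/sqrt(HW) normalization is used, so Parseval holds exactly
#    (sum(img^2) == sum(|k|^2)).

fftshift2 <- function(m) {
  d <- dim(m)
  i <- c(seq(floor(d[1] / 2) + 1, d[1]), seq_len(floor(d[1] / 2)))
  j <- c(seq(floor(d[2] / 2) + 1, d[2]), seq_len(floor(d[2] / 2)))
  m[i, j, drop = FALSE]
}

ifftshift2 <- function(m) {
  d <- dim(m)
  i <- c(seq(ceiling(d[1] / 2) + 1, d[1]), seq_len(ceiling(d[1] / 2)))
  j <- c(seq(ceiling(d[2] / 2) + 1, d[2]), seq_len(ceiling(d[2] / 2)))
  m[i, j, drop = FALSE]
}

#' Image to centered k-space and back
#'
#' `to_kspace` computes the centered, unitary 2-D discrete Fourier transform
#' of a real slice; `from_kspace` inverts it and returns the magnitude (real,
#' non-negative), mirroring how magnitude MRI images are reconstructed.
#'
#' @param img real matrix (H x W), finite.
#' @param k complex matrix as produced by `to_kspace` (centered spectrum,
#'   phase-encode axis = rows).
#' @return `to_kspace`: complex H x W matrix; `from_kspace`: real non-negative
#'   H x W matrix.
#' @export
to_kspace <- function(img) {
  if (!is.matrix(img) || !all(is.finite(img))) stop_contract("img must be a finite real matrix")
  fftshift2(stats::fft(img)) / sqrt(length(img))
}

#' @rdname to_kspace
#' @export
from_kspace <- function(k) {
  if (!is.matrix(k)) stop_contract("k must be a matrix")
  Mod(stats::fft(ifftshift2(k), inverse = TRUE)) / sqrt(length(k))
}

#' Apply an in-plane rigid transform to a slice
#'
#' Rotates about the image center by `rotation` degrees, then translates by
#' (`shift_x`, `shift_y`) millimetres (converted to pixels via `spacing`).
#' Resampling is bilinear with zero fill outside the field of view, matching
#' what a rigid head movement does to a 2-D magnitude slice.
#'
#' @param img real matrix.
#' @param motion a motion event as produced by [draw_motion_events()]: a list
#'   with `rotation` (degrees), `shift_x`, `shift_y` (mm).
#' @param spacing pixel size in mm (scalar or length-2 `c(row, col)`).
#' @return transformed matrix, same shape.
#' @export
apply_rigid <- function(img, motion, spacing = 1) {
  if (any(spacing <= 0)) stop_config("spacing must be positive (mm/pixel)")
  spacing <- rep_len(spacing, 2)
  H <- nrow(img); W <- ncol(img)
  if (motion$rotation == 0 && motion$shift_x == 0 && motion$shift_y == 0) return(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  th <- motion$rotation * pi / 180
  # translation in pixels: shift_x moves columns, shift_y moves rows
  tx <- motion$shift_x / spacing[2]
  ty <- motion$shift_y / spacing[1]
  # inverse map: for each output pixel, rotate back then un-translate
  gr <- matrix(seq_len(H), H, W) - cy          # row offsets
  gc <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  ur <- gr - ty
  uc <- gc - tx
  src_r <- cos(th) * ur + sin(th) * uc + cy
  src_c <- -sin(th) * ur + cos(th) * uc + cx
  bilinear_sample(img, src_r, src_c)
}

# Bilinear interpolation with zero outside [1,H]x[1,W].
bilinear_sample <- function(img, src_r, src_c) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    v <- numeric(length(ri))
    idx <- (ci[ok] - 1) * H + ri[ok]
    v[ok] <- img[idx]
    v
  }
  out <- (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    fr * fc * val(r0 + 1, c0 + 1)
  matrix(out, H, W)
}
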
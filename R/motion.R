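#' Severity presets for the k-space motion simulator
#'
#' The three named presets perturb 15 (heavy), 10 (moderate) and 7 (minor)
#' phase-encode lines, grouped into random slabs of 3-7 contiguous lines, with
#' rigid-motion draws bounded by +/-7 degrees of rotation and +/-5 mm of
#' translation per axis.
#'
#' @param name `"minor"`, `"moderate"` or `"heavy"`.
#' @param n_lines override the perturbed-line count.
#' @param slab_width_range integer pair, allowed slab widths (lines).
#' @param rot_bound rotation bound, degrees.
#' @param trans_bound translation bound, mm.
#' @param exclusion_radius number of central phase-encode lines (either side
#'   of the k-space center) never perturbed; default 0 (no exclusion).
#' @return an object of class `"rsmoco_preset"`.
#' @export
severity_preset <- function(name = c("heavy", "moderate", "minor"),
                            n_lines = NULL,
                            slab_width_range = c(3L, 7L),
                            rot_bound = 7, trans_bound = 5,
                            exclusion_radius = 0L) {
  name <- match.arg(name)
  if (is.null(n_lines)) {
    n_lines <- c(heavy = 15L, moderate = 10L, minor = 7L)[[name]]
  }
  if (n_lines < 0) stop_config("n_lines must be >= 0")
  if (length(slab_width_range) != 2 || any(slab_width_range < 1) ||
      slab_width_range[1] > slab_width_range[2]) {
    stop_config("slab_width_range must be an increasing positive pair")
  }
  if (rot_bound < 0 || trans_bound < 0) stop_config("bounds must be non-negative")
  structure(list(name = name, n_lines = as.integer(n_lines),
                 slab_width_range = as.integer(slab_width_range),
                 rot_bound = rot_bound, trans_bound = trans_bound,
                 exclusion_radius = as.integer(exclusion_radius)),
            class = "rsmoco_preset")
}

#' Draw disjoint phase-encode slabs
#'
#' Partitions `n_lines` into slab widths drawn uniformly from `width_range`
#' and places the slabs disjointly and uniformly over the `n_pe` phase-encode
#' lines. The total number of covered lines always equals `n_lines` exactly;
#' if the remaining budget cannot accommodate a width within range, the final
#' slab is clipped to the remainder (a below-minimum width is recorded in the
#' `"width_violation"` attribute rather than raised, so line accounting stays
#' exact).
#'
#' @param n_lines total lines to perturb (<= `n_pe`).
#' @param width_range integer pair of allowed widths.
#' @param n_pe number of phase-encode lines available.
#' @param rng an [rng_stream()].
#' @return list of slabs, each `list(start, width)` with 1-based line indices
#'   `start .. start+width-1`; slabs are disjoint.
#' @export
draw_slabs <- function(n_lines, width_range = c(3L, 7L), n_pe, rng) {
  if (n_lines > n_pe) stop_contract("n_lines (", n_lines, ") exceeds n_pe (", n_pe, ")")
  if (n_lines == 0) return(list())
  widths <- integer(0)
  remaining <- n_lines
  violation <- FALSE
  while (remaining > 0) {
    w <- width_range[1] + floor(rng$runif(1) * (width_range[2] - width_range[1] + 1))
    w <- min(w, remaining)
    if (w < width_range[1]) violation <- TRUE   # clipped below the minimum
    widths <- c(widths, as.integer(w))
    remaining <- remaining - w
  }
  k <- length(widths)
  free <- n_pe - n_lines
  # uniform disjoint placement: distribute the free lines into k+1 gaps
  cuts <- sort(floor(rng$runif(k) * (free + 1)))
  starts <- cuts + c(0L, cumsum(widths[-k])) + 1L
  slabs <- Map(function(s, w) list(start = as.integer(s), width = as.integer(w)),
               starts, widths)
  attr(slabs, "width_violation") <- violation
  slabs
}

#' Draw rigid motion events
#'
#' Draws `n` motion events with rotation ~ U(-rot_bound, rot_bound) degrees
#' and per-axis translation ~ U(-trans_bound, trans_bound) mm, plus slab
#' geometry for `n_pe` phase-encode lines when requested. The uniform law is
#' the simulator's reading of the stated +/- bounds.
#'
#' @param n number of events.
#' @param preset an [severity_preset()].
#' @param rng_seed integer seed.
#' @param n_pe optional phase-encode extent; if supplied, slab geometry
#'   (`slab_start`, `slab_width`) is attached by drawing slab sets of
#'   `preset$n_lines` lines until `n` events exist.
#' @return data.frame with columns `rotation`, `shift_x`, `shift_y` (and slab
#'   columns when `n_pe` is given).
#' @export
draw_motion_events <- function(n, preset = severity_preset("heavy"),
                               rng_seed = 0L, n_pe = NULL) {
  stopifnot(inherits(preset, "rsmoco_preset"))
  rng <- rng_stream(rng_seed, "motion-events")
  ev <- data.frame(
    rotation = rng$runif(n, -preset$rot_bound, preset$rot_bound),
    shift_x = rng$runif(n, -preset$trans_bound, preset$trans_bound),
    shift_y = rng$runif(n, -preset$trans_bound, preset$trans_bound)
  )
  if (!is.null(n_pe)) {
    starts <- integer(0); widths <- integer(0)
    while (length(starts) < n) {
      sl <- draw_slabs(preset$n_lines, preset$slab_width_range, n_pe, rng)
      starts <- c(starts, vapply(sl, `[[`, 1L, "start"))
      widths <- c(widths, vapply(sl, `[[`, 1L, "width"))
    }
    ev$slab_start <- starts[seq_len(n)]
    ev$slab_width <- widths[seq_len(n)]
  }
  ev
}

#' Corrupt a slice with simulated rigid motion
#'
#' Implements the in-silico artifact protocol: random disjoint slabs of
#' phase-encode lines (rows of centered k-space) are replaced by the
#' corresponding lines of the k-space of a rigidly transformed copy of the
#' image, one independent motion state per slab. The corrupted magnitude
#' image is reconstructed by inverse FFT; optional additive Gaussian noise
#' models the acquisition noise term (default none). Lines outside all slabs
#' are bit-identical to the original spectrum before inversion.
#'
#' @param img motion-free slice, matrix normalized to \[0, 1\].
#' @param preset an [severity_preset()].
#' @param rng_seed integer seed; the full draw is deterministic given it.
#' @param noise_sigma standard deviation of additive Gaussian acquisition
#'   noise applied to the reconstructed image (default 0).
#' @param spacing pixel size in mm (default 1).
#' @param return_kspace also return the original and mixed spectra (for
#'   audit/testing).
#' @return an object of class `"rsmoco_pair"`: list with `x` (input), `y`
#'   (corrupted), \eqn{r = y - x}, and `motion_log` (data.frame with one row per
#'   slab: rotation, shift_x, shift_y, slab_start, slab_width).
#' @export
corrupt_slice <- function(img, preset = severity_preset("heavy"), rng_seed = 0L,
                          noise_sigma = 0, spacing = 1, return_kspace = FALSE) {
  stopifnot(inherits(preset, "rsmoco_preset"))
  if (!is.matrix(img) || !all(is.finite(img))) stop_contract("img must be a finite matrix")
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9) {
    stop_contract("img must be normalized to [0, 1]")
  }
  rng <- rng_stream(rng_seed, "corrupt")
  H <- nrow(img)
  k0 <- to_kspace(img)
  allowed <- rep(TRUE, H)
  if (preset$exclusion_radius > 0) {
    ctr <- floor(H / 2) + 1
    excl <- max(1, ctr - preset$exclusion_radius):min(H, ctr + preset$exclusion_radius)
    allowed[excl] <- FALSE
  }
  n_pe <- sum(allowed)
  slabs <- draw_slabs(preset$n_lines, preset$slab_width_range, n_pe, rng)
  pe_index <- which(allowed)
  k_mix <- k0
  log_rows <- vector("list", length(slabs))
  for (i in seq_along(slabs)) {
    sl <- slabs[[i]]
    ev <- list(rotation = rng$runif(1, -preset$rot_bound, preset$rot_bound),
               shift_x = rng$runif(1, -preset$trans_bound, preset$trans_bound),
               shift_y = rng$runif(1, -preset$trans_bound, preset$trans_bound))
    moved <- apply_rigid(img, ev, spacing)
    km <- to_kspace(moved)
    rows <- pe_index[sl$start:(sl$start + sl$width - 1)]
    k_mix[rows, ] <- km[rows, ]
    log_rows[[i]] <- data.frame(rotation = ev$rotation, shift_x = ev$shift_x,
                                shift_y = ev$shift_y, slab_start = rows[1],
                                slab_width = sl$width)
  }
  y <- from_kspace(k_mix)
  if (noise_sigma > 0) y <- y + matrix(rng$rnorm(length(y), sd = noise_sigma), H)
  motion_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(rotation = numeric(0), shift_x = numeric(0), shift_y = numeric(0),
               slab_start = integer(0), slab_width = integer(0))
  out <- structure(list(x = img, y = y, r = y - img, motion_log = motion_log,
                        preset = preset$name, seed = rng_seed),
                   class = "rsmoco_pair")
  if (return_kspace) {
    out$k_original <- k0
    out$k_mixed <- k_mix
  }
  out
}

#' @export
print.rsmoco_pair <- function(x, ...) {
  cat(sprintf("Paired sample (%dx%d), preset '%s', %d slab(s), %d perturbed line(s)\n",
              nrow(x$x), ncol(x$x), x$preset, nrow(x$motion_log),
              sum(x$motion_log$slab_width)))
  invisible(x)
}
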
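# Reference OCTA contrasts for comparison: speckle variance on intensity
# volumes; phase variance and complex differential variance on
# complex-valued volumes. These implement the cited formulations directly,
# without the en-face enhancement pipeline.

#' Inter-frame speckle variance
#'
#' Per-voxel variance of the intensity over the repeated-frame axis.
#'
#' @param v an [oct_volume4d()] with `t >= 2`.
#' @param convention `"population"` (divisor t, the default pinned
#'   convention) or `"sample"` (divisor t - 1).
#' @return A [volume3d()] of variances (provenance `stdev_composite`).
#' @export
speckle_variance <- function(v, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  stopifnot(inherits(v, "oct_volume4d"))
  d <- dim(v$data)
  nt <- d[3]
  if (nt < 2) stop("speckle variance requires t >= 2 frames")
  mu <- array(0, dim = d[c(1, 2, 4)])
  for (f in seq_len(nt)) mu <- mu + array(v$data[, , f, , drop = FALSE], dim = d[c(1, 2, 4)])
  mu <- mu / nt
  ss <- array(0, dim = d[c(1, 2, 4)])
  for (f in seq_len(nt)) ss <- ss + (array(v$data[, , f, , drop = FALSE], dim = d[c(1, 2, 4)]) - mu)^2
  div <- if (convention == "population") nt else nt - 1
  volume3d(ss / div, dx = v$dx, dy = v$dy, dz = v$dz,
           provenance = "stdev_composite")
}

.wrap_phase <- function(p) {
  # wrap to (-pi, pi]
  out <- (p + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Phase variance
#'
#' Per-voxel variance over the repeated-frame axis of bulk-corrected phase
#' differences between consecutive frames. The bulk phase error of each
#' frame pair is estimated as the median phase difference over the frame
#' and subtracted; differences are wrapped to `(-pi, pi]`.
#'
#' @param v a [complex_volume4d()] with `t >= 2`.
#' @return A [volume3d()] of phase-difference variances.
#' @export
phase_variance <- function(v) {
  stopifnot(inherits(v, "complex_volume4d"))
  d <- dim(v$data)
  nt <- d[3]
  if (nt < 2) stop("phase variance requires t >= 2 frames")
  np <- nt - 1
  diffs <- array(0, dim = c(d[1], d[2], np, d[4]))
  for (f in seq_len(np)) {
    dphi <- .wrap_phase(Arg(v$data[, , f + 1, , drop = FALSE]) -
                          Arg(v$data[, , f, , drop = FALSE]))
    for (z in seq_len(d[4])) {
      frame <- dphi[, , 1, z]
      diffs[, , f, z] <- .wrap_phase(frame - median(frame))
    }
  }
  # spread about zero: after bulk correction the expected difference of a
  # static voxel is zero, so the second moment is the variance estimate
  # (and it remains informative for the common t = 2 case)
  out <- array(0, dim = d[c(1, 2, 4)])
  for (f in seq_len(np)) out <- out + array(diffs[, , f, , drop = FALSE], dim = d[c(1, 2, 4)])^2
  out <- out / np
  volume3d(out, dx = v$dx, dy = v$dy, dz = v$dz,
           provenance = "stdev_composite")
}

#' Complex differential variance
#'
#' Per-voxel decorrelation statistic on the complex signal:
#' `1 - |sum_t sum_w w A_t conj(A_{t+1})| / sum_t sum_w w (|A_t|^2 + |A_{t+1}|^2) / 2`,
#' with `w` a Gaussian axial (depth) window. Bounded in `[0, 1]`;
#' identical frames give 0, decorrelated speckle approaches 1.
#'
#' @param v a [complex_volume4d()] with `t >= 2`.
#' @param window_halfwidth axial window half-extent in voxels (default 2).
#' @return A [volume3d()] of CDV values.
#' @export
complex_differential_variance <- function(v, window_halfwidth = 2L) {
  stopifnot(inherits(v, "complex_volume4d"))
  d <- dim(v$data)
  nt <- d[3]
  if (nt < 2) stop("CDV requires t >= 2 frames")
  hw <- as.integer(window_halfwidth)
  w <- exp(-(-hw:hw)^2 / (2 * max(hw / 2, 0.5)^2))
  num <- array(0i, dim = d[c(1, 2, 4)])
  den <- array(0, dim = d[c(1, 2, 4)])
  for (f in seq_len(nt - 1)) {
    cross <- v$data[, , f, , drop = FALSE] * Conj(v$data[, , f + 1, , drop = FALSE])
    power <- 0.5 * (Mod(v$data[, , f, , drop = FALSE])^2 +
                      Mod(v$data[, , f + 1, , drop = FALSE])^2)
    num <- num + array(cross, dim = d[c(1, 2, 4)])
    den <- den + array(power, dim = d[c(1, 2, 4)])
  }
  # axial (y) window: weighted sliding sum along dim 2, reflect boundary
  smooth_axial <- function(a) {
    ny <- dim(a)[2]
    acc <- NULL
    for (k in seq_along(w)) {
      off <- k - hw - 1L
      idx <- pmin(pmax(seq_len(ny) + off, 1L), ny)
      term <- w[k] * a[, idx, , drop = FALSE]
      acc <- if (is.null(acc)) term else acc + term
    }
    acc
  }
  num_s <- smooth_axial(num)
  den_s <- smooth_axial(den)
  out <- 1 - Mod(num_s) / pmax(den_s, .Machine$double.xmin)
  out[den_s == 0] <- 0
  volume3d(pmin(pmax(out, 0), 1), dx = v$dx, dy = v$dy, dz = v$dz,
           provenance = "stdev_composite")
}
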
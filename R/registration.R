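# Rigid bulk-motion registration.
#
# Bulk motion (respiration, heartbeat) displaces whole frames; before
# compositing and reslicing, frames are aligned by translation estimated
# from the Fourier cross-correlation peak with parabolic sub-voxel
# refinement. Rotation is optional (small-angle grid search) and off by
# default: physiological drift in this geometry is predominantly
# translational, and residual periodic error is handled downstream by the
# bandpass step.

#' Estimate a rigid transform between two frames
#'
#' Returns the displacement of `moving` relative to `reference`: if
#' `moving[i, j] == reference[i - s1, j - s2]`, the estimate is
#' `(shift_x = s1, shift_y = s2)` (axis 1 and axis 2 of the matrix).
#' Apply with [apply_rigid()] to undo it.
#'
#' @param reference,moving numeric matrices of identical extent.
#' @param allow_rotation also search a small rotation grid (degrees
#'   `±2` in steps of 0.25). Default `FALSE`.
#' @param subpixel refine the correlation peak by parabolic interpolation.
#' @return A list of class `rigid_transform` with `shift_x`, `shift_y`,
#'   `rotation` (radians).
#' @export
estimate_rigid <- function(reference, moving, allow_rotation = FALSE,
                           subpixel = TRUE) {
  stopifnot(is.matrix(reference), is.matrix(moving),
            identical(dim(reference), dim(moving)))
  if (sd(reference) == 0 || sd(moving) == 0) {
    warning("degenerate (constant) frame; returning identity transform")
    return(structure(list(shift_x = 0, shift_y = 0, rotation = 0),
                     class = "rigid_transform"))
  }
  best <- .estimate_shift(reference, moving, subpixel)
  rotation <- 0
  if (isTRUE(allow_rotation)) {
    angles <- seq(-2, 2, by = 0.25) * pi / 180
    for (a in angles) {
      if (a == 0) next
      rot <- .rotate_bilinear(moving, -a)
      cand <- .estimate_shift(reference, rot, subpixel)
      if (cand$score > best$score) {
        best <- cand
        rotation <- a
      }
    }
  }
  structure(list(shift_x = best$s1, shift_y = best$s2, rotation = rotation),
            class = "rigid_transform")
}

.hann <- function(n) {
  if (n < 2) return(rep(1, n))
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

.estimate_shift <- function(reference, moving, subpixel = TRUE) {
  nr <- nrow(reference); nc <- ncol(reference)
  # Hann window: suppresses circular wrap-around and zero-fill edge bias
  W <- outer(.hann(nr), .hann(nc))
  r <- (reference - mean(reference)) * W
  m <- (moving - mean(moving)) * W
  cc <- Re(fft(fft(m) * Conj(fft(r)), inverse = TRUE)) / (nr * nc)
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)
  s1 <- wrap(peak[1] - 1, nr)
  s2 <- wrap(peak[2] - 1, nc)
  if (subpixel) {
    para <- function(l, c0, r0) {
      den <- l - 2 * c0 + r0
      if (den >= 0) 0 else 0.5 * (l - r0) / den
    }
    im <- peak[1]; jm <- peak[2]
    i_lo <- (im - 2) %% nr + 1; i_hi <- im %% nr + 1
    j_lo <- (jm - 2) %% nc + 1; j_hi <- jm %% nc + 1
    s1 <- s1 + para(cc[i_lo, jm], cc[im, jm], cc[i_hi, jm])
    s2 <- s2 + para(cc[im, j_lo], cc[im, jm], cc[im, j_hi])
  }
  list(s1 = s1, s2 = s2, score = max(cc))
}

.rotate_bilinear <- function(img, angle) {
  nr <- nrow(img); nc <- ncol(img)
  ci <- (nr + 1) / 2; cj <- (nc + 1) / 2
  co <- cos(angle); si <- sin(angle)
  i <- matrix(seq_len(nr), nr, nc) - ci
  j <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cj
  # source coordinates (inverse map)
  si0 <- co * i + si * j + ci
  sj0 <- -si * i + co * j + cj
  i0 <- floor(si0); j0 <- floor(sj0)
  fi <- si0 - i0; fj <- sj0 - j0
  at <- function(ii, jj) {
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    v <- numeric(length(ii))
    v[ok] <- img[cbind(ii[ok], jj[ok])]
    v
  }
  out <- (1 - fi) * (1 - fj) * at(i0, j0) + fi * (1 - fj) * at(i0 + 1, j0) +
    (1 - fi) * fj * at(i0, j0 + 1) + fi * fj * at(i0 + 1, j0 + 1)
  matrix(out, nr, nc)
}

#' Apply (undo) a rigid transform
#'
#' Shifts `frame` by the negated transform so that a frame displaced by
#' the estimated amount is brought back into register with the reference.
#' Sub-voxel shifts use bilinear interpolation; uncovered regions are
#' zero-filled.
#'
#' @param frame numeric matrix.
#' @param transform a `rigid_transform` from [estimate_rigid()].
#' @return The registered matrix.
#' @export
apply_rigid <- function(frame, transform) {
  out <- frame
  if (transform$rotation != 0)
    out <- .rotate_bilinear(out, -transform$rotation)
  if (transform$shift_x != 0 || transform$shift_y != 0)
    out <- .shift_bilinear(out, -transform$shift_x, -transform$shift_y)
  out
}

#' Register an OCT volume against bulk motion
#'
#' `across_t` aligns the repeated frames at each B-scan position to the
#' first frame (estimated frame-to-predecessor, accumulated). `across_z`
#' aligns each B-scan (averaged over its frames) to its registered
#' predecessor along the slow axis. `both` performs `across_t` followed by
#' `across_z` — the "second registration step" useful when averaging will
#' follow.
#'
#' @param v an [oct_volume4d()].
#' @param mode `"across_t"`, `"across_z"`, `"both"`, or `"none"`.
#' @param allow_rotation passed to [estimate_rigid()].
#' @return The registered [oct_volume4d()]; estimated transforms are
#'   attached as `attr(, "transforms")`, a data frame with one row per
#'   (z, t).
#' @export
register_volume <- function(v, mode = c("across_t", "across_z", "both", "none"),
                            allow_rotation = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(v, "oct_volume4d"))
  d <- dim(v$data)
  nt <- d[3]; nz <- d[4]
  data <- v$data
  log <- data.frame(z_index = integer(0), t_index = integer(0),
                    shift_x = numeric(0), shift_y = numeric(0),
                    rotation = numeric(0), stage = character(0))
  if (mode %in% c("across_t", "both") && nt > 1) {
    for (z in seq_len(nz)) {
      for (f in 2:nt) {
        # the predecessor is already registered, so the estimate against
        # it is the full transform back to the frame-1 reference
        tr <- estimate_rigid(data[, , f - 1, z], data[, , f, z],
                             allow_rotation = allow_rotation)
        data[, , f, z] <- apply_rigid(data[, , f, z], tr)
        log <- rbind(log, data.frame(z_index = z, t_index = f,
                                     shift_x = tr$shift_x,
                                     shift_y = tr$shift_y,
                                     rotation = tr$rotation,
                                     stage = "across_t"))
      }
    }
  }
  if (mode %in% c("across_z", "both") && nz > 1) {
    prev <- apply(data[, , , 1, drop = FALSE], c(1, 2), mean)
    for (z in 2:nz) {
      cur <- apply(data[, , , z, drop = FALSE], c(1, 2), mean)
      tr <- estimate_rigid(prev, cur, allow_rotation = allow_rotation)
      for (f in seq_len(nt))
        data[, , f, z] <- apply_rigid(data[, , f, z], tr)
      log <- rbind(log, data.frame(z_index = z, t_index = NA_integer_,
                                   shift_x = tr$shift_x,
                                   shift_y = tr$shift_y,
                                   rotation = tr$rotation,
                                   stage = "across_z"))
      prev <- apply(data[, , , z, drop = FALSE], c(1, 2), mean)
    }
  }
  out <- v
  out$data <- pmax(data, 0)
  attr(out, "transforms") <- log
  out
}
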
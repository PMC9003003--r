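# Frame compositing and projection operators.
#
# The repeated-frame axis t is reduced per voxel by the arithmetic mean
# (structure-preserving) or the standard deviation (flow-selective: static
# speckle is frozen across frames and cancels, decorrelating flow speckle
# does not). Projections reduce depth slabs of the en-face stack for
# visualization and per-plexus analysis.

#' Reduce the repeated-frame axis of a 4D volume
#'
#' @param v an [oct_volume4d()].
#' @param method `"mean"`, `"stdev"`, or `"single"` (frame 1).
#' @param stdev_convention `"sample"` (divisor t - 1, the default) or
#'   `"population"` (divisor t).
#' @return A [volume3d()] with provenance recorded.
#' @export
composite_frames <- function(v, method = c("mean", "stdev", "single"),
                             stdev_convention = c("sample", "population")) {
  method <- match.arg(method)
  stdev_convention <- match.arg(stdev_convention)
  stopifnot(inherits(v, "oct_volume4d"))
  d <- dim(v$data)
  nt <- d[3]
  if (method == "stdev" && nt < 2)
    stop("stdev compositing requires at least 2 frames (t >= 2)")
  out <- switch(method,
    single = array(v$data[, , 1, ], dim = d[c(1, 2, 4)]),
    mean = {
      acc <- array(0, dim = d[c(1, 2, 4)])
      for (f in seq_len(nt)) acc <- acc + array(v$data[, , f, , drop = FALSE], dim = d[c(1, 2, 4)])
      acc / nt
    },
    stdev = {
      mu <- array(0, dim = d[c(1, 2, 4)])
      for (f in seq_len(nt)) mu <- mu + array(v$data[, , f, , drop = FALSE], dim = d[c(1, 2, 4)])
      mu <- mu / nt
      ss <- array(0, dim = d[c(1, 2, 4)])
      for (f in seq_len(nt)) ss <- ss + (array(v$data[, , f, , drop = FALSE], dim = d[c(1, 2, 4)]) - mu)^2
      div <- if (stdev_convention == "sample") nt - 1 else nt
      sqrt(ss / div)
    })
  volume3d(out, dx = v$dx, dy = v$dy, dz = v$dz,
           provenance = switch(method, single = "raw_single_frame",
                               mean = "mean_composite",
                               stdev = "stdev_composite"))
}

#' Slab specification for depth projections
#'
#' @param start_slice first depth slice of the slab (1-based index into the
#'   en-face stack).
#' @param thickness_um physical slab depth in micrometres (default 60).
#' @param method reduction over depth: `"max"`, `"mean"`, or `"stdev"`.
#' @return A list of class `slab_spec`.
#' @export
slab_spec <- function(start_slice = 1L, thickness_um = 60,
                      method = c("max", "mean", "stdev")) {
  method <- match.arg(method)
  if (thickness_um <= 0) stop("thickness_um must be positive")
  if (start_slice < 1) stop("start_slice must be >= 1")
  structure(list(start_slice = as.integer(start_slice),
                 thickness_um = thickness_um, method = method),
            class = "slab_spec")
}

#' Number of depth slices covered by a slab
#'
#' `floor(thickness_um / dy)`, minimum 1.
#' @param thickness_um slab thickness in micrometres.
#' @param dy depth sampling in micrometres per slice.
#' @return Integer slice count.
#' @export
slab_slices <- function(thickness_um, dy) {
  max(1L, as.integer(floor(thickness_um / dy)))
}

#' Project one depth slab of an en-face stack
#'
#' @param s an [enface_stack()].
#' @param spec a [slab_spec()].
#' @param normalize rescale the projection to `[0, 1]` by its own min/max
#'   (default FALSE).
#' @return A numeric matrix `[x, z]`.
#' @export
project_slab <- function(s, spec, normalize = FALSE) {
  stopifnot(inherits(s, "enface_stack"), inherits(spec, "slab_spec"))
  ny <- dim(s$data)[3]
  if (spec$start_slice > ny) stop("slab start lies beyond the stack")
  n <- slab_slices(spec$thickness_um, s$dy)
  idx <- spec$start_slice:min(ny, spec$start_slice + n - 1L)
  slab <- s$data[, , idx, drop = FALSE]
  out <- switch(spec$method,
    max = apply(slab, c(1, 2), max),
    mean = apply(slab, c(1, 2), mean),
    stdev = if (length(idx) < 2) array(0, dim(slab)[1:2])
            else apply(slab, c(1, 2), sd))
  if (normalize) {
    rng <- range(out)
    if (diff(rng) > 0) out <- (out - rng[1]) / diff(rng)
  }
  out
}

#' Fire-like depth lookup table
#'
#' Black through blue, red, yellow to white; used to color-code depth
#' within a slab (superficial = blue, ~half depth = red, deepest =
#' yellow-white).
#'
#' @param fractions numeric vector in `[0, 1]`.
#' @return Matrix `[length(fractions), 3]` of RGB values in `[0, 1]`.
#' @export
fire_colormap <- function(fractions) {
  stops <- c(0, 0.25, 0.5, 0.75, 1)
  r <- c(0, 0.1, 0.9, 1.0, 1)
  g <- c(0, 0.1, 0.1, 0.9, 1)
  b <- c(0.1, 0.9, 0.2, 0.1, 1)
  f <- pmin(pmax(fractions, 0), 1)
  cbind(stats::approx(stops, r, f)$y,
        stats::approx(stops, g, f)$y,
        stats::approx(stops, b, f)$y)
}

#' Color-coded depth projection of a slab
#'
#' Per pixel, the depth (within the slab) of the maximal intensity picks
#' the hue through the colormap; brightness scales with that maximal
#' intensity (normalized by the slab maximum).
#'
#' @param s an [enface_stack()].
#' @param spec a [slab_spec()] (`method` is ignored; max is used).
#' @param colormap function mapping fractions in `[0, 1]` to an `[n, 3]`
#'   RGB matrix; default [fire_colormap()].
#' @return A numeric array `[x, z, 3]` of RGB values in `[0, 1]`.
#' @export
project_depth_colormap <- function(s, spec, colormap = fire_colormap) {
  stopifnot(inherits(s, "enface_stack"), inherits(spec, "slab_spec"))
  ny <- dim(s$data)[3]
  if (spec$start_slice > ny) stop("slab start lies beyond the stack")
  n <- slab_slices(spec$thickness_um, s$dy)
  idx <- spec$start_slice:min(ny, spec$start_slice + n - 1L)
  slab <- s$data[, , idx, drop = FALSE]
  peak <- apply(slab, c(1, 2), max)
  argd <- apply(slab, c(1, 2), which.max)
  frac <- if (length(idx) > 1) (argd - 1) / (length(idx) - 1) else argd * 0
  rgb <- colormap(as.vector(frac))
  bright <- if (max(peak) > 0) as.vector(peak) / max(peak) else as.vector(peak)
  out <- array(0, dim = c(dim(peak), 3L))
  for (ch in 1:3) out[, , ch] <- matrix(rgb[, ch] * bright, nrow(peak))
  out
}

#' Consecutive non-overlapping slab projections
#'
#' Walks from `start_slice` to the end of the stack in steps of the slab
#' thickness; a final partial slab is included and flagged via the
#' `"partial"` attribute on the returned list.
#'
#' @param s an [enface_stack()].
#' @param start_slice first depth slice.
#' @param thickness_um slab thickness in micrometres.
#' @param method projection reduction, as in [slab_spec()].
#' @return A list of projection matrices; `attr(, "partial")` is a logical
#'   vector marking slabs thinner than requested, `attr(, "start_slices")`
#'   gives each slab's first slice.
#' @export
consecutive_slabs <- function(s, start_slice = 1L, thickness_um = 60,
                              method = "max") {
  stopifnot(inherits(s, "enface_stack"))
  ny <- dim(s$data)[3]
  if (start_slice > ny || start_slice < 1)
    stop("slab start lies beyond the stack")
  n <- slab_slices(thickness_um, s$dy)
  starts <- seq(as.integer(start_slice), ny, by = n)
  out <- lapply(starts, function(s0) {
    project_slab(s, slab_spec(s0, thickness_um, method))
  })
  attr(out, "partial") <- (starts + n - 1L) > ny
  attr(out, "start_slices") <- starts
  out
}
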
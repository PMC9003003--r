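#' 4D OCT intensity volume
#'
#' The universal input container. Index semantics follow the raw scan
#' geometry: `[x, y, t, z]`, where `x` counts A-scans within a B-scan,
#' `y` is depth along the A-scan, `t` indexes repeated frames acquired at
#' the same slow-axis position, and `z` indexes B-scans. Indices are
#' 1-based in R; extents are stated as closed ranges.
#'
#' @param data 4D numeric array indexed `[x, y, t, z]`, non-negative.
#' @param dx,dy,dz voxel spacing in micrometres along x, y (depth) and z.
#' @param bit_depth nominal quantization of the source data, 8 or 16.
#'   Processing is carried out in double precision regardless.
#' @return An object of class `oct_volume4d`.
#' @export
oct_volume4d <- function(data, dx = 1.4, dy = 1.9, dz = 1.4, bit_depth = 8) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array indexed [x, y, t, z]")
  if (any(dim(data) < 1L)) stop("all four extents must be >= 1")
  if (!all(is.finite(data))) stop("intensities must be finite")
  if (min(data) < 0) stop("intensities must be non-negative")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  if (max(data) > 2^bit_depth - 1 + 1e-9)
    stop("intensities exceed the stated bit depth")
  if (dx <= 0 || dy <= 0 || dz <= 0) stop("voxel spacings must be positive")
  structure(list(data = data, dx = dx, dy = dy, dz = dz,
                 bit_depth = as.integer(bit_depth)),
            class = "oct_volume4d")
}

#' 4D complex-valued OCT volume
#'
#' Carries the complex OCT signal (real and imaginary channels) required by
#' the phase-based baseline contrasts. Intensity is the squared magnitude.
#'
#' @param data 4D complex array indexed `[x, y, t, z]`.
#' @inheritParams oct_volume4d
#' @return An object of class `complex_volume4d`.
#' @export
complex_volume4d <- function(data, dx = 1.4, dy = 1.9, dz = 1.4) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array indexed [x, y, t, z]")
  if (!is.complex(data)) stop("`data` must be complex-valued")
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop("complex samples must be finite")
  structure(list(data = data, dx = dx, dy = dy, dz = dz),
            class = "complex_volume4d")
}

#' 3D volume in B-scan order
#'
#' A `[x, y, z]` cube obtained from an [oct_volume4d()] by selecting a
#' single frame or compositing over `t`. `provenance` records how the `t`
#' axis was reduced.
#'
#' @param data 3D numeric array indexed `[x, y, z]`.
#' @inheritParams oct_volume4d
#' @param provenance one of `"raw_single_frame"`, `"mean_composite"`,
#'   `"stdev_composite"`.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, dx = 1.4, dy = 1.9, dz = 1.4,
                     provenance = c("raw_single_frame", "mean_composite",
                                    "stdev_composite")) {
  provenance <- match.arg(provenance)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed [x, y, z]")
  if (dx <= 0 || dy <= 0 || dz <= 0) stop("voxel spacings must be positive")
  structure(list(data = data, dx = dx, dy = dy, dz = dz,
                 provenance = provenance),
            class = "volume3d")
}

#' En-face (C-scan) stack
#'
#' The working representation of the enhancement pipeline: slices are
#' en-face planes, the slice index is depth. Element `[i, k, j]` equals
#' element `[i, j, k]` of the source [volume3d()] — the reslice is a pure
#' axis permutation, no resampling.
#'
#' @param data 3D numeric array indexed `[x, z, y]`.
#' @inheritParams volume3d
#' @return An object of class `enface_stack`.
#' @export
enface_stack <- function(data, dx = 1.4, dy = 1.9, dz = 1.4,
                         provenance = "raw_single_frame") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed [x, z, y]")
  structure(list(data = data, dx = dx, dy = dy, dz = dz,
                 provenance = provenance),
            class = "enface_stack")
}

#' @export
print.oct_volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<oct_volume4d> [x=%d, y=%d, t=%d, z=%d], %d-bit, dx=%g dy=%g dz=%g um\n",
              d[1], d[2], d[3], d[4], x$bit_depth, x$dx, x$dy, x$dz))
  invisible(x)
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> [x=%d, y=%d, z=%d], %s\n", d[1], d[2], d[3],
              x$provenance))
  invisible(x)
}

#' @export
print.enface_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<enface_stack> [x=%d, z=%d, y=%d], %s\n", d[1], d[2], d[3],
              x$provenance))
  invisible(x)
}

#' Reslice a B-scan volume to the en-face view
#'
#' Pure axis permutation `[x, y, z] -> [x, z, y]`; voxel values are
#' preserved exactly and no interpolation takes place.
#'
#' @param v a [volume3d()].
#' @return An [enface_stack()].
#' @export
reslice_to_enface <- function(v) {
  stopifnot(inherits(v, "volume3d"))
  enface_stack(aperm(v$data, c(1L, 3L, 2L)), dx = v$dx, dy = v$dy, dz = v$dz,
               provenance = v$provenance)
}

#' Invert the en-face reslice
#'
#' @param s an [enface_stack()].
#' @return The source-order [volume3d()].
#' @export
reslice_from_enface <- function(s) {
  stopifnot(inherits(s, "enface_stack"))
  volume3d(aperm(s$data, c(1L, 3L, 2L)), dx = s$dx, dy = s$dy, dz = s$dz,
           provenance = s$provenance)
}

#' Virtual B-scan reslice
#'
#' Permutes a `[x, y, z]` volume to `[z, y, x]`, producing cross-sections
#' orthogonal to the acquired B-scans.
#'
#' @param v a [volume3d()].
#' @return A plain 3D array indexed `[z, y, x]`.
#' @export
reslice_virtual_bscan <- function(v) {
  stopifnot(inherits(v, "volume3d"))
  aperm(v$data, c(3L, 2L, 1L))
}
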
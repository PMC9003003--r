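# Synthetic 4D OCT phantom with known vessel/fiber ground truth.
#
# The phantom encodes the statistical structure the method exploits:
#   - static tissue carries *frozen* multiplicative speckle (identical in
#     every repeated frame, spatially correlated),
#   - flowing blood carries fully developed speckle redrawn independently
#     per frame (intensity ~ mean * Exp(1)),
#   - vessels cast shadows on deeper voxels,
#   - bulk motion displaces each frame rigidly in-plane, following
#     sinusoidal breathing and heartbeat mapped through the scan rate,
#   - additive non-tissue noise of known RMS.

#' Phantom specification
#'
#' Defaults model a desk-scale murine retina acquisition: three vascular
#' plexuses (superficial with static fiber bundles, intermediate, deep),
#' vessel diameters spanning 2-20 voxels, shadowing, breathing and
#' heartbeat motion, and a 34 s volume acquisition.
#'
#' @param nx,ny,nt,nz extents along x (A-scans/B-scan), y (depth), t
#'   (repeated frames), z (B-scans).
#' @param dx,dy,dz voxel spacing, micrometres.
#' @param layers data frame with columns `name`, `y_from`, `y_to`
#'   (inclusive depth indices) and `intensity` (mean tissue reflectivity).
#' @param vessels data frame with columns `plexus`, `y0` (centre depth),
#'   `z0` (en-face intercept, voxels), `angle_deg` (en-face orientation),
#'   `radius` (voxels), `intensity`, `flow` (logical).
#' @param fibers data frame like `vessels` (no `flow`, no `y0` spread):
#'   static superficial ridge bundles.
#' @param background_rms additive non-tissue noise RMS (default 20, 8-bit).
#' @param shadow_attenuation multiplicative attenuation applied below each
#'   vessel, in `[0, 1]` (default 0.85; 1 disables shadows).
#' @param breathing_amplitude,breathing_rate_hz bulk breathing motion
#'   (voxels along y; default 6 voxels at 1 Hz, the 55-65 BPM band).
#' @param heart_amplitude,heart_rate_hz cardiac motion (default 1.5 voxels
#'   at 2.7 Hz, ~160 BPM).
#' @param scan_duration_s time to acquire the full volume (default 34 s,
#'   preserved from the full-scale acquisition so that motion phases per
#'   frame match in vivo conditions at desk scale).
#' @param speckle_correlation static speckle correlation length, voxels.
#' @param flow_decorrelation if FALSE, vessel speckle is frozen like the
#'   tissue (flow becomes invisible to temporal contrast).
#' @param motion if FALSE, all bulk motion is disabled.
#' @param complex also synthesize a complex-valued twin (for the
#'   phase-based baselines).
#' @param bit_depth 8 or 16.
#' @param seed RNG seed; a fixed seed yields bit-identical phantoms.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(nx = 64, ny = 48, nt = 3, nz = 64,
                         dx = 1.4, dy = 1.9, dz = 1.4,
                         layers = NULL, vessels = NULL, fibers = NULL,
                         background_rms = 20,
                         shadow_attenuation = 0.85,
                         breathing_amplitude = 6, breathing_rate_hz = 1.0,
                         heart_amplitude = 1.5, heart_rate_hz = 160 / 60,
                         scan_duration_s = 34,
                         speckle_correlation = 2,
                         flow_decorrelation = TRUE,
                         motion = TRUE,
                         complex = FALSE,
                         bit_depth = 8,
                         seed = 1L) {
  if (nt < 1) stop("t extent must be >= 1")
  if (breathing_rate_hz <= 0 || heart_rate_hz <= 0 || scan_duration_s <= 0)
    stop("rates and durations must be positive")
  if (shadow_attenuation < 0 || shadow_attenuation > 1)
    stop("shadow_attenuation must lie in [0, 1]")
  if (is.null(layers)) {
    layers <- data.frame(
      name = c("superficial", "intermediate", "deep"),
      y_from = round(c(0.12, 0.38, 0.64) * ny),
      y_to = round(c(0.36, 0.62, 0.88) * ny),
      intensity = c(60, 50, 50))
  }
  if (!is.null(vessels)) {
    for (i in seq_len(nrow(vessels))) {
      if (vessels$y0[i] - vessels$radius[i] < 1 ||
          vessels$y0[i] + vessels$radius[i] > ny)
        stop("vessel lies outside the volume")
    }
  }
  structure(list(nx = nx, ny = ny, nt = nt, nz = nz, dx = dx, dy = dy,
                 dz = dz, layers = layers, vessels = vessels, fibers = fibers,
                 background_rms = background_rms,
                 shadow_attenuation = shadow_attenuation,
                 breathing_amplitude = breathing_amplitude,
                 breathing_rate_hz = breathing_rate_hz,
                 heart_amplitude = heart_amplitude,
                 heart_rate_hz = heart_rate_hz,
                 scan_duration_s = scan_duration_s,
                 speckle_correlation = speckle_correlation,
                 flow_decorrelation = isTRUE(flow_decorrelation),
                 motion = isTRUE(motion), complex = isTRUE(complex),
                 bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default desk-scale retina phantom specification
#'
#' A 160 x 96 x 3 x 160 phantom with three vascular plexuses. The
#' superficial plexus is contaminated by static fiber bundles; vessel
#' diameters span 2-20 voxels (including a 4-voxel-diameter vessel in
#' every plexus); shadows and bulk motion are on.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
default_retina_spec <- function(seed = 1L, ...) {
  ny <- 96
  sup_y <- round(0.24 * ny)   # 23
  int_y <- round(0.50 * ny)   # 48
  deep_y <- round(0.76 * ny)  # 73
  vessels <- data.frame(
    plexus = c("superficial", "superficial", "superficial",
               "intermediate", "intermediate", "intermediate",
               "deep", "deep", "deep"),
    y0 = c(sup_y, sup_y, sup_y, int_y, int_y, int_y, deep_y, deep_y, deep_y),
    z0 = c(30, 75, 120, 45, 90, 135, 25, 70, 115),
    angle_deg = c(0, 15, -20, 5, 0, -10, 0, 25, -15),
    radius = c(2, 1, 4, 10, 2, 4, 2, 4, 1),
    intensity = 120,
    flow = TRUE)
  fibers <- data.frame(
    plexus = "superficial",
    y0 = round(0.17 * ny),
    z0 = c(15, 50, 60, 100, 140),
    angle_deg = c(10, -5, 30, 0, -25),
    radius = 1.5,
    intensity = 110,
    flow = FALSE)
  phantom_spec(nx = 160, ny = ny, nt = 3, nz = 160,
               vessels = vessels, fibers = fibers, seed = seed, ...)
}

# correlated, mean-one, non-negative speckle field (fully developed
# speckle smoothed to the stated correlation length)
.speckle_field <- function(dims, corr_len) {
  f <- array(rexp(prod(dims)), dim = dims)
  if (corr_len > 0) {
    k <- .gaussian_kernel_1d(corr_len / 2, halfwidth = max(1L, ceiling(corr_len)))
    for (k3 in seq_len(dims[3])) {
      m <- .conv2_reflect(f[, , k3], matrix(k, ncol = 1))
      f[, , k3] <- .conv2_reflect(m, matrix(k, nrow = 1))
    }
  }
  f / mean(f)
}

# distance of en-face point (x, z) from the line through (z = z0) with
# orientation angle_deg measured from the x axis
.line_distance <- function(xg, zg, z0, angle_deg) {
  th <- angle_deg * pi / 180
  # line: passes through (x = centre, z = z0), direction (cos th, sin th)
  x0 <- (max(xg) + 1) / 2
  abs(-sin(th) * (xg - x0) + cos(th) * (zg - z0))
}

#' Generate a synthetic OCT phantom
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` ([oct_volume4d()]), `vessel_mask`
#'   and `fiber_mask` (logical `[x, z, y]` arrays aligned with the en-face
#'   reslice of the composited volume, plus class `vessel_mask`),
#'   `layers` (the plexus depth table), `spec`, and (when
#'   `spec$complex`) `complex_volume` ([complex_volume4d()]).
#' @export
generate_phantom <- function(spec = default_retina_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  nx <- spec$nx; ny <- spec$ny; nt <- spec$nt; nz <- spec$nz
  xg <- matrix(seq_len(nx), nx, nz)
  zg <- matrix(seq_len(nz), nx, nz, byrow = TRUE)

  # structural reflectivity B[x, y, z] from the layer table
  base <- array(0, dim = c(nx, ny, nz))
  for (i in seq_len(nrow(spec$layers))) {
    yy <- max(1, spec$layers$y_from[i]):min(ny, spec$layers$y_to[i])
    base[, yy, ] <- spec$layers$intensity[i]
  }

  tubes <- rbind(
    if (!is.null(spec$vessels)) cbind(spec$vessels, kind = "vessel"),
    if (!is.null(spec$fibers)) cbind(spec$fibers, kind = "fiber"))
  vessel_mask <- array(FALSE, dim = c(nx, nz, ny))
  fiber_mask <- array(FALSE, dim = c(nx, nz, ny))
  flow_vox <- array(FALSE, dim = c(nx, ny, nz))    # [x, y, z]
  shadow <- array(1, dim = c(nx, ny, nz))

  if (!is.null(tubes) && nrow(tubes)) {
    for (i in seq_len(nrow(tubes))) {
      tb <- tubes[i, ]
      dperp <- .line_distance(xg, zg, tb$z0, tb$angle_deg)  # [x, z]
      for (y in seq_len(ny)) {
        dy_vox <- y - tb$y0
        if (abs(dy_vox) > tb$radius + 0.5) next
        inside <- sqrt(dperp^2 + dy_vox^2) <= tb$radius + 1e-9  # [x, z]
        if (!any(inside)) next
        sel <- which(inside)
        xi <- ((sel - 1) %% nx) + 1
        zi <- ((sel - 1) %/% nx) + 1
        base[cbind(xi, y, zi)] <- tb$intensity
        if (tb$kind == "vessel") {
          vessel_mask[cbind(xi, zi, y)] <- TRUE
          if (isTRUE(tb$flow)) flow_vox[cbind(xi, y, zi)] <- TRUE
        } else {
          fiber_mask[cbind(xi, zi, y)] <- TRUE
        }
      }
      if (tb$kind == "vessel" && spec$shadow_attenuation < 1) {
        caster <- dperp <= tb$radius
        y_below <- seq_len(ny) > tb$y0 + tb$radius
        if (any(caster) && any(y_below)) {
          sel <- which(caster)
          xi <- ((sel - 1) %% nx) + 1
          zi <- ((sel - 1) %/% nx) + 1
          for (y in which(y_below))
            shadow[cbind(xi, y, zi)] <-
              shadow[cbind(xi, y, zi)] * spec$shadow_attenuation
        }
      }
    }
  }

  static_speckle <- .speckle_field(c(nx, ny, nz), spec$speckle_correlation)
  static_part <- base * static_speckle * shadow

  # frame times: B-scan z, frame f acquired at t = ((z-1)*nt + (f-1)) * T_frame
  t_frame <- spec$scan_duration_s / (nz * nt)
  shift_y_of <- function(z, f) {
    if (!spec$motion) return(0)
    tt <- ((z - 1) * nt + (f - 1)) * t_frame
    spec$breathing_amplitude * sin(2 * pi * spec$breathing_rate_hz * tt) +
      spec$heart_amplitude * sin(2 * pi * spec$heart_rate_hz * tt)
  }

  data <- array(0, dim = c(nx, ny, nt, nz))
  flow_any <- which(flow_vox)
  for (f in seq_len(nt)) {
    frame_field <- static_part
    if (length(flow_any)) {
      if (spec$flow_decorrelation || f == 1) {
        flow_draw <- rexp(length(flow_any))
      }
      # without decorrelation the f == 1 draw stays frozen across frames
      frame_field[flow_any] <- base[flow_any] * flow_draw *
        shadow[flow_any]
    }
    for (z in seq_len(nz)) {
      frame <- frame_field[, , z]
      sy <- shift_y_of(z, f)
      if (sy != 0) frame <- .shift_bilinear(frame, 0, sy)
      data[, , f, z] <- frame
    }
  }
  noise <- abs(array(rnorm(length(data), sd = spec$background_rms),
                     dim = dim(data)))
  data <- data + noise
  data <- pmin(data, 2^spec$bit_depth - 1)

  out <- list(
    volume = oct_volume4d(data, dx = spec$dx, dy = spec$dy, dz = spec$dz,
                          bit_depth = spec$bit_depth),
    vessel_mask = structure(list(data = vessel_mask, source = "phantom_truth"),
                            class = "vessel_mask"),
    fiber_mask = structure(list(data = fiber_mask, source = "phantom_truth"),
                           class = "vessel_mask"),
    layers = spec$layers,
    spec = spec)

  if (spec$complex) {
    sigma_c <- sqrt(pmax(base * shadow, 0) / 2)
    re_s <- array(rnorm(nx * ny * nz), dim = c(nx, ny, nz)) * sigma_c
    im_s <- array(rnorm(nx * ny * nz), dim = c(nx, ny, nz)) * sigma_c
    cdata <- array(0i, dim = c(nx, ny, nt, nz))
    noise_sd <- spec$background_rms / sqrt(2)
    for (f in seq_len(nt)) {
      re_f <- re_s; im_f <- im_s
      if (length(flow_any) && (spec$flow_decorrelation || f == 1)) {
        re_flow <- rnorm(length(flow_any)) * sigma_c[flow_any]
        im_flow <- rnorm(length(flow_any)) * sigma_c[flow_any]
      }
      if (length(flow_any)) {
        re_f[flow_any] <- re_flow
        im_f[flow_any] <- im_flow
      }
      cdata[, , f, ] <- complex(
        real = re_f + rnorm(nx * ny * nz, sd = noise_sd),
        imaginary = im_f + rnorm(nx * ny * nz, sd = noise_sd))
    }
    out$complex_volume <- complex_volume4d(cdata, dx = spec$dx, dy = spec$dy,
                                           dz = spec$dz)
  }
  out
}

#' Plexus analysis regions from phantom metadata
#'
#' Builds per-plexus signal (vessel) and noise (non-vessel tissue,
#' including any fibers) masks aligned with the en-face stack, from the
#' phantom's layer table and ground-truth masks.
#'
#' @param phantom result of [generate_phantom()].
#' @return Named list of regions, each a list with `signal` and `noise`
#'   logical `[x, z, y]` arrays.
#' @export
phantom_plexus_regions <- function(phantom) {
  ny <- phantom$spec$ny
  vm <- phantom$vessel_mask$data
  regions <- list()
  for (i in seq_len(nrow(phantom$layers))) {
    nm <- phantom$layers$name[i]
    yy <- max(1, phantom$layers$y_from[i]):min(ny, phantom$layers$y_to[i])
    in_layer <- array(FALSE, dim = dim(vm))
    in_layer[, , yy] <- TRUE
    regions[[nm]] <- list(signal = vm & in_layer,
                          noise = !vm & in_layer)
  }
  regions
}
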
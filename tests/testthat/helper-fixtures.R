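# Shared fixtures, all generated in code.

# Small, fast phantom with one flowing vessel per plexus and one fiber;
# used by unit tests that only need plausible structure.
small_retina_spec <- function(seed = 7L, ...) {
  ny <- 48
  vessels <- data.frame(
    plexus = c("superficial", "intermediate", "deep"),
    y0 = round(c(0.24, 0.5, 0.76) * ny),
    z0 = c(16, 32, 48),
    angle_deg = c(0, 10, -15),
    radius = c(2, 3, 2),
    intensity = 120,
    flow = TRUE)
  fibers <- data.frame(
    plexus = "superficial", y0 = round(0.16 * ny), z0 = 24,
    angle_deg = 5, radius = 1.5, intensity = 110, flow = FALSE)
  phantom_spec(nx = 64, ny = ny, nt = 3, nz = 64,
               vessels = vessels, fibers = fibers, seed = seed, ...)
}

# Straight bright tube of given diameter and orientation on a noisy
# background (the t1 acceptance geometry).
render_tube_slice <- function(n, theta, diameter, intensity, noise_rms,
                              seed = 0L) {
  set.seed(seed)
  i <- matrix(seq_len(n), n, n)
  j <- matrix(seq_len(n), n, n, byrow = TRUE)
  c0 <- (n + 1) / 2
  d <- abs(-sin(theta) * (i - c0) + cos(theta) * (j - c0))
  img <- matrix(0, n, n)
  img[d <= diameter / 2] <- intensity
  img + abs(rnorm(n * n, sd = noise_rms))
}

tube_distance <- function(n, theta) {
  i <- matrix(seq_len(n), n, n)
  j <- matrix(seq_len(n), n, n, byrow = TRUE)
  c0 <- (n + 1) / 2
  abs(-sin(theta) * (i - c0) + cos(theta) * (j - c0))
}

# Plain-R rolling-ball oracle: grayscale opening with a ball structuring
# element, written independently of the compiled implementation.
oracle_rollball_background <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img); r <- floor(radius)
  off <- expand.grid(a = -r:r, b = -r:r)
  off <- off[off$a^2 + off$b^2 <= radius^2, ]
  h <- sqrt(radius^2 - off$a^2 - off$b^2)
  ero <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(off))) {
    ii <- (1:nr) + off$a[k]; jj <- (1:nc) + off$b[k]
    vi <- ii >= 1 & ii <= nr; vj <- jj >= 1 & jj <= nc
    sub <- matrix(Inf, nr, nc)
    sub[vi, vj] <- img[ii[vi], jj[vj]] - h[k]
    ero <- pmin(ero, sub)
  }
  dil <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(off))) {
    ii <- (1:nr) - off$a[k]; jj <- (1:nc) - off$b[k]
    vi <- ii >= 1 & ii <= nr; vj <- jj >= 1 & jj <= nc
    sub <- matrix(-Inf, nr, nc)
    sub[vi, vj] <- ero[ii[vi], jj[vj]] + h[k]
    dil <- pmax(dil, sub)
  }
  dil
}
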
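# SNR / CNR evaluation and ground-truth mask construction.
#
# SNR: mean intensity on the vessel mask divided by the standard deviation
# on its complement. CNR: (mu_s - mu_n) / sqrt(0.5 * (sd_s^2 + sd_n^2)),
# invariant under common affine intensity rescaling.

.mask_data <- function(m) {
  d <- if (is.list(m)) m$data else m
  storage.mode(d) <- "logical"
  d
}

.image_data <- function(x) if (is.list(x)) x$data else x

#' Signal-to-noise ratio over a vessel mask
#'
#' @param image numeric matrix/array, [enface_stack()] or [volume3d()].
#' @param mask logical mask of identical extent (or a list with `$data`);
#'   TRUE marks vessel voxels. Background is the mask complement.
#' @return Scalar SNR.
#' @export
snr <- function(image, mask) {
  v <- .image_data(image)
  m <- .mask_data(mask)
  if (!identical(dim(v), dim(m))) stop("mask extent must match the image")
  if (!any(m)) stop("vessel mask is empty")
  if (all(m)) stop("vessel mask covers everything; background is empty")
  sd_bg <- sd(v[!m])
  if (sd_bg == 0) stop("zero background standard deviation; SNR undefined")
  mean(v[m]) / sd_bg
}

#' Contrast-to-noise ratio between two regions
#'
#' @param image numeric matrix/array or stack.
#' @param signal_mask,noise_mask logical masks of identical extent.
#' @return Scalar CNR.
#' @export
cnr <- function(image, signal_mask, noise_mask) {
  v <- .image_data(image)
  s <- .mask_data(signal_mask)
  n <- .mask_data(noise_mask)
  if (!identical(dim(v), dim(s)) || !identical(dim(v), dim(n)))
    stop("mask extents must match the image")
  if (!any(s) || !any(n)) stop("empty region mask")
  mu_s <- mean(v[s]); mu_n <- mean(v[n])
  sd_s <- sd(v[s]); sd_n <- sd(v[n])
  den <- sqrt(0.5 * (sd_s^2 + sd_n^2))
  if (den == 0) {
    if (mu_s == mu_n) return(0)
    stop("zero pooled standard deviation; CNR undefined")
  }
  (mu_s - mu_n) / den
}

.otsu_threshold <- function(v, n_bins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(n_bins, 1L + as.integer((v - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  centres <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * centres)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  centres[which.max(sigma_b)]
}

.box_mean_2d <- function(m, halfwidth) {
  # local mean over a (2h+1)^2 window via integral image, edge-normalized
  nr <- nrow(m); nc <- ncol(m)
  ii <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  h <- halfwidth
  r1 <- pmax(seq_len(nr) - h, 1); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1); c2 <- pmin(seq_len(nc) + h, nc)
  S <- ii[r2 + 1, c2 + 1, drop = FALSE] - ii[r1, c2 + 1, drop = FALSE] -
    ii[r2 + 1, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
  area <- outer(r2 - r1 + 1, c2 - c1 + 1)
  S / area
}

#' Build a consensus ground-truth vessel mask
#'
#' Min-max normalizes each input stack, averages them with equal weight,
#' low-pass filters to remove small elements (Gaussian, sigma 2), zeroes
#' everything below a global Otsu threshold, then binarizes with a local
#' adaptive mean threshold (window 25 voxels, configurable offset).
#'
#' @param stacks list of [enface_stack()]s (or 3D arrays) with identical
#'   extents; a single stack is allowed.
#' @param lowpass_sigma Gaussian sigma of the low-pass, voxels.
#' @param adaptive_window local-mean window width, voxels.
#' @param adaptive_offset added to the local mean before comparison
#'   (larger = stricter). The default 0.05 (on the min-max normalized
#'   scale) was calibrated once against the phantom ground truth.
#' @return A list of class `vessel_mask` with logical `data` and
#'   `source = "estimated"`.
#' @export
build_groundtruth_mask <- function(stacks, lowpass_sigma = 2,
                                   adaptive_window = 25,
                                   adaptive_offset = 0.05) {
  if (inherits(stacks, "enface_stack") || (is.array(stacks) && !is.list(stacks)))
    stacks <- list(stacks)
  arrs <- lapply(stacks, .image_data)
  dims <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), dims), logical(1))))
    stop("all stacks must share one extent")
  norm <- lapply(arrs, function(a) {
    rng <- range(a)
    if (diff(rng) == 0) a * 0 else (a - rng[1]) / diff(rng)
  })
  avg <- Reduce(`+`, norm) / length(norm)
  if (max(avg) == 0) {
    warning("all-zero input stacks; returning an empty mask")
    return(structure(list(data = array(FALSE, dims), source = "estimated"),
                     class = "vessel_mask"))
  }
  k <- .gaussian_kernel_1d(lowpass_sigma)
  lp <- avg
  for (j in seq_len(dims[3])) {
    m <- .conv2_reflect(lp[, , j], matrix(k, ncol = 1))
    lp[, , j] <- .conv2_reflect(m, matrix(k, nrow = 1))
  }
  thr <- .otsu_threshold(lp)
  lp[lp < thr] <- 0
  h <- max(1L, as.integer(adaptive_window) %/% 2L)
  mask <- array(FALSE, dims)
  for (j in seq_len(dims[3])) {
    loc <- .box_mean_2d(lp[, , j], h)
    mask[, , j] <- lp[, , j] > (loc + adaptive_offset) & lp[, , j] > 0
  }
  structure(list(data = mask, source = "estimated"), class = "vessel_mask")
}

#' Dice overlap between two binary masks
#'
#' @param a,b logical arrays (or `vessel_mask` objects) of equal extent.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- .mask_data(a); b <- .mask_data(b)
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Step-wise CNR report across the pipeline
#'
#' For each requested compositing method, composites the 4D volume,
#' reslices to the en-face view, runs the enhancement with all checkpoints
#' saved, and evaluates the CNR at the 7 checkpoints (input plus the six
#' steps), together with the percent change relative to step 1.
#'
#' @param v an [oct_volume4d()] (registered upstream if needed).
#' @param cfg a [pipeline_config()].
#' @param signal_mask,noise_mask logical masks aligned with the en-face
#'   stack (`[x, z, y]`).
#' @param methods subset of `c("stdev", "mean", "single")`.
#' @return A `contrast_report` data frame with columns `region`, `method`,
#'   `step`, `step_name`, `metric`, `value`, `pct_change`.
#' @export
stepwise_cnr <- function(v, cfg = pipeline_config(), signal_mask, noise_mask,
                         methods = c("stdev", "mean", "single")) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (m in methods) {
    st <- reslice_to_enface(composite_frames(v, m))
    steps <- enhance_stack(st, cfg, save_steps = TRUE)
    vals <- vapply(steps, function(ck) cnr(ck, signal_mask, noise_mask),
                   numeric(1))
    rows[[m]] <- data.frame(region = "all", method = m,
                            step = seq_along(vals),
                            step_name = names(steps),
                            metric = "CNR", value = unname(vals),
                            pct_change = 100 * (unname(vals) / vals[[1]] - 1))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contrast_report", class(out))
  out
}

#' Per-plexus CNR report
#'
#' Evaluates the CNR of each vascular plexus region in each provided
#' stack (one stack per compositing method).
#'
#' @param stacks named list of [enface_stack()]s (names are the methods,
#'   e.g. `stdev`, `mean`, `single`).
#' @param regions named list of plexus regions; each region is a list with
#'   logical `signal` and `noise` masks aligned with the stacks.
#' @return A `contrast_report` data frame with columns `region`, `method`,
#'   `metric`, `value`.
#' @export
plexus_cnr_report <- function(stacks, regions) {
  if (!length(regions))
    return(structure(data.frame(region = character(0), method = character(0),
                                metric = character(0), value = numeric(0)),
                     class = c("contrast_report", "data.frame")))
  rows <- list()
  for (rn in names(regions)) {
    for (mn in names(stacks)) {
      rows[[paste(rn, mn)]] <- data.frame(
        region = rn, method = mn, metric = "CNR",
        value = cnr(stacks[[mn]], regions[[rn]]$signal, regions[[rn]]$noise))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contrast_report", class(out))
  out
}

#' Export a contrast report
#'
#' @param report a `contrast_report`.
#' @param path output path; `.csv` or `.json` chosen by extension.
#' @return `path`, invisibly.
#' @export
write_contrast_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, dataframe = "rows", digits = NA)
  } else {
    write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}
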
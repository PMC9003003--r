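test_that("snr matches its definition and signals degenerate input", {
  img <- array(0, dim = c(10, 10, 1))
  mask <- array(FALSE, dim = dim(img))
  mask[1:2, 1:2, 1] <- TRUE
  img[mask] <- 4
  img[!mask] <- rep(c(0, 2, 4, 2, 0, 2, 4, 2), length.out = sum(!mask))
  expect_equal(snr(img, mask), 4 / sd(img[!mask]))
  # signal mean zero -> SNR 0
  img2 <- img; img2[mask] <- 0
  expect_equal(snr(img2, mask), 0)
  expect_error(snr(img, array(TRUE, dim = dim(img))), "everything")
  expect_error(snr(img, array(FALSE, dim = dim(img))), "empty")
  expect_error(snr(array(1, dim = c(2, 2, 1)),
                   array(c(TRUE, FALSE), dim = c(2, 2, 1))), "zero background")
})

test_that("cnr matches its closed form", {
  set.seed(1)
  sig <- array(c(TRUE, FALSE), dim = c(20, 10, 1))
  noi <- !sig
  img <- array(0, dim = dim(sig))
  img[sig] <- 10 + rnorm(sum(sig))
  img[noi] <- rnorm(sum(noi))
  mu_s <- mean(img[sig]); mu_n <- mean(img[noi])
  expected <- (mu_s - mu_n) / sqrt(0.5 * (sd(img[sig])^2 + sd(img[noi])^2))
  expect_equal(cnr(img, sig, noi), expected)
  # equal means -> 0
  img3 <- array(rep(c(1, 2), 100), dim = c(20, 10, 1))
  expect_equal(cnr(img3, sig, sig), 0)
  # identical distributions -> near 0
  set.seed(2)
  img4 <- array(rnorm(200), dim = c(20, 10, 1))
  expect_lt(abs(cnr(img4, sig, noi)), 0.3)
})

test_that("cnr is exactly invariant under affine rescaling, snr under scaling", {
  set.seed(3)
  img <- array(runif(300, 0, 50), dim = c(10, 10, 3))
  sig <- array(FALSE, dim = dim(img)); sig[3:5, 3:5, ] <- TRUE
  noi <- !sig
  img[sig] <- img[sig] + 30
  c0 <- cnr(img, sig, noi)
  for (ab in list(c(2, 0), c(0.5, 7), c(3, -1))) {
    expect_equal(cnr(ab[1] * img + ab[2], sig, noi), c0, tolerance = 1e-12)
  }
  s0 <- snr(img, sig)
  expect_equal(snr(4 * img, sig), s0, tolerance = 1e-12)
})

test_that("groundtruth mask construction behaves on degenerate input", {
  set.seed(4)
  a <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  a[5:8, 5:8, 2] <- 6
  m_multi <- build_groundtruth_mask(list(a, a, a))
  m_single <- build_groundtruth_mask(list(a))
  expect_identical(m_multi$data, m_single$data)
  expect_warning(m0 <- build_groundtruth_mask(list(a * 0, a * 0)), "all-zero")
  expect_true(!any(m0$data))
  expect_error(build_groundtruth_mask(list(a, array(0, dim = c(2, 2, 2)))),
               "one extent")
})

test_that("groundtruth mask recovers phantom vessels (Dice >= 0.5)", {
  # consensus over the tested algorithms: enhanced stdev, enhanced
  # single-frame, and the speckle-variance baseline
  ph <- generate_phantom(small_retina_spec(seed = 5, motion = FALSE))
  st_stdev <- reslice_to_enface(composite_frames(ph$volume, "stdev"))
  st_single <- reslice_to_enface(composite_frames(ph$volume, "single"))
  sv <- reslice_to_enface(speckle_variance(ph$volume))
  cfg <- pipeline_config(rollingball_radius = 15)
  e1 <- enhance_stack(st_stdev, cfg)
  e2 <- enhance_stack(st_single, cfg)
  mask <- build_groundtruth_mask(list(e1, e2, sv))
  expect_gte(dice(mask, ph$vessel_mask), 0.5)
  # re-thresholding the binary output approximately reproduces it (the
  # low-pass erodes up to one boundary voxel per pass)
  again <- build_groundtruth_mask(list(mask$data * 1.0))
  expect_gte(dice(again, mask), 0.85)
})

test_that("stepwise_cnr reports 7 checkpoints with step-1 reference", {
  ph <- generate_phantom(small_retina_spec(seed = 6, motion = FALSE))
  sig <- ph$vessel_mask$data
  lay <- ph$layers
  tis <- array(FALSE, dim = dim(sig))
  tis[, , min(lay$y_from):max(lay$y_to)] <- TRUE
  noi <- tis & !sig
  cfg <- pipeline_config(rollingball_radius = 15)
  rep1 <- stepwise_cnr(ph$volume, cfg, sig, noi, methods = "stdev")
  expect_equal(nrow(rep1), 7)
  expect_equal(rep1$step, 1:7)
  expect_equal(rep1$pct_change[1], 0)
  # step 1 row equals cnr() of the composited, resliced input
  st <- reslice_to_enface(composite_frames(ph$volume, "stdev"))
  expect_equal(rep1$value[1], cnr(st, sig, noi))
})

test_that("plexus_cnr_report crosses methods with regions", {
  ph <- generate_phantom(small_retina_spec(seed = 7, motion = FALSE))
  regions <- phantom_plexus_regions(ph)
  stacks <- list(stdev = reslice_to_enface(composite_frames(ph$volume, "stdev")),
                 single = reslice_to_enface(composite_frames(ph$volume, "single")))
  rep1 <- plexus_cnr_report(stacks, regions)
  expect_equal(nrow(rep1), length(regions) * length(stacks))
  expect_setequal(unique(rep1$region), names(regions))
  # empty region set -> empty report
  rep0 <- plexus_cnr_report(stacks, list())
  expect_equal(nrow(rep0), 0)
})

test_that("contrast reports export to CSV and JSON", {
  df <- structure(data.frame(region = "all", method = "stdev", step = 1L,
                             metric = "CNR", value = 1.5),
                  class = c("contrast_report", "data.frame"))
  csv <- withr::local_tempfile(fileext = ".csv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_contrast_report(df, csv)
  write_contrast_report(df, jsn)
  expect_equal(read.csv(csv)$value, 1.5)
  expect_equal(jsonlite::read_json(jsn, simplifyVector = TRUE)$value, 1.5)
})
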
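test_that("phantom generation is deterministic for a fixed seed", {
  a <- generate_phantom(small_retina_spec(seed = 7))
  b <- generate_phantom(small_retina_spec(seed = 7))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$vessel_mask$data, b$vessel_mask$data)
  c2 <- generate_phantom(small_retina_spec(seed = 8))
  expect_false(identical(a$volume$data, c2$volume$data))
})

test_that("phantom does not disturb the global RNG stream", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(generate_phantom(small_retina_spec(seed = 1)))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("non-tissue RMS matches the configured value", {
  ph <- generate_phantom(small_retina_spec(seed = 2, motion = FALSE))
  lay <- ph$layers
  air <- ph$volume$data[, 1:(min(lay$y_from) - 1), , ]
  expect_lt(abs(sqrt(mean(air^2)) - 20) / 20, 0.05)
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(nt = 0), "t extent")
  expect_error(phantom_spec(breathing_rate_hz = -1), "positive")
  bad_vessels <- data.frame(plexus = "deep", y0 = 2, z0 = 10, angle_deg = 0,
                            radius = 5, intensity = 100, flow = TRUE)
  expect_error(phantom_spec(ny = 48, vessels = bad_vessels), "outside")
})

test_that("masks mark vessel and fiber voxels, fibers only superficial", {
  ph <- generate_phantom(small_retina_spec(seed = 3, motion = FALSE))
  expect_gt(sum(ph$vessel_mask$data), 0)
  expect_gt(sum(ph$fiber_mask$data), 0)
  lay <- ph$layers
  deep_rows <- lay$y_from[lay$name == "deep"]:lay$y_to[lay$name == "deep"]
  expect_true(!any(ph$fiber_mask$data[, , deep_rows]))
  # default retina spec contains a 4-voxel-diameter vessel in every plexus
  spec <- default_retina_spec()
  expect_true(all(tapply(spec$vessels$radius == 2, spec$vessels$plexus, any)))
})

test_that("frozen flow makes vessels invisible to temporal contrast", {
  ph <- generate_phantom(small_retina_spec(seed = 4, motion = FALSE,
                                           flow_decorrelation = FALSE))
  sdc <- reslice_to_enface(composite_frames(ph$volume, "stdev"))
  vm <- ph$vessel_mask$data
  lay <- ph$layers
  tis <- array(FALSE, dim = dim(vm))
  tis[, , min(lay$y_from):max(lay$y_to)] <- TRUE
  diff_means <- abs(mean(sdc$data[vm]) - mean(sdc$data[tis & !vm]))
  expect_lt(diff_means, 0.1 * ph$spec$background_rms)
  # and with decorrelation on, the separation is large
  ph2 <- generate_phantom(small_retina_spec(seed = 4, motion = FALSE))
  sdc2 <- reslice_to_enface(composite_frames(ph2$volume, "stdev"))
  expect_gt(mean(sdc2$data[vm]), mean(sdc2$data[tis & !vm]) +
              ph2$spec$background_rms)
})

test_that("vessel CNR rises monotonically with flow intensity", {
  cnrs <- vapply(c(60, 120, 220), function(intensity) {
    sp <- small_retina_spec(seed = 5, motion = FALSE, bit_depth = 16)
    sp$vessels$intensity <- intensity
    ph <- generate_phantom(sp)
    st <- reslice_to_enface(composite_frames(ph$volume, "stdev"))
    vm <- ph$vessel_mask$data
    lay <- ph$layers
    tis <- array(FALSE, dim = dim(vm))
    tis[, , min(lay$y_from):max(lay$y_to)] <- TRUE
    cnr(st, vm, tis & !vm)
  }, numeric(1))
  expect_true(all(diff(cnrs) > 0))
})

test_that("bulk motion shifts frames and registration recovers them", {
  ph <- generate_phantom(small_retina_spec(seed = 6, motion = TRUE))
  vr <- register_volume(ph$volume, "across_t")
  tr <- attr(vr, "transforms")
  expect_gt(max(abs(tr$shift_y)), 0.5)  # motion was injected and detected
  # registered frames agree better than raw frames
  raw_diff <- mean(abs(ph$volume$data[, , 2, ] - ph$volume$data[, , 1, ]))
  reg_diff <- mean(abs(vr$data[, , 2, ] - vr$data[, , 1, ]))
  expect_lt(reg_diff, raw_diff)
})

test_that("complex phantom twin matches intensity statistics", {
  ph <- generate_phantom(small_retina_spec(seed = 8, motion = FALSE,
                                           complex = TRUE))
  expect_s3_class(ph$complex_volume, "complex_volume4d")
  expect_identical(dim(ph$complex_volume$data), dim(ph$volume$data))
  # mean squared magnitude tracks the structural reflectivity scale
  lay <- ph$layers
  yy <- lay$y_from[2]:lay$y_to[2]
  inten <- Mod(ph$complex_volume$data[, yy, 1, ])^2
  expect_gt(mean(inten), 10)
})
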
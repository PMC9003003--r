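test_that("oct_volume4d enforces its invariants", {
  d <- array(0, dim = c(2, 3, 1, 2))
  expect_s3_class(oct_volume4d(d), "oct_volume4d")
  expect_error(oct_volume4d(array(0, dim = c(2, 3, 4))), "4D")
  expect_error(oct_volume4d(d - 1), "non-negative")
  expect_error(oct_volume4d(d + 300, bit_depth = 8), "bit depth")
  expect_error(oct_volume4d(d, dx = 0), "positive")
  expect_error(oct_volume4d(d, bit_depth = 12), "8 or 16")
})

test_that("reslicing is a pure permutation and an involution", {
  set.seed(1)
  v <- volume3d(array(runif(4 * 5 * 6), dim = c(4, 5, 6)))
  s <- reslice_to_enface(v)
  expect_equal(dim(s$data), c(4, 6, 5))
  # element [i, k, j] of the stack equals element [i, j, k] of the source
  for (case in list(c(1, 2, 3), c(4, 5, 6), c(2, 4, 1))) {
    expect_identical(s$data[case[1], case[3], case[2]],
                     v$data[case[1], case[2], case[3]])
  }
  # single nonzero voxel moves (1,2,3) -> (1,3,2)
  w <- volume3d(array(0, dim = c(4, 5, 6)))
  w$data[1, 2, 3] <- 9
  ws <- reslice_to_enface(w)
  expect_identical(which(ws$data != 0, arr.ind = TRUE)[1, ],
                   c(dim1 = 1L, dim2 = 3L, dim3 = 2L))
  # round trip
  expect_identical(reslice_from_enface(s)$data, v$data)
  # voxel multiset preserved
  expect_identical(sort(as.vector(s$data)), sort(as.vector(v$data)))
})

test_that("virtual B-scan reslice permutes [x,y,z] to [z,y,x]", {
  v <- volume3d(array(0, dim = c(4, 5, 6)))
  v$data[1, 2, 3] <- 7
  b <- reslice_virtual_bscan(v)
  expect_equal(dim(b), c(6, 5, 4))
  expect_identical(which(b != 0, arr.ind = TRUE)[1, ],
                   c(dim1 = 3L, dim2 = 2L, dim3 = 1L))
  # composing the two reslices is still a pure permutation of values
  s <- reslice_to_enface(v)
  expect_identical(sort(as.vector(b)), sort(as.vector(s$data)))
})

test_that("reslice extent bookkeeping matches the scan geometries", {
  v <- volume3d(array(0, dim = c(10, 12, 10)))  # stands in for 1000x1024x1000
  expect_equal(dim(reslice_to_enface(v)$data), c(10, 10, 12))
  v2 <- volume3d(array(0, dim = c(5, 12, 5)))
  expect_equal(dim(reslice_virtual_bscan(v2)), c(5, 12, 5))
})

test_that("TIFF volume round trips are bit-exact for integer data", {
  tf <- withr::local_tempfile(fileext = ".tif")
  set.seed(2)
  for (case in list(list(max = 255L, depth = 8L), list(max = 65535L, depth = 16L))) {
    d <- array(sample(0:case$max, 4 * 5 * 3 * 2, TRUE), dim = c(4, 5, 3, 2))
    v <- oct_volume4d(d, bit_depth = case$depth)
    write_stack(v, tf)
    v2 <- read_volume(tf, layout = list(n_frames_t = 3, bit_depth = case$depth))
    expect_equal(dim(v2$data), c(4, 5, 3, 2))
    expect_true(all(v$data == v2$data))
  }
  # all-zero volume
  v0 <- oct_volume4d(array(0, dim = c(3, 3, 1, 2)))
  write_stack(v0, tf)
  expect_true(all(read_volume(tf, list(n_frames_t = 1))$data == 0))
})

test_that("read_volume validates page layout", {
  tf <- withr::local_tempfile(fileext = ".tif")
  pages <- lapply(1:5, function(i) matrix(i, 3, 4))
  write_tiff_pages(pages, tf)
  expect_error(read_volume(tf, list(n_frames_t = 3)), "divisible")
  v <- read_volume(tf, list(n_frames_t = 1))
  expect_equal(dim(v$data), c(4, 3, 1, 5))
  # layout t=3 on 3 pages: single position
  write_tiff_pages(pages[1:3], tf)
  expect_equal(dim(read_volume(tf, list(n_frames_t = 3))$data), c(4, 3, 3, 1))
})

test_that("JSON sidecar supplies spacing and layout", {
  tf <- withr::local_tempfile(fileext = ".tif")
  d <- array(sample(0:255, 2 * 3 * 2 * 2, TRUE), dim = c(2, 3, 2, 2))
  v <- oct_volume4d(d, dx = 2.5, dy = 3.5, dz = 4.5)
  write_stack(v, tf)  # writes sidecar for 4D input
  v2 <- read_volume(tf)
  expect_equal(dim(v2$data), dim(v$data))
  expect_equal(v2$dx, 2.5)
  expect_equal(v2$dy, 3.5)
  expect_equal(v2$dz, 4.5)
})

test_that("complex volumes round trip through two-channel float TIFF", {
  tf <- withr::local_tempfile(fileext = ".tif")
  set.seed(3)
  cd <- array(complex(real = rnorm(60), imaginary = rnorm(60)),
              dim = c(5, 3, 2, 2))
  cv <- complex_volume4d(cd)
  write_stack(cv, tf)
  cv2 <- read_volume(tf, list(n_frames_t = 2))
  expect_s3_class(cv2, "complex_volume4d")
  expect_lt(max(Mod(cv$data - cv2$data)), 1e-5)
})

test_that("enface stacks write one page per depth slice", {
  tf <- withr::local_tempfile(fileext = ".tif")
  s <- enface_stack(array(sample(0:255, 4 * 6 * 5, TRUE), dim = c(4, 6, 5)))
  write_stack(s, tf)
  r <- read_tiff_pages(tf)
  expect_length(r$pages, 5)
  expect_equal(dim(r$pages[[1]]), c(6, 4))  # rows = z, cols = x
  expect_true(all(t(r$pages[[3]]) == s$data[, , 3]))
})
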
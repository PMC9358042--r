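test_that("MRC files round-trip through write_map/read_map", {
  set.seed(1)
  m <- density_map(array(rnorm(8 * 10 * 12), c(8, 10, 12)),
                   origin = c(-3.5, 2, 7), voxel_size = 1.1)
  f <- tempfile(fileext = ".mrc")
  write_map(m, f)
  m2 <- read_map(f)
  expect_identical(m2$dims, m$dims)
  expect_equal(m2$origin, m$origin, tolerance = 1e-5)
  expect_equal(m2$voxel_size, m$voxel_size, tolerance = 1e-6)
  # densities survive float32 storage; sums agree to relative 1e-6
  expect_lt(abs(sum(m2$values) - sum(m$values)) / abs(sum(m$values)), 1e-6)
  expect_lt(max(abs(m2$values - m$values)), 1e-5)

  cm <- density_map(array(1, c(8, 8, 8)))
  f2 <- tempfile(fileext = ".mrc")
  write_map(cm, f2)
  hdr <- readBin(f2, "integer", 3, size = 4, endian = "little")
  expect_identical(hdr, c(8L, 8L, 8L))
})

test_that("permuted axis order is normalized to the canonical layout", {
  set.seed(2)
  vals <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  m <- density_map(vals, origin = c(1, 2, 3))
  # write the same data with MAPC/MAPR/MAPS = 3,1,2 (file axes = z,x,y)
  f2 <- tempfile(fileext = ".mrc")
  con <- file(f2, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  perm_vals <- aperm(vals, c(3, 1, 2))
  wi(dim(perm_vals)); wi(2); wi(c(0, 0, 0)); wi(dim(perm_vals))
  wf(dim(perm_vals) * 1); wf(c(90, 90, 90))
  wi(c(3, 1, 2))                                  # MAPC MAPR MAPS
  wf(c(min(vals), max(vals), mean(vals))); wi(1); wi(0); wi(rep(0, 25))
  wf(c(1, 2, 3))                                  # ORIGIN (x, y, z)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(sd(vals)); wi(0); writeBin(raw(800), con)
  writeBin(as.numeric(perm_vals), con, size = 4, endian = "little")
  close(con)
  m2 <- read_map(f2)
  expect_equal(m2$values, m$values, tolerance = 1e-6)
  expect_equal(m2$origin, m$origin, tolerance = 1e-5)
})

test_that("malformed map files are rejected with format errors", {
  f <- tempfile()
  writeBin(as.raw(rep(7, 2048)), f)
  expect_error(read_map(f), class = "cryomrf_format_error")
})

test_that("simulated maps conserve mass and peak at atoms", {
  sm1 <- simulate_map(matrix(c(0, 0, 0), 1), weights = 1, resolution = 8,
                      voxel_size = 1, padding = 12)
  pk <- which(sm1$values == max(sm1$values), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk - 1L), as.integer(round((c(0, 0, 0) - sm1$origin))))
  set.seed(3)
  coords <- matrix(rnorm(25 * 3, sd = 4), 25)
  sm <- simulate_map(coords, elements = rep("C", 25), resolution = 10,
                     voxel_size = 1, padding = 20)
  expect_lt(abs(sum(sm$values) - 25 * 12.011) / (25 * 12.011), 0.01)
  # duplicating all atoms doubles the integral
  sm2 <- simulate_map(rbind(coords, coords), elements = rep("C", 50),
                      resolution = 10, voxel_size = 1, padding = 20)
  expect_equal(sum(sm2$values), 2 * sum(sm$values), tolerance = 1e-9)
  expect_error(simulate_map(matrix(numeric(0), 0, 3)),
               class = "cryomrf_empty_input_error")
})

test_that("simulated maps are equivariant to integer-voxel shifts", {
  set.seed(4)
  coords <- matrix(rnorm(10 * 3, sd = 3), 10)
  m1 <- simulate_map(coords, weights = rep(1, 10), resolution = 6,
                     voxel_size = 1, origin = c(-15, -15, -15),
                     dims = c(40, 40, 40))
  m2 <- simulate_map(sweep(coords, 2, c(3, -2, 5), "+"), weights = rep(1, 10),
                     resolution = 6, voxel_size = 1, origin = c(-15, -15, -15),
                     dims = c(40, 40, 40))
  expect_equal(m2$values[9:36, 1:30, 11:40], m1$values[6:33, 3:32, 6:35],
               tolerance = 1e-12)
})

test_that("contour masks threshold correctly and monotonically", {
  m <- density_map(array(c(0.1, 0.4, 0.9, rep(0, 5)), c(2, 2, 2)))
  expect_true(all(contour_mask(m, -1)$mask))
  expect_false(any(contour_mask(m, 2)$mask))
  msk <- contour_mask(m, 0.4)
  expect_identical(as.logical(msk$mask[1:3]), c(FALSE, TRUE, TRUE))
  counts <- vapply(seq(-0.5, 1.2, by = 0.1),
                   function(l) sum(contour_mask(m, l)$mask), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("ccc matches its closed form and is symmetric", {
  m1 <- density_map(array(c(1, 2, rep(0, 6)), c(2, 2, 2)))
  m2 <- density_map(array(c(2, 1, rep(0, 6)), c(2, 2, 2)))
  reg <- contour_mask(density_map(array(c(1, 1, rep(0, 6)), c(2, 2, 2))), 0.5)
  expect_equal(ccc(m1, m2, reg), 0.8)
  expect_equal(ccc(m2, m1, reg), ccc(m1, m2, reg))
  expect_equal(ccc(m1, m1, reg), 1.0)
  disj1 <- density_map(array(c(1, 0, rep(0, 6)), c(2, 2, 2)))
  disj2 <- density_map(array(c(0, 1, rep(0, 6)), c(2, 2, 2)))
  reg2 <- contour_mask(density_map(array(1, c(2, 2, 2))), 0.5)
  expect_equal(ccc(disj1, disj2, reg2), 0)
  zero <- density_map(array(0, c(2, 2, 2)))
  expect_error(ccc(m1, zero, reg), class = "cryomrf_undefined_score_error")
})

test_that("pccc matches its closed form and is affine invariant", {
  x <- density_map(array(c(0, 1, 2, rep(0, 5)), c(2, 2, 2)))
  y <- density_map(array(c(1, 0, 2, rep(0, 5)), c(2, 2, 2)))
  reg <- contour_mask(density_map(array(c(1, 1, 1, rep(0, 5)), c(2, 2, 2))), 0.5)
  expect_equal(pccc(x, y, reg), 0.5)
  expect_equal(pccc(y, x, reg), 0.5)
  expect_equal(pccc(x, x, reg), 1.0)
  anti <- density_map(array(c(3, 2, 1, rep(0, 5)), c(2, 2, 2)))
  expect_equal(pccc(x, anti, reg), -1.0)
  y2 <- y; y2$values <- 3 * y2$values + 7
  expect_equal(pccc(x, y2, reg), 0.5, tolerance = 1e-12)
  const <- density_map(array(1, c(2, 2, 2)))
  expect_error(pccc(x, const, reg), class = "cryomrf_undefined_score_error")
})

test_that("overlap fraction counts voxels as specified", {
  a <- array(FALSE, c(2, 2, 2))
  x <- a; x[1:5] <- TRUE
  y <- a; y[3:8] <- TRUE
  X <- structure(list(mask = x, dims = c(2, 2, 2)), class = "contour_mask")
  Y <- structure(list(mask = y, dims = c(2, 2, 2)), class = "contour_mask")
  expect_equal(overlap_fraction(X, Y), 3 / 6)
  expect_equal(overlap_fraction(Y, Y), 1.0)
  # the numerator is an integer voxel count
  expect_equal(overlap_fraction(X, Y) * sum(Y$mask), round(overlap_fraction(X, Y) * sum(Y$mask)))
  none <- structure(list(mask = a, dims = c(2, 2, 2)), class = "contour_mask")
  expect_equal(overlap_fraction(none, Y), 0)
  expect_error(overlap_fraction(X, none), class = "cryomrf_undefined_score_error")
})
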
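test_that("self-match scan returns zero shift with perfect scores", {
  set.seed(10)
  vals <- array(abs(rnorm(12^3)) + 0.1, c(12, 12, 12))
  m <- density_map(vals)
  hit <- scan_translations(m, m, "experimental")
  expect_identical(hit$shift, c(0L, 0L, 0L))
  expect_equal(hit$cc, 1, tolerance = 1e-9)
  expect_equal(hit$ov, 1)
})

test_that("a planted integer-voxel shift is recovered exactly", {
  set.seed(11)
  X <- array(0, c(20, 20, 20))
  X[5:12, 6:13, 4:11] <- abs(rnorm(512)) + 0.3
  Y <- array(X[5:12, 6:13, 4:11], c(8, 8, 8))
  for (mk in c("experimental", "simulated")) {
    hit <- scan_translations(density_map(X), density_map(Y), mk)
    expect_identical(hit$shift, c(4L, 5L, 3L))
    expect_equal(hit$ov, 1)
  }
})

test_that("FFT scan equals the naive all-shifts oracle", {
  for (tr in 1:6) {
    set.seed(tr)
    X <- density_map(array(pmax(0, rnorm(16^3, 0.2, 1)), c(16, 16, 16)))
    Y <- density_map(array(abs(rnorm(6 * 5 * 7)) + 0.1, c(6, 5, 7)))
    mk <- if (tr %% 2 == 0) "experimental" else "simulated"
    h <- scan_translations(X, Y, mk)
    nv <- naive_scan(X, Y, mk)
    expect_identical(h$shift, as.integer(nv$shift))
    expect_lt(abs(h$fit_score - nv$fit_score), 1e-6)
  }
})

test_that("oversized subunit maps raise a geometry error", {
  X <- density_map(array(1, c(8, 8, 8)))
  Y <- density_map(array(1, c(10, 8, 8)))
  expect_error(scan_translations(X, Y), class = "cryomrf_geometry_error")
})

test_that("overlap filtering keeps the inclusive boundary", {
  poses <- data.frame(ov = c(1, 0, 0.5, 0.49, 0.51), id = 1:5)
  kept <- filter_overlap(poses)
  expect_identical(kept$id, c(1L, 3L, 5L))
})

test_that("pose clustering separates centroids at the radius", {
  base <- data.frame(qw = 1, qx = 0, qy = 0, qz = 0, tx = 0, ty = 0, tz = 0,
                     cc = 0, ov = 1)
  two <- rbind(cbind(base, cx = 0, cy = 0, cz = 0, fit_score = 2),
               cbind(base, cx = 7.9, cy = 0, cz = 0, fit_score = 1))
  expect_equal(nrow(cluster_poses(two, 8)), 1)
  expect_equal(cluster_poses(two, 8)$fit_score, 2)
  two$cx[2] <- 8.1
  expect_equal(nrow(cluster_poses(two, 8)), 2)
  expect_equal(nrow(cluster_poses(two[0, ], 8)), 0)
  # idempotence and subset property
  set.seed(12)
  many <- do.call(rbind, lapply(1:30, function(i)
    cbind(base, cx = runif(1, 0, 40), cy = runif(1, 0, 40),
          cz = runif(1, 0, 40), fit_score = runif(1))))
  cl <- cluster_poses(many, 8)
  expect_true(all(cl$fit_score %in% many$fit_score))
  expect_equal(cluster_poses(cl, 8), cl, ignore_attr = TRUE)
  if (nrow(cl) > 1) {
    d <- dist(cl[, c("cx", "cy", "cz")])
    expect_gte(min(d), 8)
  }
})

make_single_subunit_case <- function(seed = 21, n_res = 15) {
  s <- make_toy_complex(2, n_res, seed = seed)[[1]]
  m <- simulate_map(cryomrf:::subunit_coords(s), elements = s$atoms$element,
                    resolution = 10, voxel_size = 1, padding = 10)
  wl <- 0.5 * 0.1 * max(m$values)
  m$values[m$values < wl] <- 0
  list(s = s, map = m)
}

test_that("search_subunit recovers a planted pose and honors the caps", {
  case <- make_single_subunit_case()
  rot <- rotation_set(40, include_identity = TRUE)
  ps <- search_subunit(case$map, case$s, rot)
  expect_s3_class(ps, "pose_set")
  expect_lte(nrow(ps$poses), 100)
  expect_true(all(ps$poses$ov >= 0.5))
  expect_true(all(diff(ps$poses$fit_score) <= 0))
  expect_equal(ps$poses$fit_score, ps$poses$cc + ps$poses$ov, tolerance = 1e-12)
  top <- ps$poses[1, ]
  # top pose within one voxel of the true placement, identity rotation
  expect_lt(sqrt(sum((c(top$cx, top$cy, top$cz) - centroid(case$s))^2)),
            sqrt(3) + 1e-9)
  expect_lt(quat_angle(c(top$qw, top$qx, top$qy, top$qz)), 1e-6)
  if (nrow(ps$poses) > 1)
    expect_gte(min(dist(ps$poses[, c("cx", "cy", "cz")])), 8)
})

test_that("search_subunit is equivariant to integer-voxel map shifts", {
  case <- make_single_subunit_case(seed = 22, n_res = 12)
  rot <- rotation_set(15, include_identity = TRUE)
  d <- case$map$dims
  sh <- c(3L, 2L, 4L)
  embed_at <- function(off) {
    big <- array(0, d + 8L)
    big[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <-
      case$map$values
    density_map(big, origin = case$map$origin, voxel_size = case$map$voxel_size)
  }
  ps1 <- search_subunit(embed_at(c(0L, 0L, 0L)), case$s, rot)
  ps2 <- search_subunit(embed_at(sh), case$s, rot)
  expect_equal(ps2$poses$cx, ps1$poses$cx + sh[1], tolerance = 1e-9)
  expect_equal(ps2$poses$cy, ps1$poses$cy + sh[2], tolerance = 1e-9)
  expect_equal(ps2$poses$cz, ps1$poses$cz + sh[3], tolerance = 1e-9)
  expect_equal(ps2$poses$fit_score, ps1$poses$fit_score, tolerance = 1e-6)
})

test_that("an empty overlap filter result names the subunit", {
  case <- make_single_subunit_case(seed = 23, n_res = 10)
  empty <- case$map
  empty$values[] <- 0
  empty$values[1, 1, 1] <- 1   # a contour far from anything fittable
  rot <- rotation_set(5)
  expect_error(search_subunit(empty, case$s, rot),
               class = "cryomrf_empty_pose_set_error")
})
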
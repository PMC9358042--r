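test_that("kabsch recovers exact superpositions", {
  set.seed(51)
  X <- matrix(rnorm(30), 10)
  fit0 <- kabsch(X, X)
  expect_lt(fit0$rmsd, 1e-9)
  expect_lt(quat_angle(fit0$transform$q), 1e-6)
  # 90-degree rotation about z
  qz <- c(cos(pi / 4), 0, 0, sin(pi / 4))
  Y <- transform_point(rigid_transform(qz, c(1, -2, 3)), X)
  fit <- kabsch(X, Y)
  expect_lt(fit$rmsd, 1e-9)
  expect_lt(quat_angle(fit$transform$q, qz), 1e-6)
  expect_error(kabsch(X, X[1:5, ]), class = "cryomrf_contract_error")
})

test_that("kabsch is optimal against random rival transforms", {
  set.seed(52)
  A <- matrix(rnorm(45), 15)
  B <- matrix(rnorm(45), 15)   # unrelated clouds: nonzero residual
  best <- kabsch(A, B)$rmsd
  for (i in 1:1000) {
    tr <- random_transform(NULL, 5)
    rival <- sqrt(mean(rowSums((transform_point(tr, A) - B)^2)))
    expect_gte(rival, best - 1e-9)
  }
})

test_that("complex RMSD is zero for identity and label swaps", {
  cx <- make_toy_complex(3, 18, seed = 53)
  expect_lt(complex_rmsd(cx, cx)$rmsd, 1e-9)
  dup <- make_toy_complex(3, 15, seed = 54, duplicate_chains = TRUE)
  swapped <- dup[c(2, 1, 3)]
  expect_lt(complex_rmsd(swapped, dup)$rmsd, 1e-9)
  # rigid motion of the whole model is absorbed by the global fit
  tr <- random_transform(55, 30)
  moved <- lapply(cx, apply_transform, transform = tr)
  expect_lt(complex_rmsd(moved, cx)$rmsd, 1e-9)
})

test_that("permutation minimum matches the all-permutations oracle", {
  for (seed in c(56, 57)) {
    dup <- make_toy_complex(4, 12, seed = seed, duplicate_chains = TRUE)
    model <- lapply(seq_along(dup), function(i)
      apply_transform(dup[[i]], random_transform(seed * 10 + i, 2)))
    model <- model[c(3, 1, 4, 2)]
    got <- complex_rmsd(model, dup)
    expect_equal(got$rmsd, brute_complex_rmsd(model, dup), tolerance = 1e-9)
    # permutation search can only improve on the identity correspondence
    id_ca_m <- do.call(rbind, lapply(model, function(s) s$calpha))
    id_ca_r <- do.call(rbind, lapply(dup, function(s) s$calpha))
    expect_lte(got$rmsd, kabsch(id_ca_m, id_ca_r)$rmsd + 1e-12)
  }
  # five identical copies still match the brute force
  dup5 <- make_toy_complex(5, 8, seed = 58, duplicate_chains = TRUE)
  model5 <- dup5[c(4, 5, 1, 3, 2)]
  expect_lt(complex_rmsd(model5, dup5)$rmsd, 1e-9)
  expect_equal(complex_rmsd(model5, dup5)$rmsd,
               brute_complex_rmsd(model5, dup5), tolerance = 1e-9)
})

test_that("mismatched sequences raise an evaluation error", {
  a <- make_toy_complex(2, 10, seed = 59)
  b <- make_toy_complex(2, 11, seed = 60)
  expect_error(complex_rmsd(a, b), class = "cryomrf_evaluation_error")
})

test_that("APS weights per-subunit deviations by residue count", {
  cx <- make_toy_complex(2, 20, seed = 61)
  self <- evaluate_assembly(cx, cx)
  expect_lt(self$rmsd, 1e-9)
  expect_lt(self$aps_shift, 1e-9)
  expect_lt(self$aps_angle, 1e-6)
  # sizes 100 and 300 residues, angles 20 and 0 degrees -> weighted mean 5
  big <- make_toy_complex(2, c(100, 300), seed = 62)
  ang <- 20 * pi / 180
  q20 <- c(cos(ang / 2), 0, 0, sin(ang / 2))
  cen <- centroid(big[[1]])
  rot_in_place <- compose_transform(
    rigid_transform(t = cen),
    compose_transform(rigid_transform(q20),
                      rigid_transform(t = -cen)))
  model <- list(apply_transform(big[[1]], rot_in_place), big[[2]])
  # supply the identity global fit: the APS definition assumes the complex
  # is already superimposed
  fit <- list(mapping = c(1L, 2L), transform = rigid_transform())
  res <- aps(model, big, fit)
  expect_equal(res$per_subunit$angle, c(20, 0), tolerance = 1e-6)
  expect_equal(res$aps_angle, (100 * 20 + 300 * 0) / 400, tolerance = 1e-6)
  expect_equal(res$aps_shift, 0, tolerance = 1e-9)
  # equal sizes, 90 and 0 degrees -> 45
  eq <- make_toy_complex(2, 50, seed = 63)
  q90 <- c(cos(pi / 4), 0, 0, sin(pi / 4))
  cen1 <- centroid(eq[[1]])
  rot90 <- compose_transform(
    rigid_transform(t = cen1),
    compose_transform(rigid_transform(q90), rigid_transform(t = -cen1)))
  model2 <- list(apply_transform(eq[[1]], rot90), eq[[2]])
  res2 <- aps(model2, eq, list(mapping = c(1L, 2L), transform = rigid_transform()))
  expect_equal(res2$aps_angle, 45, tolerance = 1e-6)
  expect_equal(res2$aps_shift, 0, tolerance = 1e-9)
})

test_that("per-subunit APS angle equals the planted rotation angle", {
  cx <- make_toy_complex(2, 25, seed = 64)
  for (theta_deg in c(10, 67.5, 140)) {
    th <- theta_deg * pi / 180
    ax <- c(1, 2, -1) / sqrt(6)
    q <- c(cos(th / 2), sin(th / 2) * ax)
    cen <- centroid(cx[[1]])
    rot <- compose_transform(
      rigid_transform(t = cen),
      compose_transform(rigid_transform(q), rigid_transform(t = -cen)))
    model <- list(apply_transform(cx[[1]], rot), cx[[2]])
    res <- aps(model, cx, list(mapping = c(1L, 2L), transform = rigid_transform()))
    expect_equal(res$per_subunit$angle[1], theta_deg, tolerance = 1e-3)
  }
})
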
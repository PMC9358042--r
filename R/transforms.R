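#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation followed by a translation,
#' `x -> R(q) x + t`. Rotations are stored as unit quaternions in
#' scalar-first order `(w, x, y, z)` with the active, right-handed
#' convention, so `quat_multiply(q1, q2)` rotates by `q2` first.
#'
#' @param q numeric length-4 unit quaternion `(w, x, y, z)`.
#' @param t numeric length-3 translation in Angstrom.
#' @return An object of class `rigid_transform` with elements `q` and `t`.
#' @examples
#' T1 <- rigid_transform(c(1, 0, 0, 0), c(1, 2, 3))
#' transform_point(T1, c(0, 0, 0))
#' @export
rigid_transform <- function(q = c(1, 0, 0, 0), t = c(0, 0, 0)) {
  q <- as.numeric(q); t <- as.numeric(t)
  stopifnot(length(q) == 4, length(t) == 3, all(is.finite(q)), all(is.finite(t)))
  n <- sqrt(sum(q^2))
  if (abs(n - 1) > 1e-9)
    stop_cryomrf("quaternion must have unit norm (|q| = ", format(n), ")",
                 class = "cryomrf_contract_error")
  structure(list(q = q / n, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> q = [", paste(signif(x$q, 5), collapse = ", "),
      "], t = [", paste(signif(x$t, 5), collapse = ", "), "] A\n")
  invisible(x)
}

#' Convert a unit quaternion to a 3x3 rotation matrix
#'
#' @param q unit quaternion `(w, x, y, z)`.
#' @return 3x3 proper rotation matrix (determinant +1).
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternion product
#'
#' `quat_multiply(q1, q2)` is the quaternion of the composed rotation
#' "apply q2, then q1": `R(q1 q2) = R(q1) R(q2)`.
#' @param q1,q2 unit quaternions `(w, x, y, z)`.
#' @return unit quaternion.
#' @export
quat_multiply <- function(q1, q2) {
  w1 <- q1[1]; x1 <- q1[2]; y1 <- q1[3]; z1 <- q1[4]
  w2 <- q2[1]; x2 <- q2[2]; y2 <- q2[3]; z2 <- q2[4]
  q <- c(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
         w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
         w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
         w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
  q / sqrt(sum(q^2))
}

quat_conjugate <- function(q) c(q[1], -q[2:4])

#' Geodesic angle between two rotations
#'
#' Rotation angle (degrees, in `[0, 180]`) of `R(q1)^T R(q2)`, i.e. the
#' angular distance on SO(3) with `q` and `-q` identified.
#' @param q1,q2 unit quaternions.
#' @return angle in degrees.
#' @export
quat_angle <- function(q1, q2 = c(1, 0, 0, 0)) {
  d <- min(1, abs(sum(q1 * q2)))
  2 * acos(d) * 180 / pi
}

#' Apply a rigid transform to points
#'
#' @param transform a `rigid_transform`.
#' @param x numeric 3-vector or an n x 3 matrix of coordinates (Angstrom).
#' @return transformed coordinates with the same shape as `x`.
#' @export
transform_point <- function(transform, x) {
  R <- quat_to_matrix(transform$q)
  if (is.matrix(x)) {
    sweep(x %*% t(R), 2, transform$t, "+")
  } else {
    as.numeric(R %*% x + transform$t)
  }
}

#' Compose two rigid transforms
#'
#' `compose_transform(T2, T1)` is "apply T1 first, then T2".
#' @param T2,T1 `rigid_transform` objects.
#' @return `rigid_transform` equal to the composition.
#' @export
compose_transform <- function(T2, T1) {
  rigid_transform(quat_multiply(T2$q, T1$q),
                  transform_point(T2, T1$t))
}

#' Invert a rigid transform
#'
#' @param transform a `rigid_transform`.
#' @return the inverse transform, `T^-1 T = identity`.
#' @export
invert_transform <- function(transform) {
  qi <- quat_conjugate(transform$q)
  rigid_transform(qi, -as.numeric(quat_to_matrix(qi) %*% transform$t))
}

#' Draw a random rigid transform
#'
#' The rotation is uniform on SO(3) (normalized 4-variate Gaussian
#' quaternion); the translation is uniform in the cube
#' `[-max_shift, max_shift]^3`. Used to scramble subunits when building
#' benchmarks.
#'
#' @param seed optional integer; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @param max_shift maximum absolute translation per axis, Angstrom.
#' @return a `rigid_transform`.
#' @export
random_transform <- function(seed = NULL, max_shift = 20) {
  stopifnot(max_shift >= 0)
  with_seed(seed, {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    t <- stats::runif(3, -max_shift, max_shift)
    rigid_transform(q, t)
  })
}

#' Serialize / deserialize rigid transforms as JSON
#'
#' Transforms are stored as `{"q": [w, x, y, z], "t": [x, y, z]}`; a list of
#' transforms becomes a JSON array.
#'
#' @param transforms a `rigid_transform` or list of them.
#' @param path file path.
#' @return `write_transforms_json` returns `path` invisibly;
#'   `read_transforms_json` returns a list of `rigid_transform`s.
#' @export
write_transforms_json <- function(transforms, path) {
  if (inherits(transforms, "rigid_transform")) transforms <- list(transforms)
  payload <- lapply(transforms, function(T) list(q = T$q, t = T$t))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transforms_json
#' @export
read_transforms_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(i)
    rigid_transform(payload$q[[i]], payload$t[[i]]))
}

# Deterministic near-uniform sampling of SO(3): super-Fibonacci spiral on
# the quaternion 3-sphere. Any requested size n gives a low-dispersion set.
super_fibonacci <- function(n) {
  phi <- sqrt(2)
  psi <- 1.533751168755204288118041  # real root of psi^4 = psi + 4
  i <- seq_len(n) - 0.5
  t <- i / n
  d <- 2 * pi * i
  r <- sqrt(t)
  R <- sqrt(1 - t)
  a <- d / phi
  b <- d / psi
  cbind(r * sin(a), r * cos(a), R * sin(b), R * cos(b))
}

#' Near-uniform rotation sampling set
#'
#' Generates a deterministic set of approximately uniformly distributed
#' rotations (unit quaternions) covering SO(3), via a super-Fibonacci
#' spiral on the quaternion sphere. The default size is 7416 orientations,
#' the sampling density used for the full pose search; smaller sets are
#' convenient for coarse searches and tests.
#'
#' `coverage_deg` is an empirical dispersion bound: the maximum geodesic
#' angle from a probe set of random rotations to its nearest set member,
#' inflated by a 25\% safety margin.
#'
#' @param n_target number of orientations (default 7416).
#' @param include_identity if `TRUE`, the first element is replaced by the
#'   identity rotation.
#' @return object of class `rotation_set`: list with `quaternions`
#'   (n x 4 matrix, rows unit, no duplicates up to sign) and `coverage_deg`.
#' @examples
#' rs <- rotation_set(60)
#' nrow(rs$quaternions)
#' @export
rotation_set <- function(n_target = 7416, include_identity = FALSE) {
  stopifnot(n_target >= 1)
  Q <- super_fibonacci(n_target)
  if (include_identity) Q[1, ] <- c(1, 0, 0, 0)
  # canonical sign (first nonzero component positive) for the duplicate check
  s <- sign(Q[, 1] + (Q[, 1] == 0) * sign(Q[, 2] + (Q[, 2] == 0)))
  Qc <- Q * s
  if (anyDuplicated(round(Qc, 12)))
    stop_cryomrf("rotation set contains duplicate orientations",
                 class = "cryomrf_internal_error")
  probes <- with_seed(194714, {
    P <- matrix(stats::rnorm(4 * 500), ncol = 4)
    P / sqrt(rowSums(P^2))
  })
  # nearest-member geodesic angle for each probe
  dots <- abs(probes %*% t(Q))
  cover <- max(2 * acos(pmin(1, apply(dots, 1, max)))) * 180 / pi
  structure(list(quaternions = Q, coverage_deg = 1.25 * cover),
            class = "rotation_set")
}

#' @export
print.rotation_set <- function(x, ...) {
  cat("<rotation_set>", nrow(x$quaternions), "orientations, coverage ~",
      signif(x$coverage_deg, 4), "deg\n")
  invisible(x)
}
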
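pad_to <- function(a, P) {
  out <- array(0, dim = P)
  d <- dim(a)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
  out
}

# Precomputed experimental-side FFTs for the translational scan. The map is
# embedded in a grid of at least `min_dims` (zero-padded, `lo_pad` voxels on
# the low side of each axis) so that any rotated subunit grid fits; the
# padded grid is then extended to FFT-friendly sizes. Because shifts are
# restricted to placements with the subunit grid fully inside the padded
# experimental grid, the circular FFT correlation is free of wrap-around.
make_scan_plan <- function(exp_map, min_dims = exp_map$dims, lo_pad = 0L) {
  nX <- exp_map$dims
  lo <- rep(as.integer(lo_pad), 3)
  target <- pmax(nX + 2L * lo, as.integer(min_dims))
  X <- array(0, target)
  X[lo[1] + seq_len(nX[1]), lo[2] + seq_len(nX[2]), lo[3] + seq_len(nX[3])] <-
    exp_map$values
  P <- vapply(target, function(n) stats::nextn(n, c(2, 3, 5)), integer(1))
  list(dims = target,
       origin = exp_map$origin - lo * exp_map$voxel_size,
       voxel = exp_map$voxel_size,
       P = P,
       FX = stats::fft(pad_to(X, P)),
       FX2 = stats::fft(pad_to(X^2, P)),
       FM = stats::fft(pad_to((X > 0) + 0, P)))
}

# index vectors that realize k -> -k (mod P) per axis, for unpacking two
# real-array spectra from one complex FFT
rev_idx <- function(n) c(1L, n:2L)

scan_with_plan <- function(plan, subunit_map, map_kind, footprint_frac) {
  nX <- plan$dims; nY <- subunit_map$dims
  if (any(nY > nX))
    stop_cryomrf("subunit map (", paste(nY, collapse = "x"),
                 ") larger than experimental map (", paste(nX, collapse = "x"), ")",
                 class = "cryomrf_geometry_error")
  if (max(abs(plan$voxel - subunit_map$voxel_size)) > 1e-6)
    stop_cryomrf("voxel sizes differ between maps", class = "cryomrf_geometry_error")
  Fmask <- subunit_map$values >= footprint_frac * max(subunit_map$values)
  nF <- sum(Fmask)
  if (nF == 0)
    stop_cryomrf("empty subunit footprint", class = "cryomrf_undefined_score_error")
  YF <- subunit_map$values * Fmask
  P <- plan$P
  # one complex FFT carries both real arrays
  Z <- stats::fft(pad_to(YF, P) + 1i * pad_to(Fmask + 0, P))
  Zr <- Conj(Z[rev_idx(P[1]), rev_idx(P[2]), rev_idx(P[3])])
  FYf <- (Z + Zr) / 2
  FFm <- (Z - Zr) / 2i
  vr1 <- seq_len(nX[1] - nY[1] + 1)
  vr2 <- seq_len(nX[2] - nY[2] + 1)
  vr3 <- seq_len(nX[3] - nY[3] + 1)
  # pack two cross-correlations per inverse FFT
  inv1 <- stats::fft(plan$FX * Conj(FYf) + 1i * (plan$FX * Conj(FFm)),
                     inverse = TRUE)[vr1, vr2, vr3, drop = FALSE] / prod(P)
  inv2 <- stats::fft(plan$FX2 * Conj(FFm) + 1i * (plan$FM * Conj(FFm)),
                     inverse = TRUE)[vr1, vr2, vr3, drop = FALSE] / prod(P)
  num <- Re(inv1)   # sum X * Y over footprint, per shift
  sx  <- Im(inv1)   # sum X over footprint
  sx2 <- Re(inv2)   # sum X^2 over footprint
  ovc <- round(Im(inv2))  # overlapping voxel count
  ov <- pmin(1, pmax(0, ovc / nF))
  sy <- sum(YF); sy2 <- sum(YF^2)
  if (map_kind == "experimental") {
    cc <- num / sqrt(pmax(sx2, 0) * sy2)
    cc[sx2 <= 0] <- -Inf
  } else {
    varx <- sx2 - sx^2 / nF
    vary <- sy2 - sy^2 / nF
    cc <- (num - sx * sy / nF) / sqrt(pmax(varx, 0) * vary)
    cc[varx <= pmax(sx2, 0) * 1e-10] <- -Inf
  }
  fit <- cc + ov
  if (!any(is.finite(fit)))
    stop_cryomrf("no shift with a defined score",
                 class = "cryomrf_undefined_score_error")
  best <- which.max(fit)   # first max in linear order: lexicographic (z, y, x)
  idx <- arrayInd(best, dim(fit))[1, ] - 1L
  list(shift = idx,
       cc = cc[best], ov = ov[best], fit_score = fit[best],
       offset = plan$origin + idx * plan$voxel - subunit_map$origin)
}

#' Best translational placement of a subunit map by FFT scan
#'
#' Scores every integer-voxel shift of `subunit_map` inside `exp_map` with
#' cross-correlation plus overlap and returns the best. All per-shift sums
#' run over the subunit footprint (the subunit map's own contour at
#' `footprint_frac` of its maximum); the experimental contour mask is taken
#' as the non-zero voxels of `exp_map`, which the caller is expected to
#' have thresholded at the working contour level. Shifts are restricted to
#' placements with the subunit grid fully inside the experimental grid, so
#' the zero-padded FFT equals a naive per-shift evaluation exactly (no
#' wrap-around aliasing).
#'
#' @param exp_map experimental `density_map`, thresholded (values below the
#'   working contour set to zero).
#' @param subunit_map simulated `density_map` of the (rotated) subunit,
#'   same voxel size as `exp_map`.
#' @param map_kind `"experimental"` scores with [ccc()], `"simulated"` with
#'   [pccc()].
#' @param footprint_frac fraction of the subunit map maximum defining its
#'   footprint.
#' @return list with `shift` (0-based voxel shift), `cc`, `ov`,
#'   `fit_score = cc + ov`, and `offset` (Angstrom translation taking the
#'   subunit-map frame into the experimental frame).
#' @export
scan_translations <- function(exp_map, subunit_map,
                              map_kind = c("simulated", "experimental"),
                              footprint_frac = 0.03) {
  map_kind <- match.arg(map_kind)
  plan <- make_scan_plan(exp_map)
  scan_with_plan(plan, subunit_map, map_kind, footprint_frac)
}

#' Drop poses with insufficient map overlap
#'
#' Keeps exactly the poses whose overlap with the experimental contour is
#' at least `min_overlap` (inclusive boundary), preserving order.
#'
#' @param poses data.frame of poses with an `ov` column.
#' @param min_overlap overlap cutoff, default 0.5.
#' @return filtered data.frame.
#' @export
filter_overlap <- function(poses, min_overlap = 0.5) {
  poses[poses$ov >= min_overlap, , drop = FALSE]
}

#' Greedy distance clustering of poses
#'
#' Poses are visited in descending `fit_score`; a pose is kept iff its
#' placed centroid is at least `radius` from every centroid already kept.
#' Output is sorted by descending `fit_score`. Ties are broken by the
#' original row order (rotation index, then scan order), so clustering is
#' deterministic. Idempotent: re-clustering a clustered set is the
#' identity.
#'
#' @param poses data.frame with columns `fit_score`, `cx`, `cy`, `cz`.
#' @param radius minimum centroid separation, Angstrom (default 8).
#' @return clustered data.frame, descending `fit_score`.
#' @export
cluster_poses <- function(poses, radius = 8) {
  if (nrow(poses) == 0) return(poses)
  ord <- order(-poses$fit_score)
  poses <- poses[ord, , drop = FALSE]
  cen <- as.matrix(poses[, c("cx", "cy", "cz")])
  keep <- logical(nrow(poses))
  kept <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(nrow(poses))) {
    if (nrow(kept) == 0 ||
        min(sqrt(rowSums(sweep(kept, 2, cen[i, ])^2))) >= radius) {
      keep[i] <- TRUE
      kept <- rbind(kept, cen[i, , drop = FALSE])
    }
  }
  poses[keep, , drop = FALSE]
}

#' Exhaustive 6D pose search for one subunit
#'
#' For every rotation in `rotations` the subunit is rotated about its
#' C-alpha centroid, rendered as a simulated map at the experimental voxel
#' size and resolution, and translationally scanned by FFT; the best shift
#' per rotation is kept. Poses with overlap below `min_overlap` are
#' dropped, the rest greedily clustered at `cluster_radius`, and up to
#' `max_poses` retained, sorted by `fit_score = cc + ov`.
#'
#' The experimental grid is transparently zero-padded so that every
#' rotation of the subunit fits; the padding never changes scores of
#' interior placements.
#'
#' @param exp_map experimental `density_map`, already thresholded at the
#'   working contour (values below it zeroed).
#' @param s a `subunit`.
#' @param rotations a `rotation_set`.
#' @param map_kind score flavor, see [scan_translations()].
#' @param resolution map resolution (kernel FWHM), Angstrom.
#' @param min_overlap overlap cutoff (default 0.5).
#' @param cluster_radius pose-cluster separation, Angstrom (default 8).
#' @param max_poses retention cap (default 100).
#' @param footprint_frac subunit footprint contour fraction.
#' @return object of class `pose_set`: list with `subunit_id` and `poses`,
#'   a data.frame with rotation index, quaternion (`qw,qx,qy,qz`),
#'   translation (`tx,ty,tz`), placed centroid (`cx,cy,cz`), `cc`, `ov`,
#'   `fit_score`.
#' @export
search_subunit <- function(exp_map, s, rotations,
                           map_kind = c("simulated", "experimental"),
                           resolution = 10, min_overlap = 0.5,
                           cluster_radius = 8, max_poses = 100,
                           footprint_frac = 0.03) {
  map_kind <- match.arg(map_kind)
  stopifnot(inherits(s, "subunit"), inherits(rotations, "rotation_set"))
  Q <- rotations$quaternions
  cen <- centroid(s)
  A <- subunit_coords(s)
  elems <- s$atoms$element
  v <- exp_map$voxel_size[1]
  sub_pad <- 0.8 * resolution
  maxrad <- max(sqrt(rowSums(sweep(A, 2, cen)^2)))
  worst_sub_dim <- as.integer(ceiling((2 * maxrad + 2 * sub_pad) / v)) + 2L
  plan <- make_scan_plan(exp_map, min_dims = rep(worst_sub_dim, 3), lo_pad = 3L)
  rows <- vector("list", nrow(Q))
  for (r in seq_len(nrow(Q))) {
    R <- quat_to_matrix(Q[r, ])
    Arot <- sweep(A, 2, cen) %*% t(R)
    sub_map <- simulate_map(Arot, elements = elems, resolution = resolution,
                            voxel_size = v, padding = sub_pad,
                            truncate_sigma = 3)
    hit <- tryCatch(scan_with_plan(plan, sub_map, map_kind, footprint_frac),
                    cryomrf_undefined_score_error = function(e) NULL)
    if (is.null(hit)) next
    # rotation is about the centroid, so the placed centroid is the offset
    rows[[r]] <- data.frame(rotation = r,
                            qw = Q[r, 1], qx = Q[r, 2], qy = Q[r, 3], qz = Q[r, 4],
                            tx = hit$offset[1] - sum(R[1, ] * cen),
                            ty = hit$offset[2] - sum(R[2, ] * cen),
                            tz = hit$offset[3] - sum(R[3, ] * cen),
                            cx = hit$offset[1], cy = hit$offset[2], cz = hit$offset[3],
                            cc = hit$cc, ov = hit$ov, fit_score = hit$fit_score)
  }
  poses <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(poses) || nrow(poses) == 0)
    stop_cryomrf("no candidate poses for subunit ", s$id,
                 class = "cryomrf_empty_pose_set_error")
  poses <- filter_overlap(poses, min_overlap)
  if (nrow(poses) == 0)
    stop_cryomrf("no pose of subunit ", s$id, " overlaps the map by at least ",
                 min_overlap, class = "cryomrf_empty_pose_set_error")
  poses <- cluster_poses(poses, cluster_radius)
  poses <- utils::head(poses, max_poses)
  rownames(poses) <- NULL
  structure(list(subunit_id = s$id, poses = poses), class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat("<pose_set>", x$subunit_id, "-", nrow(x$poses), "poses, best fit",
      signif(x$poses$fit_score[1], 5), "\n")
  invisible(x)
}

#' Rigid transform of one pose row
#'
#' @param pose_set a `pose_set`.
#' @param i pose row index.
#' @return `rigid_transform` placing the subunit.
#' @export
pose_transform <- function(pose_set, i) {
  p <- pose_set$poses[i, ]
  rigid_transform(c(p$qw, p$qx, p$qy, p$qz), c(p$tx, p$ty, p$tz))
}
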
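# rotation matrix -> unit quaternion (scalar first), Shepperd's method
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  q / sqrt(sum(q^2))
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares optimal proper rotation and translation taking `moving`
#' onto `fixed`, via SVD of the covariance matrix with the determinant
#' correction that excludes reflections.
#'
#' @param moving,fixed n x 3 coordinate matrices with matched rows, n >= 3.
#' @return list with `transform` (a `rigid_transform`) and `rmsd`, the
#'   post-fit residual in Angstrom.
#' @export
kabsch <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!identical(dim(moving), dim(fixed)) || nrow(moving) < 3)
    stop_cryomrf("kabsch needs two equal-size coordinate sets of >= 3 points",
                 class = "cryomrf_contract_error")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  M <- sweep(moving, 2, cm); F <- sweep(fixed, 2, cf)
  H <- crossprod(M, F)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cf - as.numeric(R %*% cm)
  fitted <- sweep(M %*% t(R), 2, cf, "+")
  rmsd <- sqrt(mean(rowSums((fitted - fixed)^2)))
  list(transform = rigid_transform(matrix_to_quat(R), t), rmsd = rmsd)
}

# all permutations of 1..n as a matrix (rows), n! rows; n kept small by design
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

# enumerate chain correspondences: for each reference chain a model chain
# with identical residue sequence, permutations allowed within groups of
# sequence-identical chains
chain_correspondences <- function(model, ref) {
  mseq <- unname(vapply(model, function(s) s$sequence, character(1)))
  rseq <- unname(vapply(ref, function(s) s$sequence, character(1)))
  if (length(model) != length(ref) ||
      !identical(sort(mseq), sort(rseq)))
    stop_cryomrf("no valid chain correspondence: subunit sequences differ ",
                 "between model and reference", class = "cryomrf_evaluation_error")
  groups <- unique(rseq)
  per_group <- lapply(groups, function(g) {
    r_idx <- which(rseq == g)
    m_idx <- which(mseq == g)
    perms <- all_permutations(length(r_idx))
    lapply(seq_len(nrow(perms)), function(p) {
      m <- m_idx[perms[p, ]]
      names(m) <- r_idx
      m
    })
  })
  combos <- per_group[[1]]
  if (length(per_group) > 1) {
    for (g in 2:length(per_group)) {
      combos <- unlist(lapply(combos, function(a)
        lapply(per_group[[g]], function(b) c(a, b))), recursive = FALSE)
    }
  }
  # mapping[ref position] = model position
  lapply(combos, function(m) {
    out <- integer(length(ref))
    out[as.integer(names(m))] <- m
    out
  })
}

#' Permutation-aware complex RMSD
#'
#' C-alpha RMSD between a model assembly and a reference assembly after one
#' global rigid superposition of the whole complex. When the complex
#' contains sequence-identical chains, every permutation of model chains
#' onto reference chains within identity groups is tried (each with its own
#' global Kabsch fit) and the minimum RMSD is returned.
#'
#' @param model,ref lists of placed `subunit` objects.
#' @return list with `rmsd` (Angstrom), `mapping` (integer vector: model
#'   chain index per reference position), and `transform` (the optimal
#'   global `rigid_transform` applied to the model).
#' @export
complex_rmsd <- function(model, ref) {
  mappings <- chain_correspondences(model, ref)
  ref_ca <- do.call(rbind, lapply(ref, function(s) s$calpha))
  best <- NULL
  for (map in mappings) {
    mod_ca <- do.call(rbind, lapply(map, function(i) model[[i]]$calpha))
    if (nrow(mod_ca) != nrow(ref_ca)) next
    fit <- kabsch(mod_ca, ref_ca)
    if (is.null(best) || fit$rmsd < best$rmsd)
      best <- list(rmsd = fit$rmsd, mapping = map, transform = fit$transform)
  }
  if (is.null(best))
    stop_cryomrf("no valid chain correspondence: residue counts differ",
                 class = "cryomrf_evaluation_error")
  best
}

#' Assembly placement score
#'
#' After the global superposition found by [complex_rmsd()], each model
#' subunit is compared with its reference partner: the shift is the
#' distance between C-alpha centroids, the angle is the rotation angle (in
#' `[0, 180]` degrees) of the per-subunit optimal superposition. The APS is
#' the pair of residue-count-weighted means of shifts and angles.
#'
#' @param model,ref lists of placed `subunit` objects.
#' @param fit optional result of `complex_rmsd(model, ref)`; computed when
#'   missing.
#' @return list with `aps_shift` (Angstrom), `aps_angle` (degrees) and
#'   `per_subunit`, a data.frame of per-chain deviations.
#' @export
aps <- function(model, ref, fit = NULL) {
  if (is.null(fit)) fit <- complex_rmsd(model, ref)
  rows <- lapply(seq_along(ref), function(k) {
    m <- model[[fit$mapping[k]]]
    mca <- transform_point(fit$transform, m$calpha)
    rca <- ref[[k]]$calpha
    shift <- sqrt(sum((colMeans(mca) - colMeans(rca))^2))
    sub_fit <- kabsch(mca, rca)
    angle <- quat_angle(sub_fit$transform$q)
    data.frame(subunit = ref[[k]]$id, model_chain = m$id,
               residues = ref[[k]]$residue_count,
               shift = shift, angle = angle)
  })
  per <- do.call(rbind, rows)
  w <- per$residues
  list(aps_shift = sum(w * per$shift) / sum(w),
       aps_angle = sum(w * per$angle) / sum(w),
       per_subunit = per)
}

#' Evaluate a model assembly against a reference
#'
#' Convenience wrapper computing the permutation-aware RMSD and the APS in
#' one call.
#'
#' @param model,ref lists of placed `subunit` objects.
#' @return list with `rmsd`, `aps_shift`, `aps_angle`, `per_subunit`,
#'   `mapping`.
#' @export
evaluate_assembly <- function(model, ref) {
  fit <- complex_rmsd(model, ref)
  a <- aps(model, ref, fit)
  list(rmsd = fit$rmsd, aps_shift = a$aps_shift, aps_angle = a$aps_angle,
       per_subunit = a$per_subunit, mapping = fit$mapping)
}
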
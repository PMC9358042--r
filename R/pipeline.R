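#' Pipeline configuration
#'
#' All tunable constants of the fitting pipeline in one flat list, with the
#' method's defaults: 50\% overlap cutoff, 8 Angstrom pose clustering, 100
#' retained poses per subunit, log-linear weights (0.5, 0.9, 1.0, 0.8),
#' K = 10 returned models, working contour at 0.5 times the recommended
#' contour level, 7416-orientation rotation sampling.
#'
#' @param map_kind `"simulated"` (Pearson correlation) or `"experimental"`
#'   (plain cross-correlation).
#' @param resolution map resolution (kernel FWHM), Angstrom.
#' @param contour_factor working contour = `contour_factor` x recommended
#'   level.
#' @param recommended_level depositor-recommended contour level; `NULL`
#'   means use a synthetic convention of 10\% of the map maximum.
#' @param n_rotations rotation sampling size when `rotations` is `NULL`.
#' @param rotations optional `rotation_set` overriding `n_rotations`.
#' @param extra_rotations optional matrix of quaternions appended to the
#'   rotation set (e.g. planted rotations in benchmarks).
#' @param min_overlap overlap cutoff (inclusive).
#' @param cluster_radius pose-cluster separation, Angstrom.
#' @param max_poses retained poses per subunit.
#' @param footprint_frac subunit footprint contour fraction.
#' @param weights an `mrf_weights`.
#' @param K number of output assemblies.
#' @param interaction_cutoff pair-score cutoff, Angstrom.
#' @param clash_cutoff clash distance, Angstrom.
#' @param clash_fraction significant-clash threshold fraction.
#' @param verbose log stage progress to stderr.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(map_kind = c("simulated", "experimental"),
                            resolution = 10, contour_factor = 0.5,
                            recommended_level = NULL,
                            n_rotations = 7416, rotations = NULL,
                            extra_rotations = NULL,
                            min_overlap = 0.5, cluster_radius = 8,
                            max_poses = 100, footprint_frac = 0.03,
                            weights = mrf_weights(), K = 10,
                            interaction_cutoff = 10, clash_cutoff = 3.0,
                            clash_fraction = 0.1, verbose = FALSE) {
  structure(list(map_kind = match.arg(map_kind), resolution = resolution,
                 contour_factor = contour_factor,
                 recommended_level = recommended_level,
                 n_rotations = n_rotations, rotations = rotations,
                 extra_rotations = extra_rotations,
                 min_overlap = min_overlap, cluster_radius = cluster_radius,
                 max_poses = max_poses, footprint_frac = footprint_frac,
                 weights = weights, K = K,
                 interaction_cutoff = interaction_cutoff,
                 clash_cutoff = clash_cutoff, clash_fraction = clash_fraction,
                 verbose = verbose),
            class = "pipeline_config")
}

pipe_log <- function(config, ...) {
  if (isTRUE(config$verbose)) message("[cryomrf] ", ...)
}

# placed coordinates of subunit atoms under one pose row
pose_coords <- function(A, cen, pose) {
  R <- quat_to_matrix(c(pose$qw, pose$qx, pose$qy, pose$qz))
  sweep(sweep(A, 2, cen) %*% t(R), 2, c(pose$cx, pose$cy, pose$cz), "+")
}

#' Pairwise interaction tables between two pose sets
#'
#' Scores every pose pair of two subunits, with a bounding-sphere prefilter:
#' pose pairs whose centroids are farther apart than the sum of subunit
#' radii plus the cutoff get the exact all-zero score without atom work.
#'
#' @param sa,sb `subunit` objects.
#' @param psa,psb their `pose_set`s.
#' @param cutoff interaction cutoff, Angstrom.
#' @param clash_cutoff clash distance, Angstrom.
#' @return list of matrices `f_ph` and `f_cl` (rows: poses of `sa`).
#' @export
pair_score_tables <- function(sa, sb, psa, psb, cutoff = 10, clash_cutoff = 3.0) {
  pa <- interaction_props(sa); pb <- interaction_props(sb)
  A <- subunit_coords(sa); B <- subunit_coords(sb)
  ca <- centroid(sa); cb <- centroid(sb)
  ra <- max(sqrt(rowSums(sweep(A, 2, ca)^2)))
  rb <- max(sqrt(rowSums(sweep(B, 2, cb)^2)))
  na <- nrow(psa$poses); nb <- nrow(psb$poses)
  f_ph <- matrix(0, na, nb); f_cl <- matrix(0, na, nb)
  coords_a <- lapply(seq_len(na), function(i) pose_coords(A, ca, psa$poses[i, ]))
  coords_b <- lapply(seq_len(nb), function(j) pose_coords(B, cb, psb$poses[j, ]))
  cen_a <- as.matrix(psa$poses[, c("cx", "cy", "cz")])
  cen_b <- as.matrix(psb$poses[, c("cx", "cy", "cz")])
  dcen <- sqrt(cross_dist2(cen_a, cen_b))
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (dcen[i, j] > ra + rb + cutoff) next
    sc <- score_pair_coords(coords_a[[i]], coords_b[[j]], pa, pb,
                            cutoff = cutoff, clash_cutoff = clash_cutoff)
    f_ph[i, j] <- sc$f_ph
    f_cl[i, j] <- sc$f_cl
  }
  list(f_ph = f_ph, f_cl = f_cl)
}

#' Run the full fitting pipeline
#'
#' Exhaustive per-subunit 6D pose search, pairwise interaction scoring,
#' Markov-random-field construction, single-pass max-sum belief
#' propagation, and best-first top-K assembly extraction with a final clash
#' check. When a reference assembly is supplied each returned model is also
#' evaluated (permutation-aware RMSD and APS).
#'
#' @param map experimental or simulated `density_map` of the whole complex.
#' @param subunits named list of `subunit` objects (arbitrary initial
#'   placement; the search is global).
#' @param config a [pipeline_config()].
#' @param reference optional named list of placed `subunit`s for evaluation.
#' @return object of class `fit_result`: `models` (ranked list; each has
#'   `assignment`, exact `energy`, `rank`, per-subunit `transforms`, placed
#'   `subunits`, and `eval` when a reference was given), plus `pose_sets`,
#'   `graph`, `beliefs`, `config`.
#' @export
run_pipeline <- function(map, subunits, config = pipeline_config(),
                         reference = NULL) {
  stopifnot(inherits(map, "density_map"), length(subunits) >= 1)
  rl <- config$recommended_level %||% (0.1 * max(map$values))
  wl <- config$contour_factor * rl
  work <- map
  work$values[work$values < wl] <- 0
  rot <- config$rotations %||% rotation_set(config$n_rotations)
  if (!is.null(config$extra_rotations))
    rot$quaternions <- rbind(rot$quaternions, config$extra_rotations)
  pipe_log(config, "pose search over ", nrow(rot$quaternions),
           " rotations, working contour ", signif(wl, 4))
  pose_sets <- lapply(subunits, function(s) {
    ps <- search_subunit(work, s, rot, map_kind = config$map_kind,
                         resolution = config$resolution,
                         min_overlap = config$min_overlap,
                         cluster_radius = config$cluster_radius,
                         max_poses = config$max_poses,
                         footprint_frac = config$footprint_frac)
    pipe_log(config, "subunit ", s$id, ": ", nrow(ps$poses),
             " poses retained, best fit ", signif(ps$poses$fit_score[1], 5))
    ps
  })
  n <- length(subunits)
  node_energies <- lapply(pose_sets, function(ps)
    node_energy(ps$poses, config$weights))
  edge_tables <- list()
  cl_tables <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      tabs <- pair_score_tables(subunits[[i]], subunits[[j]],
                                pose_sets[[i]], pose_sets[[j]],
                                cutoff = config$interaction_cutoff,
                                clash_cutoff = config$clash_cutoff)
      key <- edge_key(i, j)
      edge_tables[[key]] <- config$weights$w_ph * tabs$f_ph +
                            config$weights$w_cl * tabs$f_cl
      cl_tables[[key]] <- tabs$f_cl
      pipe_log(config, "pair ", names(subunits)[i], "-", names(subunits)[j],
               ": ", sum(tabs$f_ph != 0), " interacting pose pairs")
    }
  }
  graph <- mrf_graph(node_energies, edge_tables, config$weights)
  beliefs <- run_max_sum(graph)
  total_atoms <- sum(vapply(subunits, function(s) nrow(s$atoms), numeric(1)))
  clash_filter <- NULL
  if (n >= 2) {
    clash_filter <- function(assignment) {
      total <- 0
      for (key in names(cl_tables)) {
        ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
        total <- total + cl_tables[[key]][assignment[ij[1]], assignment[ij[2]]]
      }
      total > config$clash_fraction * total_atoms
    }
  }
  pipe_log(config, "extracting top ", config$K, " assemblies")
  models <- extract_top_k(graph, beliefs, K = config$K,
                          clash_filter = clash_filter)
  models <- lapply(models, function(m) {
    m$transforms <- lapply(seq_len(n), function(i)
      pose_transform(pose_sets[[i]], m$assignment[i]))
    names(m$transforms) <- names(subunits)
    m$subunits <- mapply(apply_transform, subunits, m$transforms,
                         SIMPLIFY = FALSE)
    if (!is.null(reference)) m$eval <- evaluate_assembly(m$subunits, reference)
    m
  })
  structure(list(models = models, pose_sets = pose_sets, graph = graph,
                 beliefs = beliefs, config = config,
                 working_level = wl),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", length(x$models), "ranked assemblies\n")
  for (m in x$models) {
    cat(sprintf("  rank %2d  energy %10.4f", m$rank, m$energy))
    if (!is.null(m$eval))
      cat(sprintf("  RMSD %6.2f A  APS (%.2f A, %.2f deg)",
                  m$eval$rmsd, m$eval$aps_shift, m$eval$aps_angle))
    cat("\n")
  }
  invisible(x)
}

#' Write a pose set as TSV
#'
#' @param pose_set a `pose_set`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_pose_set <- function(pose_set, path) {
  df <- cbind(subunit_id = pose_set$subunit_id, pose_set$poses)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ranked models as TSV
#'
#' One row per model: rank, exact energy, pose assignment, and evaluation
#' metrics when present.
#'
#' @param result a `fit_result`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_models <- function(result, path) {
  rows <- lapply(result$models, function(m) {
    r <- data.frame(rank = m$rank, energy = m$energy,
                    assignment = paste(m$assignment, collapse = ","))
    if (!is.null(m$eval)) {
      r$rmsd <- m$eval$rmsd
      r$aps_shift <- m$eval$aps_shift
      r$aps_angle <- m$eval$aps_angle
    }
    r
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
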
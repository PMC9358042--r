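# Residue name pool for pseudo-proteins; includes charged side chains so the
# electrostatic term is exercised.
.toy_residues <- c("ALA", "LEU", "SER", "THR", "PHE", "GLY",
                   "ASP", "GLU", "LYS", "ARG", "CYS")

unit_vec <- function(v) v / sqrt(sum(v^2))
rand_unit <- function() unit_vec(stats::rnorm(3))

# Compact self-avoiding C-alpha random walk: 3.8 A steps with direction
# persistence and a pull toward the running centroid; non-adjacent C-alphas
# kept >= 4 A apart.
toy_walk <- function(n_res) {
  ca <- matrix(0, n_res, 3)
  d <- rand_unit()
  for (k in 2:n_res) {
    ok <- FALSE
    for (try in 1:60) {
      pull <- if (k > 4) unit_vec(colMeans(ca[1:(k - 1), , drop = FALSE]) - ca[k - 1, ]) else c(0, 0, 0)
      dir <- unit_vec(0.55 * d + 0.85 * rand_unit() + 0.35 * pull)
      cand <- ca[k - 1, ] + 3.8 * dir
      if (k <= 3 || min(sqrt(rowSums(sweep(ca[1:(k - 2), , drop = FALSE], 2, cand)^2))) >= 4.0) {
        ca[k, ] <- cand; d <- dir; ok <- TRUE; break
      }
    }
    if (!ok) {  # restart-free fallback: accept a straight step
      ca[k, ] <- ca[k - 1, ] + 3.8 * d
    }
  }
  ca
}

# Build one pseudo-protein subunit: backbone N, CA, O plus a CB side-chain
# atom per residue, centered at its C-alpha centroid.
toy_subunit <- function(id, n_res) {
  ca <- toy_walk(n_res)
  resid <- sample(.toy_residues, n_res, replace = TRUE)
  rows <- vector("list", n_res)
  for (k in seq_len(n_res)) {
    dprev <- if (k > 1) unit_vec(ca[k, ] - ca[k - 1, ]) else
             unit_vec(ca[k, ] - ca[min(k + 1, n_res), ] + 1e-8)
    npos <- ca[k, ] - 1.45 * dprev
    opos <- ca[k, ] + 1.25 * unit_vec(rand_unit() + 0.3 * dprev)
    cbpos <- ca[k, ] + 1.53 * rand_unit()
    rows[[k]] <- data.frame(
      name = c("N", "CA", "CB", "O"),
      element = c("N", "C", "C", "O"),
      resno = k, resid = resid[k],
      x = c(npos[1], ca[k, 1], cbpos[1], opos[1]),
      y = c(npos[2], ca[k, 2], cbpos[2], opos[2]),
      z = c(npos[3], ca[k, 3], cbpos[3], opos[3]),
      stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  cen <- colMeans(at[at$name == "CA", c("x", "y", "z")])
  at$x <- at$x - cen[1]; at$y <- at$y - cen[2]; at$z <- at$z - cen[3]
  subunit(id, at)
}

#' Generate a toy protein complex
#'
#' Builds `n_subunits` deterministic pseudo-protein chains (compact
#' self-avoiding C-alpha walks with backbone N/O and a CB pseudo side chain)
#' and packs them into mutual contact with zero inter-subunit clashes at the
#' default 3 Angstrom clash cutoff. By default chains are distinct shapes so
#' that pose recovery has a unique answer; `duplicate_chains = TRUE` makes
#' all chains copies of the first (identical sequences), exercising the
#' permutation-aware evaluation path.
#'
#' @param n_subunits number of chains, 2-7.
#' @param residues_per_subunit residues per chain (scalar or vector).
#' @param seed integer seed; the same seed gives byte-identical structures.
#' @param duplicate_chains if `TRUE` all chains share one shape and sequence.
#' @return named list of `subunit` objects (chains "A", "B", ...), placed in
#'   contact — the reference assembly.
#' @export
make_toy_complex <- function(n_subunits = 3, residues_per_subunit = 35,
                             seed = 1, duplicate_chains = FALSE) {
  stopifnot(n_subunits >= 2, n_subunits <= 7)
  n_res <- rep_len(residues_per_subunit, n_subunits)
  with_seed(seed, {
    ids <- LETTERS[seq_len(n_subunits)]
    locals <- vector("list", n_subunits)
    locals[[1]] <- toy_subunit(ids[1], n_res[1])
    for (k in 2:n_subunits) {
      locals[[k]] <- if (duplicate_chains) subunit(ids[k], locals[[1]]$atoms)
                     else toy_subunit(ids[k], n_res[k])
    }
    placed <- list(locals[[1]])
    for (k in 2:n_subunits) {
      s <- locals[[k]]
      # random orientation about its own centroid
      s <- apply_transform(s, random_transform(NULL, max_shift = 0))
      asm <- do.call(rbind, lapply(placed, subunit_coords))
      asm_cen <- colMeans(asm)
      ok <- FALSE
      for (try in 1:60) {
        u <- rand_unit()
        co <- subunit_coords(s)
        t_far <- 2 * (max(sqrt(rowSums(sweep(asm, 2, asm_cen)^2))) +
                      max(sqrt(rowSums(co^2)))) + 12
        tt <- t_far
        mind <- Inf
        while (tt > 0) {
          sh <- sweep(co, 2, asm_cen + tt * u, "+")
          mind <- sqrt(min(cross_dist2(asm, sh)))
          if (mind <= 5.0) break
          tt <- tt - max(0.25, (mind - 5.0) * 0.8)
        }
        # back off until clash-free contact
        while (tt < t_far && mind < 3.2) {
          tt <- tt + 0.25
          sh <- sweep(co, 2, asm_cen + tt * u, "+")
          mind <- sqrt(min(cross_dist2(asm, sh)))
        }
        if (mind >= 3.2 && mind <= 5.5) {
          placed[[k]] <- apply_transform(s, rigid_transform(t = asm_cen + tt * u))
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop_cryomrf("failed to pack subunit ", ids[k],
                     " after 60 attempts; try fewer or smaller subunits",
                     class = "cryomrf_generation_error")
    }
    names(placed) <- ids
    placed
  })
}

#' Build a synthetic fitting benchmark from a reference complex
#'
#' Simulates the density map of the reference assembly (Gaussian kernels,
#' default 10 Angstrom resolution and 1.0 Angstrom voxels — the simulated-map
#' convention used throughout) and independently scrambles every subunit by
#' a random rigid transform, recording the planted ground-truth transforms
#' that undo the scrambling.
#'
#' @param complex named list of placed `subunit`s (see [make_toy_complex()]).
#' @param resolution map resolution (kernel FWHM), Angstrom.
#' @param voxel_size map voxel size, Angstrom.
#' @param seed seed for the scrambling transforms.
#' @param max_shift scrambling translation bound; default half the map box
#'   diagonal, so scrambled subunits can land anywhere relevant.
#' @return object of class `toy_benchmark`: `reference`, `scrambled`,
#'   `map`, `planted` (per-subunit transforms with
#'   `planted[[k]](scrambled[[k]]) == reference[[k]]`), `scramble`,
#'   `recommended_level`, plus the generation parameters.
#' @export
make_benchmark <- function(complex, resolution = 10, voxel_size = 1.0,
                           seed = 1, max_shift = NULL) {
  coords <- do.call(rbind, lapply(complex, subunit_coords))
  elems <- unlist(lapply(complex, function(s) s$atoms$element))
  map <- simulate_map(coords, elements = elems, resolution = resolution,
                      voxel_size = voxel_size, padding = resolution)
  if (is.null(max_shift))
    max_shift <- 0.5 * sqrt(sum((map$dims * map$voxel_size)^2)) / 2
  scramble <- with_seed(seed, lapply(complex, function(s)
    random_transform(NULL, max_shift = max_shift)))
  scrambled <- mapply(apply_transform, complex, scramble, SIMPLIFY = FALSE)
  planted <- lapply(scramble, invert_transform)
  structure(list(reference = complex, scrambled = scrambled, map = map,
                 planted = planted, scramble = scramble,
                 recommended_level = 0.1 * max(map$values),
                 resolution = resolution, voxel_size = voxel_size,
                 seed = seed),
            class = "toy_benchmark")
}

#' @export
print.toy_benchmark <- function(x, ...) {
  cat("<toy_benchmark>", length(x$reference), "subunits, map",
      paste(x$map$dims, collapse = "x"), "voxels at", x$resolution,
      "A resolution\n")
  invisible(x)
}
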
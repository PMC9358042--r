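#' Score weights for the log-linear assembly energy
#'
#' The assembly energy is the weighted sum
#' `sum_i [w_cc f_cc + w_ov f_ov] + sum_(i,j) [w_ph f_ph + w_cl f_cl]`
#' with every `f` term on an energy scale (lower is better): `f_cc = -cc`,
#' `f_ov = -ov`, `f_ph` the physics interaction energy and `f_cl` the clash
#' count. The best assembly is the energy minimizer. Defaults are
#' `w_cc = 0.5, w_ov = 0.9, w_ph = 1.0, w_cl = 0.8`.
#'
#' @param w_cc,w_ov,w_ph,w_cl non-negative weights.
#' @return object of class `mrf_weights`.
#' @export
mrf_weights <- function(w_cc = 0.5, w_ov = 0.9, w_ph = 1.0, w_cl = 0.8) {
  w <- c(w_cc = w_cc, w_ov = w_ov, w_ph = w_ph, w_cl = w_cl)
  stopifnot(all(is.finite(w)), all(w >= 0))
  structure(as.list(w), class = "mrf_weights")
}

#' Node energy of a single pose
#'
#' `w_cc * (-cc) + w_ov * (-ov)`: the goodness-of-fit part of the assembly
#' energy for one placed subunit.
#'
#' @param pose list or one-row data.frame with `cc` and `ov`.
#' @param w an `mrf_weights`.
#' @return scalar energy.
#' @export
node_energy <- function(pose, w = mrf_weights()) {
  w$w_cc * (-pose$cc) + w$w_ov * (-pose$ov)
}

#' Edge energy of a pose pair
#'
#' `w_ph * f_ph + w_cl * f_cl` for one pairwise interaction.
#'
#' @param score an `interaction_score` (or any list with `f_ph`, `f_cl`).
#' @param w an `mrf_weights`.
#' @return scalar energy.
#' @export
edge_energy <- function(score, w = mrf_weights()) {
  w$w_ph * score$f_ph + w$w_cl * score$f_cl
}

#' Pairwise Markov random field over candidate poses
#'
#' Single nodes hold the candidate poses of each subunit with their node
#' energies; pairwise nodes hold, for every unordered pair of subunits, the
#' table of edge energies over pose pairs. The joint distribution
#' factorizes over node potentials `Phi(X_i) = exp(-node energy)` and edge
#' potentials `Psi(X_i, X_j) = exp(-edge energy)`; the partition function is
#' never computed since only MAP inference (energy minimization) is needed.
#'
#' @param node_energies named list, one numeric vector of per-pose node
#'   energies per subunit.
#' @param edge_tables named list of matrices; element `"i|j"` (with `i < j`
#'   positions in `node_energies`) has dims `poses_i x poses_j`.
#' @param weights the `mrf_weights` used to build the energies (metadata).
#' @return object of class `mrf_graph`.
#' @export
mrf_graph <- function(node_energies, edge_tables = list(), weights = mrf_weights()) {
  stopifnot(length(node_energies) >= 1)
  n <- length(node_energies)
  for (v in node_energies)
    if (!all(is.finite(v))) stop_cryomrf("non-finite node energy",
                                         class = "cryomrf_contract_error")
  for (nm in names(edge_tables)) {
    ij <- as.integer(strsplit(nm, "|", fixed = TRUE)[[1]])
    stopifnot(length(ij) == 2, ij[1] < ij[2], ij[2] <= n)
    tab <- edge_tables[[nm]]
    if (!identical(dim(tab), c(length(node_energies[[ij[1]]]),
                               length(node_energies[[ij[2]]]))))
      stop_cryomrf("edge table ", nm, " has wrong dims",
                   class = "cryomrf_contract_error")
    if (!all(is.finite(tab)))
      stop_cryomrf("non-finite edge energy in table ", nm,
                   class = "cryomrf_contract_error")
  }
  structure(list(node_energies = node_energies, edge_tables = edge_tables,
                 weights = weights, n = n),
            class = "mrf_graph")
}

edge_key <- function(i, j) paste0(min(i, j), "|", max(i, j))

# edge energy table oriented so rows index subunit i
edge_table_for <- function(graph, i, j) {
  tab <- graph$edge_tables[[edge_key(i, j)]]
  if (is.null(tab)) return(NULL)
  if (i < j) tab else t(tab)
}

#' Exact assembly energy of a complete assignment
#'
#' Sum of node energies plus edge energies over all pairwise tables; the
#' quantity the MAP search minimizes.
#'
#' @param assignment integer vector, one pose index per subunit.
#' @param graph an `mrf_graph`.
#' @return scalar energy.
#' @export
total_energy <- function(assignment, graph) {
  n <- graph$n
  if (length(assignment) != n || any(is.na(assignment)))
    stop_cryomrf("assignment must give one pose per subunit",
                 class = "cryomrf_contract_error")
  e <- 0
  for (i in seq_len(n)) e <- e + graph$node_energies[[i]][assignment[i]]
  for (nm in names(graph$edge_tables)) {
    ij <- as.integer(strsplit(nm, "|", fixed = TRUE)[[1]])
    e <- e + graph$edge_tables[[nm]][assignment[ij[1]], assignment[ij[2]]]
  }
  e
}

#' Single-pass max-sum (min-sum) belief propagation
#'
#' Initial beliefs of a single node are its per-pose node energies. In
#' phase one every single node sends its beliefs to the incident pairwise
#' nodes; in phase two every pairwise node `(i, j)` sends to node `i`, for
#' each pose of `i`, the minimum over poses of `j` of (edge energy + `j`'s
#' initial belief) — min-sum on energies is max-sum on scores. Final
#' beliefs are initial beliefs plus all incoming messages. One pass, no
#' iteration; exact for two subunits, a heuristic lower-bound guide for
#' more.
#'
#' @param graph an `mrf_graph`.
#' @return object of class `belief_state`: lists `initial` and `final` of
#'   per-subunit numeric vectors.
#' @export
run_max_sum <- function(graph) {
  n <- graph$n
  for (i in seq_len(n))
    if (length(graph$node_energies[[i]]) == 0)
      stop_cryomrf("subunit ", names(graph$node_energies)[i] %||% i,
                   " has an empty pose set", class = "cryomrf_inference_error")
  initial <- graph$node_energies
  final <- initial
  for (nm in names(graph$edge_tables)) {
    ij <- as.integer(strsplit(nm, "|", fixed = TRUE)[[1]])
    i <- ij[1]; j <- ij[2]
    tab <- graph$edge_tables[[nm]]
    # message to i: per pose of i, best compatible pose of j
    final[[i]] <- final[[i]] + apply(sweep(tab, 2, initial[[j]], "+"), 1, min)
    final[[j]] <- final[[j]] + apply(sweep(tab, 1, initial[[i]], "+"), 2, min)
  }
  structure(list(initial = initial, final = final), class = "belief_state")
}

# Admissible lower bound on completing a partial assignment (subunits
# 1..k assigned). Each unassigned subunit contributes the minimum over its
# poses of: node energy + edges to assigned subunits + row-minima of edges
# to later unassigned subunits (each unassigned-unassigned edge counted at
# its lower endpoint). Independent minima never exceed the joint minimum,
# so best-first search with this bound emits complete assignments in exact
# energy order.
completion_bound <- function(graph, assignment, k) {
  n <- graph$n
  if (k == n) return(0)
  h <- 0
  for (u in (k + 1):n) {
    vec <- graph$node_energies[[u]]
    for (a in seq_len(k)) {
      tab <- edge_table_for(graph, u, a)
      if (!is.null(tab)) vec <- vec + tab[, assignment[a]]
    }
    if (u < n) for (u2 in (u + 1):n) {
      tab <- edge_table_for(graph, u, u2)
      if (!is.null(tab)) vec <- vec + apply(tab, 1, min)
    }
    h <- h + min(vec)
  }
  h
}

#' Extract the top-K assemblies by best-first heap search
#'
#' Best-first (A*-style) search over partial pose assignments: a min-heap
#' is keyed by the exact energy of the assigned part plus an admissible
#' lower bound on the remainder, so complete assignments are emitted in
#' exact nondecreasing energy order — the output provably equals the
#' enumeration top-K. Beliefs from [run_max_sum()] may be supplied to order
#' subunit expansion (most discriminating first); they never affect
#' correctness. Models failing the clash filter are discarded and the
#' search continues until `K` survivors or exhaustion.
#'
#' Ties in energy are broken by lexicographic pose-index order.
#'
#' @param graph an `mrf_graph`.
#' @param beliefs optional `belief_state` (expansion-order hint).
#' @param K number of models to return (default 10).
#' @param clash_filter optional `function(assignment) -> logical`; `TRUE`
#'   means the model is discarded as clashing.
#' @return list of `assembly_model` objects (assignment, exact `energy`,
#'   `rank`), at most `K`, ordered by energy.
#' @export
extract_top_k <- function(graph, beliefs = NULL, K = 10, clash_filter = NULL) {
  n <- graph$n
  stopifnot(K >= 1)
  for (i in seq_len(n))
    if (length(graph$node_energies[[i]]) == 0)
      stop_cryomrf("subunit ", names(graph$node_energies)[i] %||% i,
                   " has an empty pose set", class = "cryomrf_inference_error")
  # expansion order: keep natural order (deterministic); beliefs reserved
  # as a hint do not change the admissibility of the bound
  h <- heap_new()
  tie_of <- function(a) paste(sprintf("%06d", a), collapse = ",")
  root_bound <- completion_bound(graph, integer(0), 0)
  heap_push(h, root_bound, "", list(assign = integer(0), g = 0))
  out <- list()
  rank <- 0L
  while (heap_size(h) > 0 && rank < K) {
    nd <- heap_pop(h)
    k <- length(nd$val$assign)
    if (k == n) {
      if (!is.null(clash_filter) && isTRUE(clash_filter(nd$val$assign))) next
      rank <- rank + 1L
      out[[rank]] <- structure(list(assignment = nd$val$assign,
                                    energy = nd$val$g, rank = rank),
                               class = "assembly_model")
      next
    }
    u <- k + 1L
    npose <- length(graph$node_energies[[u]])
    for (p in seq_len(npose)) {
      a2 <- c(nd$val$assign, p)
      g2 <- nd$val$g + graph$node_energies[[u]][p]
      for (a in seq_len(k)) {
        tab <- edge_table_for(graph, u, a)
        if (!is.null(tab)) g2 <- g2 + tab[p, a2[a]]
      }
      f2 <- g2 + completion_bound(graph, a2, u)
      heap_push(h, f2, tie_of(a2), list(assign = a2, g = g2))
    }
  }
  if (length(out) == 0)
    stop_cryomrf("no valid (clash-free) models found",
                 class = "cryomrf_no_valid_models_error")
  out
}

#' @export
print.assembly_model <- function(x, ...) {
  cat("<assembly_model> rank", x$rank, "energy", signif(x$energy, 6),
      "assignment [", paste(x$assignment, collapse = ", "), "]\n")
  invisible(x)
}
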
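# Element codes and pair parameter tables for the interaction score.
# Element-level Lennard-Jones parameters (r_min contribution in Angstrom,
# well depth in kcal/mol-like units); values are generic heavy-atom radii.
.elem_codes <- c(C = 1L, N = 2L, O = 3L, S = 4L)
.lj_rhalf <- c(1.90, 1.80, 1.70, 2.00, 1.85)   # C N O S other
.lj_eps   <- c(0.12, 0.16, 0.20, 0.25, 0.15)

elem_code <- function(element) {
  code <- .elem_codes[toupper(element)]
  code[is.na(code)] <- 5L
  unname(code)
}

# Residue-level partial charges: charged side chains carry +-1 split over
# their terminal atoms; all other atoms are neutral. Pseudo-proteins whose
# side chain is a single CB atom get the full charge on CB.
.charge_atoms <- list(
  ASP = c(OD1 = -0.5, OD2 = -0.5), GLU = c(OE1 = -0.5, OE2 = -0.5),
  LYS = c(NZ = 1), ARG = c(NH1 = 0.5, NH2 = 0.5)
)
.residue_charge <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1)

atom_charges <- function(atoms) {
  q <- numeric(nrow(atoms))
  for (res in unique(atoms$resno[atoms$resid %in% names(.residue_charge)])) {
    sel <- atoms$resno == res
    resid <- atoms$resid[sel][1]
    tab <- .charge_atoms[[resid]]
    hit <- sel & atoms$name %in% names(tab)
    if (any(hit)) {
      q[hit] <- tab[atoms$name[hit]]
    } else {
      cb <- sel & atoms$name == "CB"
      if (any(cb)) q[which(cb)[1]] <- .residue_charge[resid]
    }
  }
  q
}

# Per-subunit cached scoring properties, computed once per subunit.
interaction_props <- function(s) {
  at <- s$atoms
  code <- elem_code(at$element)
  list(code = code,
       charge = atom_charges(at),
       is_sg = at$name == "SG" & code == 4L,
       rhalf = .lj_rhalf[code],
       eps = .lj_eps[code])
}

#' Count steric clashes between two atom sets
#'
#' Number of cross pairs of heavy atoms closer than `cutoff`.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices, Angstrom.
#' @param cutoff clash distance, Angstrom (default 3.0).
#' @return integer count (symmetric in its arguments).
#' @export
clash_count <- function(coords_a, coords_b, cutoff = 3.0) {
  d2 <- cross_dist2(as.matrix(coords_a), as.matrix(coords_b))
  sum(d2 < cutoff^2)
}

cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Core scorer on raw coordinates + cached properties. Terms:
#  - vdw: Lennard-Jones 12-6 in r_min form, eps*((rm/r)^12 - 2 (rm/r)^6),
#    pairwise r_min = sum of element radii, eps = geometric mean; soft-core
#    cap at +10 per pair so overlapping atoms stay finite.
#  - elec: Coulomb with distance-dependent dielectric eps(r) = 4r,
#    E = 332.0636 q_i q_j / (4 r^2), r floored at 1 Angstrom.
#  - hbond_ss: donor-acceptor N...O pairs in 2.6-3.5 A contribute -1 each;
#    disulfide SG...SG pairs in 1.8-2.4 A contribute -2 each. No angular term.
#  - solvation: contact approximation below 5 A; hydrophobic-hydrophobic
#    (C-C) contacts rewarded -0.03, polar-against-hydrophobic burial
#    penalized +0.02.
# All terms are exactly zero for atom pairs beyond `cutoff`.
score_pair_coords <- function(A, B, pa, pb, cutoff = 10, clash_cutoff = 3.0,
                              vdw_cap = 10) {
  d2 <- cross_dist2(A, B)
  na <- nrow(A)
  sel <- which(d2 <= cutoff^2)
  clashes <- sum(d2 < clash_cutoff^2)
  if (length(sel) == 0) {
    return(interaction_score(0, 0, 0, 0, clashes))
  }
  ia <- (sel - 1L) %% na + 1L
  ib <- (sel - 1L) %/% na + 1L
  r <- sqrt(d2[sel])
  rm <- pa$rhalf[ia] + pb$rhalf[ib]
  eps <- sqrt(pa$eps[ia] * pb$eps[ib])
  sr6 <- (rm / r)^6
  vdw <- sum(pmin(eps * (sr6^2 - 2 * sr6), vdw_cap))
  qq <- pa$charge[ia] * pb$charge[ib]
  rel <- pmax(r, 1)
  elec <- sum(332.0636 * qq / (4 * rel^2))
  hb <- -sum((pa$code[ia] == 2L & pb$code[ib] == 3L |
              pa$code[ia] == 3L & pb$code[ib] == 2L) & r >= 2.6 & r <= 3.5)
  ss <- -2 * sum(pa$is_sg[ia] & pb$is_sg[ib] & r >= 1.8 & r <= 2.4)
  contact <- r < 5
  cc_pair <- pa$code[ia] == 1L & pb$code[ib] == 1L
  polar_a <- pa$code[ia] %in% c(2L, 3L); polar_b <- pb$code[ib] %in% c(2L, 3L)
  mixed <- (polar_a & pb$code[ib] == 1L) | (pa$code[ia] == 1L & polar_b)
  solv <- -0.03 * sum(contact & cc_pair) + 0.02 * sum(contact & mixed)
  interaction_score(vdw, elec, hb + ss, solv, clashes)
}

#' Interaction score container
#'
#' @param vdw,elec,hbond_ss,solvation energy-like terms (lower is better).
#' @param clash_count non-negative integer clash count.
#' @return object of class `interaction_score` with the four terms,
#'   `clash_count`, the combined physics energy `f_ph` (their unweighted
#'   sum) and the clash penalty `f_cl` (= `clash_count`).
#' @export
interaction_score <- function(vdw, elec, hbond_ss, solvation, clash_count) {
  structure(list(vdw = vdw, elec = elec, hbond_ss = hbond_ss,
                 solvation = solvation, clash_count = as.integer(clash_count),
                 f_ph = vdw + elec + hbond_ss + solvation,
                 f_cl = as.numeric(clash_count)),
            class = "interaction_score")
}

#' @export
print.interaction_score <- function(x, ...) {
  cat("<interaction_score> vdw", signif(x$vdw, 4), "elec", signif(x$elec, 4),
      "hbond/ss", x$hbond_ss, "solv", signif(x$solvation, 4),
      "clashes", x$clash_count, "-> f_ph", signif(x$f_ph, 5), "\n")
  invisible(x)
}

#' Physics-based interaction score between two placed subunits
#'
#' Scores the interface between two subunits with a docking-style energy:
#' van der Waals, electrostatics, hydrogen/disulfide bonds and solvation
#' (combined into `f_ph`), plus the steric clash count (`f_cl`). The score
#' is symmetric, invariant to a common rigid motion of both subunits, and
#' exactly zero (all terms) when the minimum heavy-atom distance exceeds
#' `cutoff`.
#'
#' @param a,b placed `subunit` objects with distinct ids.
#' @param cutoff interaction cutoff, Angstrom (default 10).
#' @param clash_cutoff clash distance, Angstrom (default 3.0).
#' @return an `interaction_score`.
#' @export
pair_score <- function(a, b, cutoff = 10, clash_cutoff = 3.0) {
  stopifnot(inherits(a, "subunit"), inherits(b, "subunit"))
  if (identical(a$id, b$id))
    stop_cryomrf("pair_score requires two distinct subunits (both are '",
                 a$id, "')", class = "cryomrf_contract_error")
  score_pair_coords(subunit_coords(a), subunit_coords(b),
                    interaction_props(a), interaction_props(b),
                    cutoff = cutoff, clash_cutoff = clash_cutoff)
}

#' Does an assembly have a significant amount of clashes?
#'
#' `TRUE` iff the total cross-subunit clash count over all pairs exceeds
#' `threshold_fraction` times the total number of heavy atoms in the
#' assembly. Used to discard physically impossible assemblies.
#'
#' @param placed_subunits list of placed `subunit` objects.
#' @param threshold_fraction clash tolerance as a fraction of the atom count
#'   (default 0.1).
#' @param clash_cutoff clash distance, Angstrom.
#' @return logical.
#' @export
significant_clash <- function(placed_subunits, threshold_fraction = 0.1,
                              clash_cutoff = 3.0) {
  n <- length(placed_subunits)
  total_atoms <- sum(vapply(placed_subunits, function(s) nrow(s$atoms), numeric(1)))
  if (!is.finite(threshold_fraction)) return(FALSE)
  total <- 0
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      total <- total + clash_count(subunit_coords(placed_subunits[[i]]),
                                   subunit_coords(placed_subunits[[j]]),
                                   clash_cutoff)
    }
  }
  total > threshold_fraction * total_atoms
}
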
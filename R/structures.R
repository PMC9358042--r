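#' Subunit container
#'
#' One rigid protein chain: a table of heavy atoms plus cached C-alpha
#' coordinates. Hydrogens are never stored. The subunit "center" used for
#' pose clustering and placement bookkeeping is the unweighted C-alpha
#' centroid.
#'
#' @param id chain label.
#' @param atoms data.frame with columns `name` (atom name, e.g. "CA"),
#'   `element`, `resno` (residue index), `resid` (3-letter residue name),
#'   `x`, `y`, `z` (Angstrom).
#' @return object of class `subunit` with fields `id`, `atoms`,
#'   `residue_count`, `calpha` (matrix), `sequence` (residue-name string).
#' @export
subunit <- function(id, atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "element", "resno", "resid", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop_cryomrf("non-finite atom coordinates in subunit ", id,
                 class = "cryomrf_input_error")
  ca <- atoms[atoms$name == "CA", , drop = FALSE]
  if (nrow(ca) == 0)
    stop_cryomrf("subunit ", id, " has no C-alpha atoms",
                 class = "cryomrf_input_error")
  ca <- ca[order(ca$resno), , drop = FALSE]
  structure(list(
    id = as.character(id),
    atoms = atoms,
    residue_count = length(unique(atoms$resno)),
    calpha = unname(as.matrix(ca[, c("x", "y", "z")])),
    sequence = paste(ca$resid, collapse = "-")
  ), class = "subunit")
}

#' @export
print.subunit <- function(x, ...) {
  cat("<subunit>", x$id, "-", x$residue_count, "residues,",
      nrow(x$atoms), "heavy atoms\n")
  invisible(x)
}

subunit_coords <- function(s) unname(as.matrix(s$atoms[, c("x", "y", "z")]))

#' C-alpha centroid of a subunit
#'
#' @param s a `subunit`.
#' @return length-3 numeric, Angstrom.
#' @export
centroid <- function(s) colMeans(s$calpha)

#' Read subunits from a PDB file
#'
#' One subunit per chain. Hydrogens are dropped; for alternate locations the
#' highest-occupancy conformer is kept. Chains without C-alpha atoms are
#' skipped with a warning.
#'
#' @param path PDB file.
#' @return named list of `subunit` objects.
#' @export
read_structure <- function(path) {
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path)),
                  error = function(e) stop_cryomrf("cannot parse PDB file ", path,
                                                   ": ", conditionMessage(e),
                                                   class = "cryomrf_input_error"))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0)
    stop_cryomrf("no ATOM records in ", path, class = "cryomrf_input_error")
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  at <- at[elem != "H" & elem != "D", , drop = FALSE]
  elem <- elem[elem != "H" & elem != "D"]
  # altloc: keep the highest-occupancy conformer per (chain, resno, atom name)
  keep <- rep(TRUE, nrow(at))
  alt <- trimws(at$alt); alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- at$o; occ[is.na(occ)] <- 1
    ord <- order(key, -occ, alt)
    first <- !duplicated(key[ord])
    keep <- logical(nrow(at)); keep[ord[first]] <- TRUE
  }
  at <- at[keep, , drop = FALSE]; elem <- elem[keep]
  out <- list()
  for (ch in unique(at$chain)) {
    sel <- at$chain == ch
    df <- data.frame(name = trimws(at$elety[sel]), element = elem[sel],
                     resno = at$resno[sel], resid = trimws(at$resid[sel]),
                     x = at$x[sel], y = at$y[sel], z = at$z[sel],
                     stringsAsFactors = FALSE)
    if (!any(df$name == "CA")) {
      warning("chain ", ch, " has no C-alpha atoms; skipped")
      next
    }
    out[[ch]] <- subunit(ch, df)
  }
  if (length(out) == 0)
    stop_cryomrf("no usable protein chains in ", path,
                 class = "cryomrf_input_error")
  out
}

#' Apply a rigid transform to a subunit
#'
#' Coordinates map as `x -> R(q) x + t`; all interatomic distances are
#' preserved.
#'
#' @param s a `subunit`.
#' @param transform a `rigid_transform`.
#' @return a new `subunit` with transformed coordinates.
#' @export
apply_transform <- function(s, transform) {
  stopifnot(inherits(s, "subunit"), inherits(transform, "rigid_transform"))
  xyz <- transform_point(transform, subunit_coords(s))
  at <- s$atoms
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  subunit(s$id, at)
}

#' Write placed subunits as a multi-chain PDB file
#'
#' @param subunits list of `subunit` objects (already placed).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_assembly_pdb <- function(subunits, path) {
  ats <- lapply(subunits, function(s) cbind(s$atoms, chain = s$id))
  df <- do.call(rbind, ats)
  xyz <- as.numeric(t(as.matrix(df[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = df$resno, resid = df$resid, chain = df$chain,
                   elety = df$name, elesy = df$element)
  invisible(path)
}
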
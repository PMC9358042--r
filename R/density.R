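#' Density map container
#'
#' A 3D voxel grid of density values on an orthogonal lattice. The grid-node
#' convention is used throughout: the center of voxel `(i, j, k)` (0-based)
#' lies at `origin + c(i, j, k) * voxel_size` in Angstrom. Arrays are stored
#' X-fastest (first array index is X).
#'
#' @param values 3D numeric array of densities (arbitrary units).
#' @param origin length-3 numeric, Angstrom position of voxel (0,0,0).
#' @param voxel_size scalar or length-3 numeric, Angstrom per voxel (> 0).
#' @return object of class `density_map` with fields `values`, `origin`,
#'   `voxel_size` (always length 3) and `dims`.
#' @export
density_map <- function(values, origin = c(0, 0, 0), voxel_size = 1) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3, all(voxel_size > 0),
            all(is.finite(origin)), all(is.finite(voxel_size)))
  if (!all(is.finite(values)))
    stop_cryomrf("density values must be finite", class = "cryomrf_format_error")
  structure(list(values = values, origin = origin, voxel_size = voxel_size,
                 dims = dim(values)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("<density_map>", paste(x$dims, collapse = " x "), "voxels,",
      paste(signif(x$voxel_size, 4), collapse = "/"), "A/voxel, origin [",
      paste(signif(x$origin, 5), collapse = ", "), "]\n")
  cat("  density range [", signif(min(x$values), 4), ",",
      signif(max(x$values), 4), "]\n")
  invisible(x)
}

#' Read an MRC/CCP4 density map
#'
#' Reads MRC2014 mode-2 (float) maps. Axis order (`MAPC/MAPR/MAPS`) is
#' normalized to the canonical X-fastest layout; the origin comes from the
#' `ORIGIN` header record when non-zero, otherwise from
#' `NXSTART/NYSTART/NZSTART` times the voxel size. Only orthogonal cells
#' (all angles 90 degrees) are supported.
#'
#' @param path file path.
#' @return a `density_map`.
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 1024)
  if (length(hdr_raw) < 1024)
    stop_cryomrf("truncated MRC header in ", path, class = "cryomrf_format_error")
  magic <- rawToChar(hdr_raw[209:212])
  endian <- "little"
  ints <- readBin(hdr_raw, "integer", 256, size = 4, endian = endian)
  if (!identical(substr(magic, 1, 3), "MAP"))
    stop_cryomrf("not an MRC map (bad MAP magic bytes) in ", path,
                 class = "cryomrf_format_error")
  flts <- readBin(hdr_raw, "double", 256, size = 4, endian = endian)
  nc <- ints[1]; nr <- ints[2]; ns <- ints[3]
  mode <- ints[4]
  if (mode != 2L)
    stop_cryomrf("unsupported MRC MODE ", mode, " (only mode 2 float) in ", path,
                 class = "cryomrf_format_error")
  nstart <- ints[5:7]
  m <- ints[8:10]
  cella <- flts[11:13]
  cellb <- flts[14:16]
  if (any(abs(cellb - 90) > 1e-3))
    stop_cryomrf("non-orthogonal cell (CELLB = ",
                 paste(signif(cellb, 5), collapse = ", "), ") in ", path,
                 class = "cryomrf_format_error")
  mapcrs <- ints[17:19]
  if (!setequal(mapcrs, 1:3))
    stop_cryomrf("invalid MAPC/MAPR/MAPS = ", paste(mapcrs, collapse = ","),
                 " in ", path, class = "cryomrf_format_error")
  if (any(m <= 0) || any(cella <= 0))
    stop_cryomrf("invalid MX/MY/MZ or CELLA in ", path,
                 class = "cryomrf_format_error")
  voxel <- cella / m
  orig <- flts[50:52]
  n <- c(nc, nr, ns)
  vals <- readBin(con, "double", prod(n), size = 4, endian = endian)
  if (length(vals) < prod(n))
    stop_cryomrf("truncated MRC data block in ", path, class = "cryomrf_format_error")
  arr <- array(vals, dim = n)                 # axes in file (c, r, s) order
  perm <- match(1:3, mapcrs)                  # position of X, Y, Z among c,r,s
  arr <- aperm(arr, perm)
  nstart_xyz <- nstart[perm]
  if (all(orig == 0)) orig <- nstart_xyz * voxel
  if (!all(is.finite(arr)))
    stop_cryomrf("non-finite densities in ", path, class = "cryomrf_format_error")
  density_map(arr, origin = orig, voxel_size = voxel)
}

#' Write a density map as MRC2014
#'
#' Writes a little-endian mode-2 (float32) MRC2014 file with canonical axis
#' order (`MAPC,MAPR,MAPS = 1,2,3`) and the origin in the `ORIGIN` record.
#' `read_map` inverts it up to float32 rounding of the densities.
#'
#' @param map a `density_map`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_cryomrf("cannot open ", path,
                                                   " for writing: ", conditionMessage(e),
                                                   class = "cryomrf_io_error"))
  on.exit(close(con))
  n <- map$dims
  v <- map$voxel_size
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(n)                      # NX NY NZ
  wi(2)                      # MODE 2 float
  wi(c(0, 0, 0))             # NXSTART..
  wi(n)                      # MX MY MZ
  wf(n * v)                  # CELLA
  wf(c(90, 90, 90))          # CELLB
  wi(1:3)                    # MAPC MAPR MAPS
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(1)                      # ISPG
  wi(0)                      # NSYMBT
  wi(rep(0, 25))             # EXTRA (words 26-50 incl. word 25)
  # note: words 25..49 are EXTRA; ORIGIN occupies words 50-52
  wf(map$origin)             # ORIGIN
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # MACHST little-endian
  wf(stats::sd(as.numeric(map$values)))              # RMS
  wi(0)                      # NLABL
  writeBin(raw(800), con)    # labels
  writeBin(as.numeric(map$values), con, size = 4, endian = "little")
  invisible(path)
}

# element lookup tables shared by the simulator and the interaction scores
.atomic_mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
                  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305)

element_mass <- function(element) {
  m <- .atomic_mass[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Simulate a density map from atomic coordinates
#'
#' Each atom contributes an isotropic 3D Gaussian kernel of total mass equal
#' to its weight; `resolution` is interpreted as the kernel FWHM, i.e.
#' `sigma = resolution / (2 sqrt(2 ln 2))`. Kernels are evaluated at voxel
#' centers (grid-node convention) and truncated at 4 sigma; with padding of
#' at least twice the resolution the integrated density matches the total
#' atom weight to better than 1\%. Defaults (10 Angstrom resolution, 1.0
#' Angstrom voxels) match the simulated-map convention used for the
#' benchmark maps.
#'
#' @param coords n x 3 matrix of atom positions, Angstrom.
#' @param weights per-atom kernel mass; default the atomic mass of `elements`.
#' @param elements character vector of element symbols (used only when
#'   `weights` is missing).
#' @param resolution kernel FWHM, Angstrom.
#' @param voxel_size grid spacing, Angstrom.
#' @param padding margin added around the atom bounding box on every side,
#'   Angstrom; default `resolution`.
#' @param origin optional fixed grid origin; when given together with `dims`
#'   the atoms are rendered onto that exact grid.
#' @param dims optional fixed grid dims.
#' @param truncate_sigma kernel truncation radius in units of sigma
#'   (default 4; the pose search uses 3 for speed, trading ~0.3\% of kernel
#'   mass per axis).
#' @return a `density_map`.
#' @export
simulate_map <- function(coords, weights = NULL, elements = NULL,
                         resolution = 10, voxel_size = 1.0,
                         padding = resolution, origin = NULL, dims = NULL,
                         truncate_sigma = 4) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0)
    stop_cryomrf("cannot simulate a map from zero atoms",
                 class = "cryomrf_empty_input_error")
  stopifnot(ncol(coords) == 3, resolution > 0, voxel_size > 0, padding >= 0)
  if (is.null(weights)) {
    weights <- if (is.null(elements)) rep(12.011, nrow(coords))
               else element_mass(elements)
  }
  stopifnot(length(weights) == nrow(coords))
  v <- voxel_size
  if (is.null(origin)) {
    lo <- apply(coords, 2, min) - padding
    hi <- apply(coords, 2, max) + padding
    origin <- lo
    dims <- pmax(2L, as.integer(ceiling((hi - lo) / v)) + 1L)
  } else {
    stopifnot(!is.null(dims))
    dims <- as.integer(dims)
  }
  sigma <- resolution / (2 * sqrt(2 * log(2)))
  hw <- as.integer(ceiling(truncate_sigma * sigma / v))
  amp <- (v / (sigma * sqrt(2 * pi)))^3
  vals <- array(0, dim = dims)
  for (a in seq_len(nrow(coords))) {
    p <- (coords[a, ] - origin) / v          # atom position in voxel units
    j0 <- pmax(0L, as.integer(floor(p)) - hw)
    j1 <- pmin(dims - 1L, as.integer(ceiling(p)) + hw)
    if (any(j0 > j1)) next
    gx <- exp(-((j0[1]:j1[1] - p[1]) * v)^2 / (2 * sigma^2))
    gy <- exp(-((j0[2]:j1[2] - p[2]) * v)^2 / (2 * sigma^2))
    gz <- exp(-((j0[3]:j1[3] - p[3]) * v)^2 / (2 * sigma^2))
    block <- (weights[a] * amp) * (gx %o% gy %o% gz)
    ix <- (j0[1]:j1[1]) + 1L; iy <- (j0[2]:j1[2]) + 1L; iz <- (j0[3]:j1[3]) + 1L
    vals[ix, iy, iz] <- vals[ix, iy, iz] + block
  }
  density_map(vals, origin = origin, voxel_size = v)
}

#' Threshold a map into a contour mask
#'
#' @param map a `density_map`.
#' @param level density threshold; the mask is `TRUE` where density >= level.
#' @return object of class `contour_mask`: logical array plus the parent
#'   geometry and `level`.
#' @export
contour_mask <- function(map, level) {
  stopifnot(inherits(map, "density_map"), is.finite(level))
  structure(list(mask = map$values >= level, origin = map$origin,
                 voxel_size = map$voxel_size, dims = map$dims, level = level),
            class = "contour_mask")
}

check_same_geometry <- function(a, b) {
  if (!identical(as.integer(a$dims), as.integer(b$dims)))
    stop_cryomrf("maps/masks have different dims", class = "cryomrf_geometry_error")
}

region_values <- function(map, region) {
  if (is.null(region)) as.numeric(map$values) else map$values[region$mask]
}

#' Cross-correlation coefficient between two maps
#'
#' The unnormalized cross-correlation
#' `sum(X_i Y_i) / sqrt(sum(X_i^2) sum(Y_i^2))` over the voxels of `region`
#' (all voxels when `region` is `NULL`). Used for experimental maps; lies in
#' `[0, 1]` for non-negative densities and equals 1 iff `Y` is a positive
#' multiple of `X` on the region.
#'
#' @param X,Y `density_map`s sharing geometry.
#' @param region optional `contour_mask` restricting the sums.
#' @return scalar correlation.
#' @export
ccc <- function(X, Y, region = NULL) {
  check_same_geometry(X, Y)
  if (!is.null(region)) check_same_geometry(X, region)
  x <- region_values(X, region); y <- region_values(Y, region)
  nx <- sum(x^2); ny <- sum(y^2)
  if (nx == 0 || ny == 0)
    stop_cryomrf("zero-norm density on the scoring region",
                 class = "cryomrf_undefined_score_error")
  sum(x * y) / sqrt(nx * ny)
}

#' Pearson cross-correlation coefficient between two maps
#'
#' Mean-centered correlation over the voxels of `region`; invariant to
#' positive affine rescaling of either map and lying in `[-1, 1]`. Preferred
#' over [ccc()] for simulated maps, where mean-centering weights molecular
#' surfaces rather than dense cores.
#'
#' @inheritParams ccc
#' @return scalar correlation in `[-1, 1]`.
#' @export
pccc <- function(X, Y, region = NULL) {
  check_same_geometry(X, Y)
  if (!is.null(region)) check_same_geometry(X, region)
  x <- region_values(X, region); y <- region_values(Y, region)
  xc <- x - mean(x); yc <- y - mean(y)
  nx <- sum(xc^2); ny <- sum(yc^2)
  if (nx == 0 || ny == 0)
    stop_cryomrf("constant density on the scoring region",
                 class = "cryomrf_undefined_score_error")
  sum(xc * yc) / sqrt(nx * ny)
}

#' Overlap fraction between two contour masks
#'
#' `|X intersect Y| / |Y|`: the fraction of `Y`'s above-contour voxels that
#' fall inside `X`'s contour. Asymmetric by design — `Y` is the subunit map,
#' `X` the experimental map.
#'
#' @param X,Y `contour_mask`s sharing geometry.
#' @return scalar in `[0, 1]`.
#' @export
overlap_fraction <- function(X, Y) {
  check_same_geometry(X, Y)
  ny <- sum(Y$mask)
  if (ny == 0)
    stop_cryomrf("empty subunit mask Y", class = "cryomrf_undefined_score_error")
  sum(X$mask & Y$mask) / ny
}
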
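# Real-space density grids: construction, CCP4/MRC input/output, footprint
# masks and observed/calculated scaling.

#' Construct a density grid
#'
#' A `density_grid` is a 3D voxel array in real space with per-axis voxel
#' spacing, a Cartesian origin (position of voxel `[1,1,1]`'s center), a
#' nominal resolution, and cached map statistics: the mean `mu` and the
#' root-mean-square `sigma` of the values, as used by the EDIA normalized
#' density score.
#'
#' @param values numeric 3D array of density values.
#' @param spacing voxel spacing in Angstrom, per axis (scalar recycled).
#' @param origin Cartesian position (Angstrom) of the first voxel center.
#' @param resolution nominal resolution d_min in Angstrom.
#' @return object of class `density_grid`.
#' @export
density_grid <- function(values, spacing, origin = c(0, 0, 0),
                         resolution = NA_real_) {
  values <- as.array(values)
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("spacing must be > 0 on every axis")
  v <- as.numeric(values)
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 resolution = as.numeric(resolution),
                 mu = mean(v), sigma = sqrt(mean(v^2))),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Density grid %d x %d x %d, spacing %.3g/%.3g/%.3g A",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  if (is.finite(x$resolution)) cat(sprintf(", d_min %.2f A", x$resolution))
  cat(sprintf("\n  mu = %.4g, sigma = %.4g\n", x$mu, x$sigma))
  invisible(x)
}

# Replace values, recomputing the cached statistics.
.grid_set_values <- function(grid, values) {
  density_grid(values, grid$spacing, grid$origin, grid$resolution)
}

# Cartesian coordinates of voxel centers for given linear indices (or all).
.grid_coords <- function(grid, idx = NULL) {
  d <- dim(grid$values)
  if (is.null(idx)) idx <- seq_len(prod(d))
  ijk <- arrayInd(idx, d)
  sweep((ijk - 1) %*% diag(grid$spacing), 2, grid$origin, `+`)
}

# Grid geometry covering a set of conformers: bounding box padded by `pad`,
# spacing min(d_min/4, 0.5) (Nyquist-safe for the Gaussian atom model).
.grid_spec_for <- function(conformers, resolution, pad = 4, spacing = NULL) {
  xyz <- do.call(rbind, lapply(conformers, `[[`, "xyz"))
  spacing <- spacing %||% min(resolution / 4, 0.5)
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  n <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  list(dim = n, spacing = rep(spacing, 3), origin = lo,
       resolution = resolution)
}

#' Footprint mask around a conformer ensemble
#'
#' All voxels whose center lies within `radius` of any heavy atom of any
#' conformer. This mask defines the region over which occupancies are fit
#' and real-space correlation is computed.
#'
#' @param conformers list of [conformer()] objects (may be empty).
#' @param grid a [density_grid()].
#' @param radius mask radius in Angstrom (default 1.5, covering the first
#'   density shell).
#' @return object of class `footprint_mask`: sorted vector of linear voxel
#'   indices with the grid dimensions attached.
#' @export
footprint_mask <- function(conformers, grid, radius = 1.5) {
  stopifnot(radius > 0)
  d <- dim(grid$values)
  if (length(conformers) == 0) {
    return(structure(integer(0), grid_dim = d, class = "footprint_mask"))
  }
  xyz <- do.call(rbind, lapply(conformers, `[[`, "xyz"))
  idx <- sort(unique(cpp_mask_indices(xyz, d, grid$spacing, grid$origin,
                                      radius)))
  structure(as.integer(idx), grid_dim = d, class = "footprint_mask")
}

#' Least-squares scale from a calculated to an observed map
#'
#' Returns the scalar `s` minimizing `||s * calc - obs||^2` over the masked
#' voxels, so residuals of observed and calculated density are compared on
#' a common scale.
#'
#' @param calc,obs congruent [density_grid()] objects.
#' @param mask a [footprint_mask()] on the same grid.
#' @return scale factor (numeric scalar).
#' @export
scale_calc_to_obs <- function(calc, obs, mask) {
  stopifnot(all(dim(calc$values) == dim(obs$values)))
  if (length(mask) == 0) stop("mask is empty")
  x <- as.numeric(calc$values[mask])
  y <- as.numeric(obs$values[mask])
  den <- sum(x * x)
  if (den == 0) stop("calculated map is identically zero on the mask")
  sum(x * y) / den
}

# ---- CCP4/MRC map input/output -------------------------------------------

#' Read a CCP4/MRC density map
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32). Maps stored with a
#' permuted axis order (MAPC/MAPR/MAPS) are returned in canonical X/Y/Z
#' order. The origin is taken from the ORIGIN header words when set,
#' otherwise from NCSTART/NRSTART/NSSTART times the voxel spacing.
#'
#' @param path path to a CCP4/MRC map file.
#' @param resolution optional nominal resolution to attach to the grid.
#' @return a [density_grid()].
#' @export
read_map <- function(path, resolution = NA_real_) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024)
  if (length(hdr_raw) < 1024) stop("malformed header: file truncated")
  ints <- readBin(hdr_raw, "integer", n = 256, size = 4, endian = "little")
  flts <- readBin(hdr_raw, "double", n = 256, size = 4, endian = "little")
  maptag <- rawToChar(hdr_raw[209:212])
  if (!grepl("^MAP", maptag))
    stop("malformed header: missing MAP stamp (not a CCP4/MRC file?)")
  nc <- ints[1]; nr <- ints[2]; ns <- ints[3]; mode <- ints[4]
  if (any(c(nc, nr, ns) <= 0)) stop("malformed header: bad dimensions")
  start <- ints[5:7]
  m <- ints[8:10]
  cell <- flts[11:13]
  mapcrs <- ints[17:19]
  if (!all(sort(mapcrs) == 1:3))
    stop("malformed header: invalid MAPC/MAPR/MAPS")
  nvox <- nc * nr * ns
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1,
                             signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                             endian = "little")),
    "2" = readBin(con, "double", n = nvox, size = 4, endian = "little"),
    stop("unsupported mode: ", mode))
  if (length(data) < nvox) stop("malformed header: data shorter than stated")
  arr <- array(data, dim = c(nc, nr, ns))
  # permute from file (col, row, sec) order to canonical x, y, z
  perm <- order(mapcrs)          # position of x, y, z among file axes
  arr <- aperm(arr, perm)
  m_xyz <- m[perm]
  start_xyz <- start[perm]
  cell_xyz <- cell[perm]
  spacing <- ifelse(m_xyz > 0, cell_xyz / m_xyz, 1)
  org <- flts[50:52]
  if (all(org == 0) && any(start_xyz != 0)) org <- start_xyz * spacing
  density_grid(arr, spacing = spacing, origin = org,
               resolution = resolution)
}

#' Write a density grid as a CCP4/MRC map (mode 2, float32)
#'
#' @param grid a [density_grid()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_map <- function(grid, path) {
  d <- dim(grid$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  v <- as.numeric(grid$values)
  wi(d)                                   # NC NR NS
  wi(2)                                   # MODE float32
  wi(c(0, 0, 0))                          # NCSTART..
  wi(d)                                   # MX MY MZ
  wf(d * grid$spacing)                    # CELLA
  wf(c(90, 90, 90))                       # CELLB
  wi(c(1, 2, 3))                          # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))          # AMIN AMAX AMEAN
  wi(1)                                   # ISPG
  wi(0)                                   # NSYMBT
  wi(rep(0, 25))                          # EXTRA (words 25-49)
  wf(grid$origin)                         # ORIGIN (words 50-52)
  writeBin(charToRaw("MAP "), con)        # word 53
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # machine stamp
  wf(stats::sd(v))                        # RMS
  wi(0)                                   # NLABL
  writeBin(raw(800), con)                 # labels
  wf(v)
  invisible(path)
}
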
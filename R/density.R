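# Calculated density from atoms: each heavy atom contributes an isotropic
# Gaussian whose integral equals its electron count and whose width combines
# the atomic B-factor with a resolution-dependent blur.

# Effective B: atomic B plus a resolution blur B_blur = 8 * d_min^2, chosen
# so the atom peak width tracks the nominal map resolution.
.b_blur <- function(resolution) 8 * resolution^2

.conformer_density_at <- function(points, conf, elements, resolution) {
  z <- .element_z(elements)
  beff <- conf$b_factors + .b_blur(resolution)
  if (any(beff <= 0)) stop("zero/negative effective B-factor")
  cpp_atom_density(points, conf$xyz, z, beff)
}

#' Calculated density map for a weighted conformer ensemble
#'
#' Synthesizes `rho_calc = sum_i w_i * rho(conformer_i)` on a voxel grid.
#' Each heavy atom contributes a single isotropic Gaussian
#' `rho_a(r) = Z (4 pi / B_eff)^(3/2) exp(-4 pi^2 r^2 / B_eff)` with
#' `B_eff = B_atom + 8 d_min^2`, which integrates to the element's electron
#' count Z. The map is linear in the weights.
#'
#' @param conformers list of [conformer()] objects sharing one topology.
#' @param weights nonnegative weights, `sum(weights) <= 1`.
#' @param topology the shared [ligand_topology()] (supplies elements).
#' @param resolution nominal resolution d_min (Angstrom).
#' @param grid either `NULL` (a grid is built over the ensemble's bounding
#'   box padded by 4 A, spacing `min(d_min/4, 0.5)` A) or an existing
#'   [density_grid()] whose geometry is reused.
#' @return a [density_grid()].
#' @export
calc_density <- function(conformers, weights, topology, resolution,
                         grid = NULL) {
  if (length(conformers) == 0) stop("empty conformer list")
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  if (length(weights) != length(conformers))
    stop("one weight per conformer required")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) > 1 + 1e-9) stop("weights must sum to <= 1")
  spec <- if (is.null(grid)) {
    .grid_spec_for(conformers, resolution)
  } else {
    list(dim = dim(grid$values), spacing = grid$spacing,
         origin = grid$origin, resolution = grid$resolution %||% resolution)
  }
  pts <- .grid_coords(list(values = array(0, spec$dim),
                           spacing = spec$spacing, origin = spec$origin))
  vals <- numeric(nrow(pts))
  for (i in seq_along(conformers)) {
    if (weights[i] == 0) next
    vals <- vals + weights[i] *
      .conformer_density_at(pts, conformers[[i]], topology$elements,
                            resolution)
  }
  density_grid(array(vals, spec$dim), spec$spacing, spec$origin,
               resolution)
}

# Per-conformer density rows evaluated at masked voxel centers only:
# the design matrix of the occupancy QP (conformers x masked voxels).
.density_rows <- function(conformers, topology, grid, mask, resolution) {
  pts <- .grid_coords(grid, as.integer(mask))
  t(vapply(conformers, function(cf)
    .conformer_density_at(pts, cf, topology$elements, resolution),
    numeric(nrow(pts))))
}
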
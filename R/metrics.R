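# Real-space validation metrics: RSCC, per-atom EDIA / combined EDIAm, and
# coordinate RMSD helpers.

#' Real-space correlation coefficient
#'
#' Pearson correlation of observed versus calculated density over the
#' masked voxels. Symmetric in its two maps and invariant under positive
#' affine rescaling of either.
#'
#' @param obs,calc congruent [density_grid()] objects.
#' @param mask a [footprint_mask()] with at least two voxels.
#' @return correlation in `[-1, 1]`.
#' @export
rscc <- function(obs, calc, mask) {
  stopifnot(all(dim(obs$values) == dim(calc$values)))
  if (length(mask) < 2) stop("mask must contain at least 2 voxels")
  x <- as.numeric(obs$values[as.integer(mask)])
  y <- as.numeric(calc$values[as.integer(mask)])
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero-variance input: correlation undefined")
  stats::cor(x, y)
}

#' Truncated normalized density score z(p)
#'
#' The per-grid-point score entering EDIA: the map-normalized density
#' `(rho - mu) / sigma` floored at 0 and truncated at `zeta = 1.2`, so
#' excess density beyond 1.2 sigma earns no extra support and negative
#' density earns none at all.
#'
#' @param rho density value(s) at grid points.
#' @param mu map mean.
#' @param sigma map root-mean-square (must be > 0).
#' @param zeta truncation point (default 1.2).
#' @return score(s) in `[0, zeta]`.
#' @export
edia_z <- function(rho, mu, sigma, zeta = 1.2) {
  if (sigma <= 0) stop("sigma must be > 0")
  pmin(pmax((rho - mu) / sigma, 0), zeta)
}

# Atom support radius (Angstrom): radius at which the Gaussian atom image
# falls to 5% of its peak, B_eff = B_atom + 8 d_min^2, with a mild element
# factor (heavier atoms image slightly wider). Element- and resolution-
# dependent by construction.
.edia_radius <- function(elements, resolution, b_factor = 20) {
  if (!is.finite(resolution)) resolution <- 1.0
  beff <- b_factor + 8 * resolution^2
  sqrt(log(20) * beff) / (2 * pi) * (.element_z(elements) / 6)^(1 / 6)
}

# Distance-dependent weight: positive support inside r, a smooth negative
# penalty lobe (depth 0.15) between r and 2r, zero beyond. The lobe depth
# balances the very large positive-region z saturation seen on
# ligand-local grids, where sigma is computed over a mostly empty box.
.edia_weight <- function(d, r, depth = 0.15) {
  w <- numeric(length(d))
  inside <- d <= r
  w[inside] <- 1 - (d[inside] / r)^2
  ring <- d > r & d <= 2 * r
  t <- d[ring] / r - 1
  w[ring] <- -depth * 4 * t * (1 - t)
  w
}

#' Electron density support for an individual atom (EDIA)
#'
#' Estimates how well the map supports one atom:
#' `EDIA(a) = sum_p w(p,a) o(p,a) z(p) / sum_{p: w > 0} w(p,a)`,
#' where `z(p)` is the truncated normalized density ([edia_z()]), `w(p,a)`
#' a distance-dependent weight (positive within the atom's support radius,
#' negative in a shell out to twice that radius, penalizing unclaimed
#' excess density), and `o(p,a)` an ownership factor partitioning voxels
#' among atoms: voxels inside several atoms' positive regions are split
#' evenly, and negative-shell voxels count only when no atom claims them
#' positively. Negative totals are floored at 0.
#'
#' @param position atom position (length-3, Angstrom).
#' @param element element symbol.
#' @param grid the observed [density_grid()] (its `mu`/`sigma` normalize
#'   the density).
#' @param neighbors optional matrix of neighboring atom positions with
#'   their elements in `neighbor_elements`, competing for voxel ownership.
#' @param neighbor_elements element symbols aligned with `neighbors` rows.
#' @param b_factor the atom's isotropic B-factor (Angstrom^2); widens the
#'   support radius together with the resolution blur.
#' @param neighbor_b b_factors for the neighbor atoms (scalar recycled).
#' @param zeta truncation point for [edia_z()].
#' @return EDIA score (>= 0).
#' @export
edia_atom <- function(position, element, grid, neighbors = NULL,
                      neighbor_elements = NULL, b_factor = 20,
                      neighbor_b = 20, zeta = 1.2) {
  if (!is.finite(grid$sigma) || grid$sigma <= 0)
    stop("grid sigma must be finite and > 0")
  r <- .edia_radius(element, grid$resolution, b_factor)
  idx <- sort(unique(cpp_mask_indices(matrix(position, 1, 3),
                                      dim(grid$values), grid$spacing,
                                      grid$origin, 2 * r)))
  if (length(idx) == 0) stop("atom outside grid")
  pts <- .grid_coords(grid, idx)
  d <- sqrt(rowSums(sweep(pts, 2, position)^2))
  w <- .edia_weight(d, r)
  z <- edia_z(as.numeric(grid$values[idx]), grid$mu, grid$sigma, zeta)
  # ownership against neighbors
  o <- rep(1, length(idx))
  claimed <- d <= r
  nclaims <- as.numeric(claimed)
  if (!is.null(neighbors) && nrow(neighbors) > 0) {
    if (length(neighbor_b) == 1)
      neighbor_b <- rep(neighbor_b, nrow(neighbors))
    rn <- .edia_radius(neighbor_elements, grid$resolution, neighbor_b)
    for (j in seq_len(nrow(neighbors))) {
      dj <- sqrt(rowSums(sweep(pts, 2, as.numeric(neighbors[j, ]))^2))
      nclaims <- nclaims + (dj <= rn[j])
    }
  }
  pos_region <- w > 0
  o[pos_region] <- 1 / pmax(nclaims[pos_region], 1)
  neg_region <- w < 0
  o[neg_region] <- as.numeric(nclaims[neg_region] == 0)
  den <- sum(w[pos_region])
  if (den <= 0) return(0)
  max(0, sum(w * o * z) / den)
}

#' Combined electron-density support for a ligand (EDIAm)
#'
#' Computes EDIA for each heavy atom of every conformer in the model (each
#' atom competing for voxel ownership with all other atoms of the model)
#' and combines them with a power mean of exponent -2, which weights
#' poorly-supported atoms heavily; an arithmetic mean is available via
#' `combine = "mean"`. Raising every per-atom EDIA raises EDIAm. Intended
#' for maps of resolution 2.0 A or better (the spherical-atom picture
#' degrades beyond that; a warning is issued, not an error).
#'
#' @param conformers list of [conformer()] objects (the model).
#' @param topology shared [ligand_topology()].
#' @param grid observed [density_grid()].
#' @param combine `"power"` (exponent -2, default) or `"mean"`.
#' @param zeta truncation point for [edia_z()].
#' @return list with `ediam` and `per_atom` (matrix conformers x atoms).
#' @export
ediam <- function(conformers, topology, grid, combine = c("power", "mean"),
                  zeta = 1.2) {
  combine <- match.arg(combine)
  if (length(conformers) == 0) stop("empty model")
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  if (is.finite(grid$resolution) && grid$resolution > 2.0)
    warning("EDIA at resolution worse than 2 A is unreliable ",
            "(spherical-atom assumption)")
  # ownership competes within one conformer only: alternate conformers of
  # the same ligand share density by design and are not rivals for it
  per <- matrix(NA_real_, length(conformers), topology$heavy_atom_count)
  for (ci in seq_along(conformers)) {
    cf <- conformers[[ci]]
    for (ai in seq_len(topology$heavy_atom_count)) {
      per[ci, ai] <- edia_atom(cf$xyz[ai, ], topology$elements[ai], grid,
                               neighbors = cf$xyz[-ai, , drop = FALSE],
                               neighbor_elements = topology$elements[-ai],
                               b_factor = cf$b_factors[ai],
                               neighbor_b = cf$b_factors[-ai],
                               zeta = zeta)
    }
  }
  vals <- as.numeric(per)
  score <- if (combine == "power") {
    mean(pmax(vals, 1e-3)^(-2))^(-1 / 2)
  } else {
    mean(vals)
  }
  list(ediam = score, per_atom = per)
}

#' Smallest RMSD between a model's conformers and a reference
#'
#' @param conformers list of [conformer()] objects (nonempty).
#' @param reference a [conformer()] with the same topology/atom order.
#' @return minimum in-place [rmsd()] over the model's conformers (Angstrom).
#' @export
closest_conformer_rmsd <- function(conformers, reference) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  if (length(conformers) == 0) stop("empty model")
  min(vapply(conformers, rmsd, numeric(1), c2 = reference))
}

#' Assemble a validation report
#'
#' @param conformers model conformers.
#' @param topology shared topology.
#' @param obs observed [density_grid()].
#' @param mask [footprint_mask()] around the model.
#' @param resolution nominal resolution.
#' @param reference optional reference conformer for RMSD reporting.
#' @return object of class `validation_report` with `rscc`, `ediam`,
#'   `per_atom_edia`, `rmsd_to_reference`.
#' @export
validation_report <- function(conformers, topology, obs, mask, resolution,
                              reference = NULL) {
  weights <- vapply(conformers, `[[`, numeric(1), "occupancy")
  calc <- calc_density(conformers, weights, topology, resolution,
                       grid = obs)
  ed <- suppressWarnings(ediam(conformers, topology, obs))
  structure(list(
    rscc = rscc(obs, calc, mask),
    ediam = ed$ediam,
    per_atom_edia = ed$per_atom,
    rmsd_to_reference = if (!is.null(reference))
      closest_conformer_rmsd(conformers, reference) else NA_real_
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation: RSCC = %.4f, EDIAm = %.4f", x$rscc, x$ediam))
  if (is.finite(x$rmsd_to_reference))
    cat(sprintf(", closest-conformer RMSD = %.3f A", x$rmsd_to_reference))
  cat("\n")
  invisible(x)
}

#' Serialize a validation report
#'
#' Writes the report as JSON and the per-atom EDIA table as a flat TSV
#' (one row per conformer/atom).
#'
#' @param report a [validation_report()].
#' @param json_file,tsv_file output paths (either may be `NULL` to skip).
#' @param atom_names optional atom names for the TSV.
#' @return invisibly, the list written to JSON.
#' @export
write_report <- function(report, json_file = NULL, tsv_file = NULL,
                         atom_names = NULL) {
  payload <- list(rscc = report$rscc, ediam = report$ediam,
                  rmsd_to_reference = report$rmsd_to_reference,
                  per_atom_edia = report$per_atom_edia)
  if (!is.null(json_file))
    jsonlite::write_json(payload, json_file, auto_unbox = TRUE,
                         digits = NA, na = "null")
  if (!is.null(tsv_file)) {
    pa <- report$per_atom_edia
    df <- data.frame(
      conformer = rep(seq_len(nrow(pa)), times = ncol(pa)),
      atom = rep(atom_names %||% paste0("atom", seq_len(ncol(pa))),
                 each = nrow(pa)),
      edia = as.numeric(pa))
    df <- df[order(df$conformer), ]
    write.table(df, tsv_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(payload)
}
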
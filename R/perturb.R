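# Local rigid-body enrichment of QP survivors before final selection.

#' Rigid-body perturbation of conformers
#'
#' For each input conformer, emits the original plus rigid rotations of
#' 5, 10 and 15 degrees in both directions about each of the three
#' principal axes through the centroid (18 rotations) and rigid
#' translations of +/-0.3 A along each Cartesian map axis (6 translations):
#' 25 outputs per input, applied one at a time (no rotation-translation
#' products). Rigid motions preserve all intramolecular distances, so
#' chemistry is trivially preserved.
#'
#' @param conformers nonempty list of [conformer()] objects.
#' @param rot_angles rotation magnitudes in degrees (default `c(5,10,15)`,
#'   applied with both signs).
#' @param translation translation step in Angstrom (default 0.3).
#' @return list of perturbed conformers, `25 * length(conformers)` by
#'   default, originals included.
#' @export
perturb_conformers <- function(conformers, rot_angles = c(5, 10, 15),
                               translation = 0.3) {
  if (length(conformers) == 0) stop("empty conformer list")
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  out <- list()
  for (cf in conformers) {
    xyz <- cf$xyz
    if (nrow(xyz) < 3) stop("degenerate geometry (< 3 atoms)")
    ctr <- .centroid(xyz)
    cen <- sweep(xyz, 2, ctr)
    axes <- eigen(crossprod(cen), symmetric = TRUE)$vectors
    res <- list(cf)
    for (ax in 1:3) {
      for (ang in c(rot_angles, -rot_angles)) {
        res <- c(res, list(conformer(
          .rotate_points(xyz, ctr, axes[, ax], ang),
          cf$b_factors, source = paste0(cf$source, "+rot"))))
      }
    }
    for (ax in 1:3) {
      for (s in c(1, -1)) {
        shift <- c(0, 0, 0); shift[ax] <- s * translation
        res <- c(res, list(conformer(sweep(xyz, 2, shift, `+`),
                                     cf$b_factors,
                                     source = paste0(cf$source, "+trans"))))
      }
    }
    out <- c(out, res)
  }
  out
}
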
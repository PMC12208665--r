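# Conformers: one heavy-atom coordinate set with per-atom B-factors and an
# occupancy, in the frame of the density map.

#' Construct a conformer
#'
#' @param xyz numeric matrix, one row per heavy atom (Angstrom, map frame).
#' @param b_factors per-atom isotropic B-factors (Angstrom^2), all > 0.
#'   A scalar is recycled.
#' @param occupancy fraction in `[0, 1]`.
#' @param altloc single-character alternate-location label, or `""`.
#' @param source free-text provenance tag (e.g. the sampling strategy).
#' @return object of class `conformer`.
#' @export
conformer <- function(xyz, b_factors = 20, occupancy = 1, altloc = "",
                      source = "input") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must have three columns")
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  n <- nrow(xyz)
  if (length(b_factors) == 1) b_factors <- rep(b_factors, n)
  if (length(b_factors) != n) stop("b_factors length must match atom count")
  if (any(b_factors <= 0)) stop("all B-factors must be > 0")
  if (occupancy < 0 || occupancy > 1) stop("occupancy must be in [0, 1]")
  if (nchar(altloc) > 1) stop("altloc must be one character or empty")
  structure(list(xyz = xyz, b_factors = as.numeric(b_factors),
                 occupancy = as.numeric(occupancy), altloc = altloc,
                 source = source),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat("Conformer:", nrow(x$xyz), "heavy atoms, occupancy",
      format(x$occupancy, digits = 3),
      if (nzchar(x$altloc)) paste0("(altloc ", x$altloc, ")"), "\n")
  invisible(x)
}

.check_same_topology <- function(c1, c2) {
  if (nrow(c1$xyz) != nrow(c2$xyz))
    stop("conformers have different atom counts")
}

#' Root-mean-square deviation between two conformers
#'
#' Computed in place over heavy atoms with fixed atom order, with no
#' superposition: position in the map matters, so rigidly displaced copies
#' are genuinely distinct.
#'
#' @param c1,c2 [conformer()] objects (or bare coordinate matrices) with the
#'   same atom count and order.
#' @return RMSD in Angstrom.
#' @examples
#' a <- conformer(matrix(rnorm(12), 4, 3))
#' b <- conformer(a$xyz + rep(c(1, 0, 0), each = 4))
#' rmsd(a, b)  # exactly 1
#' @export
rmsd <- function(c1, c2) {
  x1 <- if (inherits(c1, "conformer")) c1$xyz else as.matrix(c1)
  x2 <- if (inherits(c2, "conformer")) c2$xyz else as.matrix(c2)
  if (!all(dim(x1) == dim(x2))) stop("atom-count mismatch")
  sqrt(mean(rowSums((x1 - x2)^2)))
}

# Flatten a list of conformers to an n_conf x (3*natom) matrix (row-major
# per conformer: x1 y1 z1 x2 ...), used by the compiled dedup kernel.
.conformer_matrix <- function(conformers) {
  do.call(rbind, lapply(conformers, function(cf) as.vector(t(cf$xyz))))
}
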
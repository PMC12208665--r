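# Element tables and small geometry helpers shared across modules.

# Covalent radii (Angstrom), Cordero 2008 values for the elements that occur
# in typical ligands. Used for geometry-based bond perception.
.covalent_radius <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  SI = 1.11, P = 1.07, S = 1.05, CL = 1.02, BR = 1.20, I = 1.39,
  SE = 1.20, AS = 1.19
)

# Atomic numbers (electron counts for the neutral atom); the Gaussian atom
# density integrates to this value.
.atomic_number <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, SI = 14, P = 15, S = 16,
  CL = 17, BR = 35, I = 53, SE = 34, AS = 33
)

.norm_element <- function(x) {
  x <- toupper(trimws(x))
  x[x == ""] <- NA_character_
  x
}

.element_z <- function(elements) {
  z <- .atomic_number[.norm_element(elements)]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(z)]), collapse = ", "))
  }
  unname(z)
}

.element_covr <- function(elements) {
  r <- .covalent_radius[.norm_element(elements)]
  if (anyNA(r)) {
    stop("no covalent radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

.is_hydrogen <- function(elements) .norm_element(elements) %in% c("H", "D")

# Rotation matrix for angle (degrees) about unit axis u (Rodrigues).
.rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotate rows of xyz about an axis through `origin`.
.rotate_points <- function(xyz, origin, axis, angle_deg) {
  R <- .rotation_matrix(axis, angle_deg)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
}

.centroid <- function(xyz) colMeans(xyz)

`%||%` <- function(a, b) if (is.null(a)) b else a
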
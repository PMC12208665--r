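# Synthetic two-conformer benchmark: four programmatically built ligand
# archetypes covering distinct disorder classes, simulated ground-truth
# density over a grid of occupancy splits and resolutions, and a benchmark
# emitter (model + map pairs with a manifest).

# ---- idealized geometry helpers ------------------------------------------

.zigzag_chain <- function(n, bond = 1.53, angle = 111) {
  half <- angle / 2 * pi / 180
  x <- (seq_len(n) - 1) * bond * sin(half)
  y <- bond * cos(half) * (seq_len(n) %% 2)
  cbind(x, y, 0)
}

# tetrahedral completion: unit vectors for the two remaining substituent
# directions at a center with known neighbor directions v1, v2
.tetrahedral_dirs <- function(v1, v2) {
  b <- -(v1 / sqrt(sum(v1^2)) + v2 / sqrt(sum(v2^2)))
  b <- b / sqrt(sum(b^2))
  n <- c(v1[2] * v2[3] - v1[3] * v2[2],
         v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  n <- n / sqrt(sum(n^2))
  phi <- 54.75 * pi / 180
  list(cos(phi) * b + sin(phi) * n, cos(phi) * b - sin(phi) * n)
}

.ring_flip_pair <- function() {
  # methylcyclohexane: chair ring, A with one methyl orientation, B the
  # flipped chair (localized ring flip)
  r <- 1.46; z <- 0.222; bond <- 1.53
  th <- (0:5) * pi / 3
  ring <- cbind(r * cos(th), r * sin(th), z * (-1)^(0:5))
  methyl_at <- function(ring) {
    dirs <- .tetrahedral_dirs(ring[2, ] - ring[1, ], ring[6, ] - ring[1, ])
    ring[1, ] + bond * dirs[[1]]
  }
  a <- rbind(ring, methyl_at(ring))
  ring_b <- ring; ring_b[, 3] <- -ring_b[, 3]
  b <- rbind(ring_b, methyl_at(ring_b))
  bonds <- rbind(cbind(1:5, 2:6), c(1, 6), c(1, 7))
  list(id = "ring_flip", smiles = "CC1CCCCC1",
       elements = rep("C", 7), bonds = bonds, xyz_a = a, xyz_b = b)
}

.linear_pair <- function() {
  # octane: long linear ligand; B is a whole-body displacement of A
  a <- .zigzag_chain(8)
  b <- .rotate_points(a, .centroid(a), c(0, 0, 1), 12)
  b <- sweep(b, 2, c(0.5, 0.45, 0.3), `+`)
  list(id = "linear", smiles = "CCCCCCCC",
       elements = rep("C", 8), bonds = cbind(1:7, 2:8),
       xyz_a = a, xyz_b = b)
}

.torsion_pair <- function() {
  # n-propanol heavy atoms C-C-C-O: B shifts the terminal torsion by 120
  # degrees (localized disorder from a single torsional change)
  a <- .zigzag_chain(4)
  b <- a
  axis <- a[3, ] - a[2, ]
  b[4, ] <- .rotate_points(a[4, , drop = FALSE], a[2, ], axis, 120)
  list(id = "torsion_shift", smiles = "CCCO",
       elements = c("C", "C", "C", "O"), bonds = cbind(1:3, 2:4),
       xyz_a = a, xyz_b = b)
}

.macrocycle_pair <- function() {
  # 12-membered carbon macrocycle with a 4-atom branch; B rotates the
  # branch about its attachment bond and the terminal atom about the
  # penultimate bond (branch + terminal-end heterogeneity)
  bond <- 1.53
  R <- bond / (2 * sin(pi / 12))
  th <- (0:11) * pi / 6
  ring <- cbind(R * cos(th), R * sin(th), 0)
  dx <- bond * sin(55.5 * pi / 180)
  dz <- bond * cos(55.5 * pi / 180)
  branch <- t(vapply(1:4, function(k)
    ring[1, ] + c(k * dx, 0, dz * (k %% 2)), numeric(3)))
  a <- rbind(ring, branch)
  b <- a
  idx_branch <- 13:16
  axis1 <- a[13, ] - a[1, ]
  b[14:16, ] <- .rotate_points(b[14:16, , drop = FALSE], a[13, ], axis1, 65)
  axis2 <- b[15, ] - b[14, ]
  b[16, ] <- .rotate_points(b[16, , drop = FALSE], b[14, ], axis2, 120)
  bonds <- rbind(cbind(1:11, 2:12), c(1, 12), c(1, 13),
                 cbind(13:15, 14:16))
  list(id = "macrocycle", smiles = "CCCCC1CCCCCCCCCCC1",
       elements = rep("C", 16), bonds = bonds, xyz_a = a, xyz_b = b)
}

#' Benchmark ligand archetypes
#'
#' Four programmatically constructed two-conformer ligands mirroring the
#' benchmark's disorder classes: a localized ring flip (methylcyclohexane
#' chair flip), a long linear ligand with non-localized whole-body
#' displacement (octane), localized disorder from a single torsional shift
#' (propanol), and a 12-membered macrocycle with branch and terminal-end
#' heterogeneity. Each archetype shares one topology between its A and B
#' conformers, both pass [validate_connectivity()], and the A/B in-place
#' RMSD is at least 0.5 A.
#'
#' @param b_factor B-factor assigned to every atom of both conformers.
#' @return list of four archetypes, each a list with `id`, `smiles`,
#'   `topology`, `conformer_a`, `conformer_b`.
#' @export
fixture_ligands <- function(b_factor = 15) {
  raw <- list(.ring_flip_pair(), .linear_pair(), .torsion_pair(),
              .macrocycle_pair())
  lapply(raw, function(ar) {
    top <- ligand_topology(ar$elements, ar$bonds,
                           rep(1, nrow(ar$bonds)))
    list(id = ar$id, smiles = ar$smiles, topology = top,
         conformer_a = conformer(ar$xyz_a, b_factor, occupancy = 1,
                                 altloc = "A", source = "truth_A"),
         conformer_b = conformer(ar$xyz_b, b_factor, occupancy = 1,
                                 altloc = "B", source = "truth_B"))
  })
}

# B-factor inflation schedule: crisp at 0.8 A, increasingly smeared toward
# 2.5 A. Stand-in constants (B0 = 15 A^2, slope 20 A^2 per A of d_min).
.benchmark_b_factor <- function(resolution, b0 = 15, slope = 20) {
  b0 + slope * (resolution - 0.8)
}

#' Build a synthetic benchmark case
#'
#' @param archetype one element of [fixture_ligands()].
#' @param q_a,q_b occupancies of conformers A and B (`q_a + q_b = 1`);
#'   `q_a` is the occupancy of the deposited/input conformer.
#' @param resolution map resolution (Angstrom).
#' @param noise_seed seed for the Gaussian map noise.
#' @param noise_alpha noise scale: noise sd = `alpha * d_min * sigma` of
#'   the clean map (default 0.05/A).
#' @return object of class `benchmark_case`.
#' @export
benchmark_case <- function(archetype, q_a, q_b, resolution,
                           noise_seed = 1L, noise_alpha = 0.05) {
  stopifnot(abs(q_a + q_b - 1) < 1e-9, q_a >= 0, q_b >= 0)
  structure(list(archetype = archetype, q_a = q_a, q_b = q_b,
                 resolution = resolution, noise_seed = as.integer(noise_seed),
                 noise_alpha = noise_alpha),
            class = "benchmark_case")
}

#' Simulate the ground-truth density map of a benchmark case
#'
#' The map is the occupancy-weighted calculated density of the A and B
#' conformers, with every atom's B-factor inflated on a resolution
#' schedule (`B = 15 + 20 (d_min - 0.8)` A^2, emulating growing positional
#' uncertainty at worse resolution) plus i.i.d. Gaussian noise of standard
#' deviation `alpha * d_min * sigma_clean`, i.e. noise growing linearly
#' with d_min. Reproducible for a fixed `noise_seed`.
#'
#' @param case a [benchmark_case()].
#' @return a [density_grid()].
#' @export
build_truth_map <- function(case) {
  stopifnot(inherits(case, "benchmark_case"))
  ar <- case$archetype
  bf <- .benchmark_b_factor(case$resolution)
  ca <- ar$conformer_a; ca$b_factors <- rep(bf, length(ca$b_factors))
  cb <- ar$conformer_b; cb$b_factors <- rep(bf, length(cb$b_factors))
  clean <- calc_density(list(ca, cb), c(case$q_a, case$q_b), ar$topology,
                        case$resolution)
  if (case$noise_alpha > 0) {
    sd_noise <- case$noise_alpha * case$resolution * clean$sigma
    set.seed(case$noise_seed)
    noisy <- clean$values +
      array(rnorm(length(clean$values), 0, sd_noise), dim(clean$values))
    clean <- .grid_set_values(clean, noisy)
  }
  clean
}

#' Emit the full synthetic benchmark
#'
#' Writes one (model, map) pair per archetype x occupancy split x
#' resolution: the multiconformer truth model (altlocs A/B with their
#' occupancies), the single-conformer input model (A only, occupancy 1.0),
#' and the simulated CCP4 map, plus a TSV manifest of case metadata. At
#' the default configuration (4 archetypes, occupancy splits 0.50/0.50,
#' 0.60/0.40, 0.70/0.30, 0.80/0.20, 0.90/0.10, resolutions 0.8-2.5 A in
#' 0.1 A steps) this is 360 pairs. Reruns with the same seed are
#' byte-identical.
#'
#' @param outdir output directory (created if missing).
#' @param archetypes archetype list (default [fixture_ligands()]).
#' @param splits occupancies of the A conformer (B gets the complement).
#' @param resolutions resolution sweep in Angstrom.
#' @param seed base seed; each case derives its own noise seed from it.
#' @param noise_alpha noise scale per Angstrom of d_min.
#' @param write_maps write CCP4 maps (set `FALSE` to emit models and
#'   manifest only, e.g. for a quick dry run).
#' @return the manifest as a data frame (one row per emitted pair),
#'   invisibly also written to `manifest.tsv` in `outdir`.
#' @export
generate_benchmark <- function(outdir,
                               archetypes = fixture_ligands(),
                               splits = c(0.50, 0.60, 0.70, 0.80, 0.90),
                               resolutions = seq(0.8, 2.5, by = 0.1),
                               seed = 1L, noise_alpha = 0.05,
                               write_maps = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  case_no <- 0L
  for (ar in archetypes) {
    for (qa in splits) {
      for (res in resolutions) {
        case_no <- case_no + 1L
        qb <- 1 - qa
        case <- benchmark_case(ar, qa, qb, res,
                               noise_seed = seed + case_no,
                               noise_alpha = noise_alpha)
        tag <- sprintf("%s_qa%02d_res%02.0f", ar$id, round(qa * 100),
                       res * 10)
        truth_file <- file.path(outdir, paste0(tag, "_truth.pdb"))
        input_file <- file.path(outdir, paste0(tag, "_input.pdb"))
        map_file <- file.path(outdir, paste0(tag, ".ccp4"))
        bf <- .benchmark_b_factor(res)
        ca <- ar$conformer_a; ca$occupancy <- qa
        ca$b_factors <- rep(bf, length(ca$b_factors))
        cb <- ar$conformer_b; cb$occupancy <- qb
        cb$b_factors <- rep(bf, length(cb$b_factors))
        .write_ligand_pdb(ar$topology, list(ca, cb), truth_file)
        cin <- ar$conformer_a; cin$altloc <- ""; cin$occupancy <- 1
        cin$b_factors <- rep(bf, length(cin$b_factors))
        .write_ligand_pdb(ar$topology, cin, input_file)
        if (write_maps) write_map(build_truth_map(case), map_file)
        rows[[case_no]] <- data.frame(
          case = tag, archetype = ar$id, q_a = qa, q_b = qb,
          resolution = res, b_factor = bf, noise_alpha = noise_alpha,
          noise_seed = seed + case_no,
          truth_file = basename(truth_file),
          input_file = basename(input_file),
          map_file = if (write_maps) basename(map_file) else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest
}
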
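# Biased conformer sampling: a seeded torsion-driver generator over the
# ligand's rotatable bonds, specialized by strategy-specific constraints,
# plus principal-axis flip sampling and RMSD deduplication.
#
# Every ligand undergoes three preliminary searches (unconstrained, fixed
# terminal atoms, blob); ligands with a side chain of >= 4 atoms add a
# branch search, and side chains of > 30 atoms add a long-chain search.
# Constraints are hard per-conformer postconditions, not averages.

#' Build a sampling plan
#'
#' Decides the total conformer budget and its split across the active
#' search strategies: 5000 conformers for ligands with fewer than 25 heavy
#' atoms, 7000 otherwise (overridable), divided evenly across active
#' strategies with any remainder going to the unconstrained search.
#'
#' @param topology a [ligand_topology()].
#' @param n_override optional total budget override (positive integer).
#' @param flip enable 180-degree principal-axis flip sampling (off by
#'   default; intended for supervised cases).
#' @param seed integer random seed governing all sampling randomness.
#' @return object of class `sampling_plan`: `strategies`, `n`,
#'   `allocation` (named, sums to `n`), `seed`, `flip`.
#' @export
build_plan <- function(topology, n_override = NULL, flip = FALSE,
                       seed = 1L) {
  stopifnot(inherits(topology, "ligand_topology"))
  if (!is.null(n_override) && n_override <= 0)
    stop("n_override must be positive")
  n <- n_override %||% if (topology$heavy_atom_count < 25) 5000L else 7000L
  n <- as.integer(n)
  flags <- classify_topology(topology)
  strategies <- c("unconstrained", "fixed_terminal", "blob")
  if (flags[["branch_search"]]) strategies <- c(strategies, "branch")
  if (flags[["long_chain_search"]]) strategies <- c(strategies, "long_chain")
  if (flip) strategies <- c(strategies, "flip")
  k <- length(strategies)
  alloc <- rep(n %/% k, k)
  alloc[1] <- alloc[1] + n - sum(alloc)   # remainder to unconstrained
  names(alloc) <- strategies
  structure(list(strategies = strategies, n = n, allocation = alloc,
                 seed = as.integer(seed), flip = flip),
            class = "sampling_plan")
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat("Sampling plan:", x$n, "conformers over",
      length(x$strategies), "strategies (seed", paste0(x$seed, ")\n"))
  print(x$allocation)
  invisible(x)
}

# ---- torsion driving ------------------------------------------------------

# Apply torsion deltas (degrees) to a coordinate set. `rbs` is a list of
# rotatable-bond entries (a, b, moving): the `moving` component rotates
# about the a->b axis. Bond lengths and angles are untouched, so 1-2 and
# 1-3 geometry is preserved exactly.
.apply_torsions <- function(xyz, rbs, deltas) {
  for (i in seq_along(rbs)) {
    rb <- rbs[[i]]
    axis <- xyz[rb$b, ] - xyz[rb$a, ]
    xyz[rb$moving, ] <- .rotate_points(xyz[rb$moving, , drop = FALSE],
                                       xyz[rb$a, ], axis, deltas[i])
  }
  xyz
}

# Clash screen: nonbonded heavy-atom pairs (graph distance >= 3) must stay
# above `cut`; this also guarantees geometry-based bond perception cannot
# pick up a spurious bond, so chemistry is preserved through sampling.
.clash_free <- function(xyz, nb_pairs, cut = 2.0) {
  if (nrow(nb_pairs) == 0) return(TRUE)
  d2 <- rowSums((xyz[nb_pairs[, 1], , drop = FALSE] -
                 xyz[nb_pairs[, 2], , drop = FALSE])^2)
  all(d2 > cut^2)
}

# Strategy-specific torsion subsets. For `within`, keep bonds whose moving
# side lies entirely in `allowed` atoms (branch search: only the side
# chain moves). For `avoiding`, keep bonds with a side that excludes every
# `frozen` atom, flipping the moving side if necessary (long-chain search:
# the core moves, the chain stays put).
.bonds_moving_within <- function(rot, allowed) {
  out <- list()
  for (rb in rot) {
    if (all(rb$moving %in% allowed)) out <- c(out, list(rb))
    else if (all(rb$other %in% allowed)) out <- c(out, list(.flip_rb(rb)))
  }
  out
}
.bonds_avoiding <- function(rot, frozen) {
  out <- list()
  for (rb in rot) {
    if (!any(rb$moving %in% frozen)) out <- c(out, list(rb))
    else if (!any(rb$other %in% frozen)) out <- c(out, list(.flip_rb(rb)))
  }
  out
}

.sample_strategy <- function(strategy, n_target, topology, seed_conf,
                             rot, nb_pairs, max_tries = 3L) {
  xyz0 <- seed_conf$xyz
  centroid0 <- .centroid(xyz0)
  blob_R <- sqrt(max(rowSums(sweep(xyz0, 2, centroid0)^2)))
  terms <- .terminal_atoms(topology)
  term_pairs <- if (length(terms) >= 2) t(combn(terms, 2)) else
    matrix(integer(0), ncol = 2)
  term_d0 <- if (nrow(term_pairs)) sqrt(rowSums(
    (xyz0[term_pairs[, 1], , drop = FALSE] -
     xyz0[term_pairs[, 2], , drop = FALSE])^2)) else numeric(0)

  long_members <- unlist(lapply(topology$side_chains, function(sc)
    if (sc$size > 30) sc$members), use.names = FALSE)
  branch_members <- unlist(lapply(topology$side_chains, function(sc)
    if (sc$size >= 4) sc$members), use.names = FALSE)

  rbs <- switch(strategy,
    unconstrained = , fixed_terminal = , blob = rot,
    branch = .bonds_moving_within(rot, branch_members),
    long_chain = .bonds_avoiding(rot, long_members),
    stop("unknown strategy: ", strategy))
  if (length(rot) == 0) rbs <- list()

  accept <- function(xyz) {
    if (!.clash_free(xyz, nb_pairs)) return(NULL)
    if (strategy == "fixed_terminal" && nrow(term_pairs)) {
      d <- sqrt(rowSums((xyz[term_pairs[, 1], , drop = FALSE] -
                         xyz[term_pairs[, 2], , drop = FALSE])^2))
      if (any(abs(d - term_d0) > 0.1)) return(NULL)
    }
    if (strategy == "blob") {
      xyz <- sweep(sweep(xyz, 2, .centroid(xyz)), 2, centroid0, `+`)
      r <- sqrt(rowSums(sweep(xyz, 2, centroid0)^2))
      if (any(r > blob_R + 1e-6)) return(NULL)
    }
    xyz
  }

  out <- vector("list", n_target)
  found <- 0L
  tries <- 0L
  budget <- max_tries * n_target
  while (found < n_target && tries < budget) {
    tries <- tries + 1L
    if (length(rbs) == 0) break
    deltas <- switch(strategy,
      fixed_terminal = {
        amp <- sample(c(5, 10, 20, 40), 1)
        runif(length(rbs), -amp, amp)
      },
      runif(length(rbs), -180, 180))
    xyz <- .apply_torsions(xyz0, rbs, deltas)
    xyz <- accept(xyz)
    if (is.null(xyz)) next
    found <- found + 1L
    out[[found]] <- conformer(xyz, b_factors = seed_conf$b_factors,
                              occupancy = 1, source = strategy)
  }
  out[seq_len(found)]
}

#' Generate a constrained conformer ensemble
#'
#' Runs every strategy in the plan against the seed conformer. Strategy
#' contracts (hard, per conformer): *unconstrained* drives all rotatable
#' bonds freely; *fixed_terminal* preserves every terminal-terminal
#' heavy-atom distance within 0.1 A of the seed; *blob* keeps every atom
#' within the seed's bounding sphere (radius = max distance from the seed
#' centroid to any seed atom, conformers recentered onto the seed
#' centroid); *branch* keeps all core (non-side-chain) atoms exactly at
#' seed coordinates; *long_chain* keeps the long side chain fixed while
#' the core moves; *flip* adds the principal-axis flip family (see
#' [flip_sample()]). B-factors are inherited atom-by-atom from the seed.
#' Sampled geometries are clash-screened so every emitted conformer passes
#' [validate_connectivity()]. The seed conformer itself is always injected
#' into the returned pool (tagged `"input"`). Deterministic given the
#' plan's seed; each strategy draws from its own derived seed, so results
#' do not depend on scheduling.
#'
#' @param plan a [build_plan()] result.
#' @param topology the ligand's [ligand_topology()].
#' @param seed_conformer the input [conformer()].
#' @param cores number of worker processes for strategy-parallel sampling
#'   (capped at 5; results are identical for any value).
#' @return list of [conformer()] objects (the seed first), at most
#'   `plan$n + 1` plus flip outputs.
#' @export
sample_conformers <- function(plan, topology, seed_conformer, cores = 1L) {
  stopifnot(inherits(plan, "sampling_plan"))
  rot <- .rotatable_bonds(topology)
  nb_pairs <- .nonbonded_pairs(topology)
  strategies <- plan$strategies
  cores <- min(max(1L, as.integer(cores)), 5L, length(strategies))

  worker <- function(si) {
    strategy <- strategies[si]
    set.seed(plan$seed + 1000L * si)
    if (strategy == "flip") {
      fl <- flip_sample(seed_conformer)
      head(fl, plan$allocation[[strategy]])
    } else {
      res <- .sample_strategy(strategy, plan$allocation[[strategy]],
                              topology, seed_conformer, rot, nb_pairs)
      if (length(res) == 0 && length(rot) > 0)
        warning("strategy '", strategy,
                "' produced no conformers within its retry budget")
      res
    }
  }
  per_strategy <- if (cores > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(strategies), worker, mc.cores = cores)
  } else {
    lapply(seq_along(strategies), worker)
  }
  seed0 <- seed_conformer
  seed0$source <- "input"
  c(list(seed0), unlist(per_strategy, recursive = FALSE))
}

#' Principal-axis flip sampling
#'
#' Rotates the seed conformer by 180 degrees about each of its three
#' principal axes through the centroid, generating three flipped base
#' conformations, then applies fine rotations of each base flip about its
#' parent axis at -10, -8, ..., -2, +2, ..., +10 degrees (ten per base
#' flip). All outputs share the seed centroid.
#'
#' @param seed_conformer a [conformer()] with at least 3 non-collinear
#'   atoms.
#' @return list of 33 conformers (3 base flips + 30 fine rotations).
#' @export
flip_sample <- function(seed_conformer) {
  xyz <- seed_conformer$xyz
  if (nrow(xyz) < 3) stop("flip sampling needs at least 3 atoms")
  ctr <- .centroid(xyz)
  cen <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(cen), symmetric = TRUE)
  if (ev$values[2] < 1e-8 * max(ev$values[1], 1))
    stop("degenerate (collinear) geometry: principal axes undefined")
  axes <- ev$vectors
  fine <- c(seq(-10, -2, by = 2), seq(2, 10, by = 2))
  out <- list()
  for (ax in 1:3) {
    u <- axes[, ax]
    base <- .rotate_points(xyz, ctr, u, 180)
    out <- c(out, list(conformer(base, seed_conformer$b_factors,
                                 source = "flip_base")))
    for (ang in fine) {
      out <- c(out, list(conformer(.rotate_points(base, ctr, u, ang),
                                   seed_conformer$b_factors,
                                   source = "flip_fine")))
    }
  }
  out
}

#' Remove redundant conformers
#'
#' Conformers closer than `threshold` in-place RMSD (no superposition,
#' fixed atom order) are redundant; within each redundant pair one is
#' removed uniformly at random under the seed. The surviving set contains
#' no pair below the threshold, and the operation is idempotent and
#' deterministic given the seed.
#'
#' @param conformers list of [conformer()] objects sharing one topology.
#' @param threshold RMSD threshold in Angstrom (default 0.2).
#' @param seed integer seed controlling which member of a redundant pair
#'   is dropped.
#' @return the surviving conformer list (original order preserved).
#' @export
deduplicate <- function(conformers, threshold = 0.2, seed = 1L) {
  n <- length(conformers)
  if (n <= 1) return(conformers)
  X <- .conformer_matrix(conformers)
  set.seed(seed)
  ord <- sample.int(n)
  keep_ord <- cpp_dedup_keep(X[ord, , drop = FALSE], threshold)
  keep <- sort(ord[keep_ord])
  conformers[keep]
}
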
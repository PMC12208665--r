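# Ligand topology: the heavy-atom element/bond graph with template bond
# orders, ring systems, side chains and the structural flags that drive
# strategy selection.

#' Construct a ligand topology
#'
#' A `ligand_topology` is the heavy-atom bond graph of a ligand together
#' with template bond orders (from a SMILES template), its ring systems,
#' its acyclic side chains, and a macrocycle flag. All sampling and scoring
#' operates on this object; hydrogens are never part of it.
#'
#' @param elements character vector of element symbols, heavy atoms only.
#' @param bonds two-column integer matrix of 1-based atom index pairs.
#' @param bond_orders numeric vector of bond orders aligned with `bonds`
#'   rows (1, 2, 3; aromatic bonds appear kekulized).
#' @param atom_names optional character vector of canonical atom names.
#' @return An object of class `ligand_topology` with fields `elements`,
#'   `atom_names`, `bonds`, `bond_orders`, `heavy_atom_count`,
#'   `ring_atoms`, `ring_systems`, `ring_sizes`, `side_chains`,
#'   `is_macrocycle`.
#' @examples
#' # n-butane: C1-C2-C3-C4
#' top <- ligand_topology(rep("C", 4), cbind(1:3, 2:4), rep(1, 3))
#' top$heavy_atom_count
#' @export
ligand_topology <- function(elements, bonds, bond_orders = NULL,
                            atom_names = NULL) {
  elements <- .norm_element(elements)
  n <- length(elements)
  if (any(.is_hydrogen(elements)))
    stop("ligand_topology holds heavy atoms only")
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (n > 1 && nrow(bonds) == 0) stop("bond graph is empty")
  if (nrow(bonds) > 0) {
    if (any(bonds < 1L) || any(bonds > n)) stop("bond index out of range")
    # canonical order within each bond row
    bonds <- t(apply(bonds, 1, sort))
    bonds <- matrix(as.integer(bonds), ncol = 2)
  }
  bond_orders <- bond_orders %||% rep(1, nrow(bonds))
  if (length(bond_orders) != nrow(bonds))
    stop("bond_orders length must match bond count")
  g <- .topology_graph(n, bonds)
  if (n > 1 && igraph::components(g)$no != 1L)
    stop("bond graph is not connected")

  rings <- .perceive_rings(g, bonds)
  side <- .perceive_side_chains(g, rings$ring_atoms)

  structure(list(
    elements = elements,
    atom_names = atom_names %||% paste0(elements, seq_len(n)),
    bonds = bonds,
    bond_orders = as.numeric(bond_orders),
    heavy_atom_count = n,
    ring_atoms = rings$ring_atoms,
    ring_systems = rings$ring_systems,
    ring_sizes = rings$ring_sizes,
    side_chains = side,
    is_macrocycle = any(rings$ring_sizes >= 12)
  ), class = "ligand_topology")
}

.topology_graph <- function(n, bonds) {
  igraph::graph_from_edgelist(bonds, directed = FALSE) +
    igraph::vertices(setdiff(seq_len(n), as.vector(bonds)))
}

# Ring atoms = atoms on at least one cycle (endpoints of non-bridge edges).
# Ring sizes are taken as the shortest cycle through each cyclic edge, which
# recovers the ring size exactly for isolated rings (incl. macrocycles) and a
# constituent small-ring size inside fused systems.
.perceive_rings <- function(g, bonds) {
  if (nrow(bonds) == 0 || igraph::ecount(g) == 0)
    return(list(ring_atoms = integer(0), ring_systems = list(),
                ring_sizes = integer(0)))
  br <- igraph::bridges(g)
  cyc_edges <- setdiff(seq_len(igraph::ecount(g)), as.integer(br))
  if (length(cyc_edges) == 0)
    return(list(ring_atoms = integer(0), ring_systems = list(),
                ring_sizes = integer(0)))
  ends <- igraph::ends(g, cyc_edges, names = FALSE)
  ring_atoms <- sort(unique(as.vector(ends)))
  sizes <- vapply(seq_along(cyc_edges), function(i) {
    g2 <- igraph::delete_edges(g, cyc_edges[i])
    d <- igraph::distances(g2, v = ends[i, 1], to = ends[i, 2])[1, 1]
    as.integer(d + 1)
  }, integer(1))
  sub <- igraph::induced_subgraph(g, ring_atoms)
  comp <- igraph::components(sub)
  ring_systems <- split(ring_atoms, comp$membership)
  names(ring_systems) <- NULL
  list(ring_atoms = ring_atoms, ring_systems = ring_systems,
       ring_sizes = sort(unique(sizes)))
}

# A side chain is a maximal connected acyclic heavy-atom subgraph hanging off
# a ring system; for acyclic ligands, a branch hanging off the graph-center
# atom. Each entry records the anchor atom (ring/center atom) and members.
.perceive_side_chains <- function(g, ring_atoms) {
  n <- igraph::vcount(g)
  if (n <= 1) return(list())
  if (length(ring_atoms) > 0) {
    anchor_set <- ring_atoms
  } else {
    ecc <- igraph::eccentricity(g)
    anchor_set <- which(ecc == min(ecc))[1]  # graph center, first on ties
  }
  rest <- setdiff(seq_len(n), anchor_set)
  if (length(rest) == 0) return(list())
  sub <- igraph::induced_subgraph(g, rest)
  comp <- igraph::components(sub)
  lapply(seq_len(comp$no), function(k) {
    members <- rest[comp$membership == k]
    nb <- unique(unlist(igraph::adjacent_vertices(g, members)))
    anchor <- intersect(as.integer(nb), anchor_set)[1]
    list(anchor = anchor, members = members, size = length(members))
  })
}

#' Classify a ligand topology into sampling-strategy flags
#'
#' Decides which specialized conformer searches apply: branch search for
#' ligands carrying an acyclic side chain of at least four heavy atoms,
#' long-chain search when a side chain exceeds 30 atoms, and macrocycle
#' handling when any ring has 12 or more atoms.
#'
#' @param topology a [ligand_topology()].
#' @return named logical vector with elements `branch_search`,
#'   `long_chain_search`, `macrocycle`.
#' @export
classify_topology <- function(topology) {
  stopifnot(inherits(topology, "ligand_topology"))
  sizes <- vapply(topology$side_chains, `[[`, numeric(1), "size")
  c(branch_search = any(sizes >= 4),
    long_chain_search = any(sizes > 30),
    macrocycle = isTRUE(topology$is_macrocycle))
}

#' @export
print.ligand_topology <- function(x, ...) {
  cat("Ligand topology:", x$heavy_atom_count, "heavy atoms,",
      nrow(x$bonds), "bonds\n")
  cat("  elements:", paste(x$elements, collapse = " "), "\n")
  if (length(x$ring_sizes))
    cat("  ring sizes:", paste(x$ring_sizes, collapse = ", "), "\n")
  sc <- vapply(x$side_chains, `[[`, numeric(1), "size")
  if (length(sc)) cat("  side chains:", paste(sc, collapse = ", "), "atoms\n")
  if (x$is_macrocycle) cat("  macrocycle: yes\n")
  fl <- classify_topology(x)
  cat("  strategy flags:", paste(names(fl)[fl], collapse = ", "),
      if (!any(fl)) "(none)", "\n")
  invisible(x)
}

# Rotatable bonds: acyclic (bridge) bonds whose removal moves >= 1 heavy atom
# on each side, i.e. both endpoints have heavy-atom degree >= 2.
.rotatable_bonds <- function(topology) {
  g <- .topology_graph(topology$heavy_atom_count, topology$bonds)
  if (igraph::ecount(g) == 0) return(NULL)
  deg <- igraph::degree(g)
  br <- as.integer(igraph::bridges(g))
  keep <- Filter(function(e) {
    ab <- topology$bonds[e, ]
    deg[ab[1]] >= 2 && deg[ab[2]] >= 2
  }, br)
  if (length(keep) == 0) return(NULL)
  out <- lapply(keep, function(e) {
    ab <- topology$bonds[e, ]
    g2 <- igraph::delete_edges(g, e)
    comp <- igraph::components(g2)$membership
    moving <- which(comp == comp[ab[2]])
    other <- which(comp == comp[ab[1]])
    list(a = ab[1], b = ab[2], moving = moving, other = other)
  })
  out
}

# Flip a rotatable bond so the opposite component moves.
.flip_rb <- function(rb) {
  list(a = rb$b, b = rb$a, moving = rb$other, other = rb$moving)
}

# Pairs of atoms at graph distance >= 3 (used for clash screening: bonded and
# angle-related pairs keep their geometry under torsion driving).
.nonbonded_pairs <- function(topology) {
  g <- .topology_graph(topology$heavy_atom_count, topology$bonds)
  d <- igraph::distances(g)
  idx <- which(upper.tri(d) & d >= 3, arr.ind = TRUE)
  idx
}

# Terminal heavy atoms: degree 1 in the heavy-atom graph.
.terminal_atoms <- function(topology) {
  g <- .topology_graph(topology$heavy_atom_count, topology$bonds)
  which(igraph::degree(g) == 1)
}
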
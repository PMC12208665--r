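# SMILES bond-order templates and geometry-based connectivity checking.
#
# The SMILES string carries the intended chemistry (elements + bond orders);
# coordinates carry only positions. Bonds are perceived from geometry with
# covalent radii and then matched against the template graph by
# element-colored graph isomorphism (VF2); on success the template's bond
# orders are transferred onto the perceived bonds.

# Parse a SMILES into a heavy-atom template: elements + bond list with
# orders (kekulized). Delegates parsing to ChemmineR/ChemmineOB.
.smiles_template <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elements <- .norm_element(sub("_.*$", "", rownames(ab)))
  heavy <- !.is_hydrogen(elements)
  idx_map <- cumsum(heavy)
  bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  orders <- as.numeric(bb[, 3])
  keep <- heavy[bonds[, 1]] & heavy[bonds[, 2]]
  bonds <- cbind(idx_map[bonds[keep, 1]], idx_map[bonds[keep, 2]])
  list(elements = elements[heavy],
       bonds = matrix(as.integer(bonds), ncol = 2),
       orders = orders[keep])
}

# Perceive bonds from geometry: two heavy atoms are bonded when their
# distance is below the sum of covalent radii plus a 0.45 A tolerance.
.perceive_bonds <- function(xyz, elements, tol = 0.45) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  r <- .element_covr(elements)
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(r, r, `+`) + tol
  hit <- which(upper.tri(d) & d < cut & d > 0.4, arr.ind = TRUE)
  matrix(as.integer(hit), ncol = 2)
}

.element_color <- function(elements) {
  as.integer(factor(.norm_element(elements),
                    levels = names(.atomic_number)))
}

# Element-colored graph isomorphism between two bond graphs. Returns the
# mapping from graph 1 vertices to graph 2 vertices, or NULL.
.match_graphs <- function(elements1, bonds1, elements2, bonds2) {
  if (length(elements1) != length(elements2)) return(NULL)
  if (nrow(bonds1) != nrow(bonds2)) return(NULL)
  if (!identical(sort(.norm_element(elements1)),
                 sort(.norm_element(elements2)))) return(NULL)
  g1 <- .topology_graph(length(elements1), bonds1)
  g2 <- .topology_graph(length(elements2), bonds2)
  maps <- tryCatch(
    igraph::subgraph_isomorphisms(
      pattern = g1, target = g2, method = "vf2",
      vertex.color1 = .element_color(elements1),
      vertex.color2 = .element_color(elements2)),
    error = function(e) list())
  if (length(maps) == 0) return(NULL)
  as.integer(maps[[1]])
}

#' Validate ligand connectivity against a SMILES template
#'
#' Re-perceives bonds from the conformer's geometry (covalent-radius
#' criterion) and attempts to assign the SMILES template's bond orders by
#' element-colored graph matching. Succeeds only when the geometry still
#' encodes the intended chemical connectivity; a broken bond, a fused pair
#' of atoms or any other corrupted geometry makes the match fail.
#'
#' @param conf a [conformer()].
#' @param topology the ligand's [ligand_topology()].
#' @param smiles optional SMILES string; defaults to the template already
#'   stored in the topology's bond graph (the topology itself is used as
#'   the template when no SMILES is given).
#' @return `TRUE` if the geometry supports the template connectivity,
#'   `FALSE` otherwise. Never raises on a failed match.
#' @export
validate_connectivity <- function(conf, topology, smiles = NULL) {
  tmpl <- if (!is.null(smiles)) {
    tryCatch(.smiles_template(smiles), error = function(e) NULL)
  } else {
    list(elements = topology$elements, bonds = topology$bonds,
         orders = topology$bond_orders)
  }
  if (is.null(tmpl)) return(FALSE)
  ok <- tryCatch({
    perceived <- .perceive_bonds(conf$xyz, topology$elements)
    !is.null(.match_graphs(tmpl$elements, tmpl$bonds,
                           topology$elements, perceived))
  }, error = function(e) FALSE)
  isTRUE(ok)
}

# Build a ligand_topology from observed coordinates + elements, taking bond
# orders from the SMILES template. Errors when composition or connectivity
# disagrees with the template.
.topology_from_template <- function(xyz, elements, atom_names, smiles) {
  tmpl <- .smiles_template(smiles)
  if (!identical(sort(.norm_element(elements)), sort(tmpl$elements)))
    stop("SMILES/coordinate atom-composition mismatch: coordinates have [",
         paste(sort(.norm_element(elements)), collapse = " "),
         "], SMILES has [", paste(sort(tmpl$elements), collapse = " "), "]")
  perceived <- .perceive_bonds(xyz, elements)
  mp <- .match_graphs(tmpl$elements, tmpl$bonds, elements, perceived)
  if (is.null(mp))
    stop("cannot assign SMILES bond orders: geometry-derived connectivity ",
         "does not match the template")
  # order per perceived bond, transferred through the template mapping
  key <- function(b) paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  mapped <- cbind(mp[tmpl$bonds[, 1]], mp[tmpl$bonds[, 2]])
  orders <- tmpl$orders[match(key(perceived), key(mapped))]
  ligand_topology(elements, perceived, orders, atom_names = atom_names)
}
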
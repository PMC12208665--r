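# Structure I/O: load a ligand from PDB/PDBx-mmCIF, write multiconformer
# ligands, and embed a fitted model back into the untouched full structure.
# All parsing is delegated to bio3d.

.read_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  if (is_cif) bio3d::read.cif(path, rm.alt = FALSE)
  else bio3d::read.pdb(path, rm.alt = FALSE)
}

.parse_selection <- function(selection) {
  if (is.list(selection)) {
    return(list(chain = as.character(selection$chain),
                resno = as.integer(selection$resno)))
  }
  parts <- strsplit(as.character(selection), ",", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("selection must be \"CHAIN,RESNUM\", e.g. \"A,101\"")
  list(chain = trimws(parts[1]), resno = as.integer(trimws(parts[2])))
}

.atom_elements <- function(atom) {
  ele <- .norm_element(atom$elesy %||% rep("", nrow(atom)))
  miss <- is.na(ele) | !(ele %in% names(.atomic_number))
  if (any(miss)) {
    # fall back to the atom name with digits and altloc noise stripped
    guess <- toupper(gsub("[^A-Za-z].*$", "", trimws(atom$elety[miss])))
    two <- guess %in% names(.atomic_number) & nchar(guess) == 2
    one <- substr(guess, 1, 1)
    ele[miss] <- ifelse(two, guess, one)
  }
  ele
}

#' Load a ligand from a structure file with a SMILES bond-order template
#'
#' Reads a PDB or PDBx/mmCIF file, extracts one ligand residue by chain and
#' residue number, drops hydrogens, perceives bonds from the deposited
#' geometry and assigns bond orders from the SMILES template. If the residue
#' carries alternate locations, the 'A' coordinates are kept (with a
#' warning) and the deposited occupancy is preserved.
#'
#' @param structure_file path to a PDB or PDBx/mmCIF file.
#' @param selection ligand selection, `"CHAIN,RESNUM"` (as on the command
#'   line) or `list(chain =, resno =)`.
#' @param smiles SMILES string for the ligand; the heavy-atom composition
#'   must match the selected residue.
#' @return list with `topology` (a [ligand_topology()]) and `conformer`
#'   (a [conformer()]).
#' @export
load_ligand <- function(structure_file, selection, smiles) {
  pdb <- .read_structure(structure_file)
  sel <- .parse_selection(selection)
  atom <- pdb$atom
  hit <- atom$chain == sel$chain & atom$resno == sel$resno
  hit[is.na(hit)] <- FALSE
  if (!any(hit))
    stop("selection not found: no residue ", sel$resno,
         " in chain ", sel$chain)
  lig <- atom[hit, , drop = FALSE]
  alts <- setdiff(unique(trimws(lig$alt %||% "")), c("", NA))
  if (length(alts) > 0) {
    warning("ligand has alternate locations (",
            paste(alts, collapse = ", "), "); keeping 'A'")
    keep_alt <- trimws(lig$alt) %in% c("", alts[order(alts)][1])
    lig <- lig[keep_alt, , drop = FALSE]
  }
  ele <- .atom_elements(lig)
  heavy <- !.is_hydrogen(ele)
  lig <- lig[heavy, , drop = FALSE]
  ele <- ele[heavy]
  if (nrow(lig) == 0) stop("selection contains no heavy atoms")
  xyz <- as.matrix(lig[, c("x", "y", "z")])
  topology <- .topology_from_template(xyz, ele, trimws(lig$elety), smiles)
  b <- as.numeric(lig$b)
  b[!is.finite(b) | b <= 0] <- 20
  occ <- as.numeric(lig$o)
  occ[!is.finite(occ)] <- 1
  cf <- conformer(xyz, b_factors = b, occupancy = min(1, max(0, occ[1])),
                  altloc = "", source = "input")
  list(topology = topology, conformer = cf)
}

# Write one or more conformers of a ligand as a (multiconformer) PDB file.
# Conformers get altlocs and their own occupancies; a single conformer with
# empty altloc is written without an altloc column.
.write_ligand_pdb <- function(topology, conformers, file,
                              resid = "LIG", chain = "A", resno = 1L) {
  confs <- if (inherits(conformers, "conformer")) list(conformers)
           else conformers
  n <- topology$heavy_atom_count
  xyz <- do.call(rbind, lapply(confs, `[[`, "xyz"))
  alt <- unlist(lapply(confs, function(cf)
    rep(if (nzchar(cf$altloc)) cf$altloc else "", n)))
  o <- unlist(lapply(confs, function(cf) rep(cf$occupancy, n)))
  b <- unlist(lapply(confs, `[[`, "b_factors"))
  bio3d::write.pdb(file = file, xyz = as.vector(t(xyz)),
                   type = rep("HETATM", nrow(xyz)),
                   resno = rep(resno, nrow(xyz)),
                   resid = rep(resid, nrow(xyz)),
                   eleno = seq_len(nrow(xyz)),
                   elety = rep(topology$atom_names, length(confs)),
                   chain = rep(chain, nrow(xyz)),
                   alt = alt, o = o, b = b,
                   elesy = rep(topology$elements, length(confs)))
  invisible(file)
}

# Read a (possibly multiconformer) ligand PDB written by .write_ligand_pdb
# back into a list of conformers.
.read_ligand_pdb <- function(file, selection = NULL) {
  pdb <- bio3d::read.pdb(file, rm.alt = FALSE)
  atom <- pdb$atom
  if (!is.null(selection)) {
    sel <- .parse_selection(selection)
    atom <- atom[atom$chain == sel$chain & atom$resno == sel$resno, ,
                 drop = FALSE]
  }
  ele <- .atom_elements(atom)
  atom <- atom[!.is_hydrogen(ele), , drop = FALSE]
  av <- trimws(atom$alt %||% rep("", nrow(atom)))
  av[is.na(av)] <- ""
  alts <- sort(unique(av))
  lapply(alts, function(a) {
    sub <- atom[av == a, , drop = FALSE]
    conformer(as.matrix(sub[, c("x", "y", "z")]),
              b_factors = pmax(as.numeric(sub$b), 1e-3),
              occupancy = as.numeric(sub$o[1]),
              altloc = a, source = "file")
  })
}

# Embed fitted ligand conformers into the untouched full structure: every
# atom outside the selected residue is carried through unchanged; the
# ligand rows are replaced by one copy per conformer with altloc labels and
# occupancies.
.embed_model <- function(structure_file, selection, topology, conformers,
                         file) {
  pdb <- .read_structure(structure_file)
  sel <- .parse_selection(selection)
  atom <- pdb$atom
  hit <- atom$chain == sel$chain & atom$resno == sel$resno
  hit[is.na(hit)] <- FALSE
  keep <- atom[!hit, , drop = FALSE]
  lig0 <- atom[hit, , drop = FALSE]
  resid <- lig0$resid[1]
  lig_rows <- do.call(rbind, lapply(conformers, function(cf) {
    data.frame(type = "HETATM", eleno = 0L,
               elety = topology$atom_names,
               alt = if (nzchar(cf$altloc)) cf$altloc else "",
               resid = resid, chain = sel$chain, resno = sel$resno,
               insert = "", x = cf$xyz[, 1], y = cf$xyz[, 2],
               z = cf$xyz[, 3], o = cf$occupancy, b = cf$b_factors,
               segid = "", elesy = topology$elements, charge = "",
               stringsAsFactors = FALSE)
  }))
  cols <- intersect(names(keep), names(lig_rows))
  all_atom <- rbind(keep[, cols, drop = FALSE],
                    lig_rows[, cols, drop = FALSE])
  all_atom$eleno <- seq_len(nrow(all_atom))
  xyz <- as.vector(t(as.matrix(all_atom[, c("x", "y", "z")])))
  bio3d::write.pdb(file = file, xyz = xyz, type = all_atom$type,
                   resno = all_atom$resno, resid = all_atom$resid,
                   eleno = all_atom$eleno, elety = all_atom$elety,
                   chain = all_atom$chain, alt = all_atom$alt,
                   o = all_atom$o, b = all_atom$b, elesy = all_atom$elesy,
                   insert = all_atom$insert)
  invisible(file)
}
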
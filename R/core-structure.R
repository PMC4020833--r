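#' Construct a structure model
#'
#' A `StructureModel` is the minimal static description of a protein chain
#' used by all analysis stages: atom identities, Cartesian positions (nm),
#' hydrogen-bond roles and the covalent bonds needed to attach hydrogens to
#' their donor heavy atoms.
#'
#' @param atoms data.frame with columns `atom_id` (integer, unique),
#'   `atom_name`, `element`, `residue_number` (integer, non-decreasing),
#'   `residue_name`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in nm.
#' @param bonds two-column integer matrix of bonded `atom_id` pairs, or
#'   `NULL` to infer hydrogen attachments from geometry.
#' @param hbond_roles character vector per atom, values in
#'   `c("donor-heavy", "acceptor", "hydrogen", "none")`, or `NULL` to assign
#'   from elements and bonds (N/O/S with an attached hydrogen are donors,
#'   oxygens and hydrogen-free nitrogens are acceptors).
#' @return object of class `StructureModel`.
#' @export
structure_model <- function(atoms, xyz, bonds = NULL, hbond_roles = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) == nrow(xyz), ncol(xyz) == 3)
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$residue_number <- as.integer(atoms$residue_number)
  if (anyDuplicated(atoms$atom_id))
    trj_error("trajcomm_integrity_error", "duplicate atom_id: %s",
              paste(unique(atoms$atom_id[duplicated(atoms$atom_id)]), collapse = ", "))
  if (is.unsorted(atoms$residue_number))
    trj_error("trajcomm_integrity_error",
              "residue_number must be non-decreasing in atom order")
  if (!all(is.finite(xyz)))
    trj_error("trajcomm_integrity_error", "non-finite atom positions")
  xyz <- unname(as.matrix(xyz))

  has_h <- any(atoms$element == "H")
  if (is.null(bonds) && has_h) bonds <- infer_h_bonds(atoms, xyz)
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (is.null(hbond_roles)) hbond_roles <- assign_hbond_roles(atoms, bonds)
  stopifnot(all(hbond_roles %in% c("donor-heavy", "acceptor", "hydrogen", "none")))

  # each flagged hydrogen must sit on exactly one donor-heavy atom
  id2row <- stats::setNames(seq_len(nrow(atoms)), atoms$atom_id)
  for (h in which(hbond_roles == "hydrogen")) {
    hid <- atoms$atom_id[h]
    partners <- c(bonds[bonds[, 1] == hid, 2], bonds[bonds[, 2] == hid, 1])
    donors <- partners[hbond_roles[id2row[as.character(partners)]] == "donor-heavy"]
    if (length(donors) != 1L)
      trj_error("trajcomm_integrity_error",
                "hydrogen atom %d bonded to %d donor-heavy atoms (need exactly 1)",
                hid, length(donors))
  }

  structure(list(atoms = atoms, xyz = xyz, bonds = bonds,
                 hbond_roles = hbond_roles, has_hydrogens = has_h),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel: %d atoms, residues %d-%d, hydrogens %s\n",
              nrow(x$atoms), min(x$atoms$residue_number),
              max(x$atoms$residue_number),
              if (x$has_hydrogens) "present" else "absent"))
  invisible(x)
}

n_atoms <- function(s) nrow(s$atoms)

# attach each hydrogen to the nearest heavy atom within 1.2 Angstrom
infer_h_bonds <- function(atoms, xyz) {
  hs <- which(atoms$element == "H")
  heavy <- which(atoms$element != "H")
  out <- matrix(integer(0), ncol = 2)
  for (h in hs) {
    d2 <- colSums((t(xyz[heavy, , drop = FALSE]) - xyz[h, ])^2)
    j <- which.min(d2)
    if (d2[j] <= ang2nm(1.2)^2)
      out <- rbind(out, c(atoms$atom_id[heavy[j]], atoms$atom_id[h]))
  }
  out
}

assign_hbond_roles <- function(atoms, bonds) {
  roles <- rep("none", nrow(atoms))
  id2row <- stats::setNames(seq_len(nrow(atoms)), atoms$atom_id)
  roles[atoms$element == "H"] <- "hydrogen"
  h_ids <- atoms$atom_id[atoms$element == "H"]
  bonded_to_h <- unique(c(bonds[bonds[, 2] %in% h_ids, 1],
                          bonds[bonds[, 1] %in% h_ids, 2]))
  bonded_to_h <- setdiff(bonded_to_h, h_ids)
  don <- atoms$element %in% c("N", "O", "S") & atoms$atom_id %in% bonded_to_h
  roles[don] <- "donor-heavy"
  acc <- (atoms$element == "O" | (atoms$element == "N" & !don)) & !don
  roles[acc & roles == "none"] <- "acceptor"
  # oxygens that also carry a hydrogen stay donors; fine for backbone models
  roles
}

#' Read a structure file
#'
#' Supported dialects: `pdb` (fixed-column ATOM/HETATM records, author residue
#' numbering preserved verbatim, coordinates converted Angstrom to nm) and
#' `internal-json` (the package's own lossless serialization).
#'
#' @param path file path.
#' @param dialect `"pdb"` or `"internal-json"`.
#' @return [structure_model()] object.
#' @export
load_structure <- function(path, dialect = c("pdb", "internal-json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    trj_error("trajcomm_io_error", "file not found: %s", path)
  if (dialect == "internal-json") return(read_structure_json(path))
  read_pdb(path)
}

read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM  |HETATM)", lines)
  recs <- lines[keep]
  lineno <- which(keep)
  if (length(recs) == 0L)
    trj_error("trajcomm_format_error", "no ATOM/HETATM records in %s", path)
  fx <- function(rec, a, b) substr(rec, a, b)
  n <- length(recs)
  serial <- suppressWarnings(as.integer(fx(recs, 7, 11)))
  name <- trimws(fx(recs, 13, 16))
  resname <- trimws(fx(recs, 18, 20))
  resseq <- suppressWarnings(as.integer(fx(recs, 23, 26)))
  x <- suppressWarnings(as.numeric(fx(recs, 31, 38)))
  y <- suppressWarnings(as.numeric(fx(recs, 39, 46)))
  z <- suppressWarnings(as.numeric(fx(recs, 47, 54)))
  elem <- trimws(fx(recs, 77, 78))
  bad <- which(is.na(serial) | is.na(resseq) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    trj_error("trajcomm_format_error", "unparsable ATOM record at line %d of %s",
              lineno[bad[1]], path)
  elem[elem == ""] <- vapply(name[elem == ""], function(nm) {
    nm <- gsub("[0-9]", "", nm)
    substr(nm, 1, 1)
  }, character(1))
  atoms <- data.frame(atom_id = serial, atom_name = name, element = elem,
                      residue_number = resseq, residue_name = resname,
                      stringsAsFactors = FALSE)
  structure_model(atoms, ang2nm(cbind(x, y, z)))
}

#' Write a structure as PDB
#'
#' Coordinates are converted nm to Angstrom at %8.3f precision (the PDB
#' fixed-column limit); everything else round-trips losslessly.
#'
#' @param structure a `StructureModel`.
#' @param path output file path.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  xyz <- nm2ang(structure$xyz)
  recs <- sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                  a$atom_id,
                  ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name),
                  a$residue_name, a$residue_number,
                  xyz[, 1], xyz[, 2], xyz[, 3], a$element)
  writeLines(c(recs, "TER", "END"), path)
  invisible(path)
}

#' @rdname write_structure_pdb
#' @export
write_structure_json <- function(structure, path) {
  jsonlite::write_json(
    list(atoms = structure$atoms,
         xyz = structure$xyz,
         bonds = structure$bonds,
         hbond_roles = structure$hbond_roles),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

read_structure_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  bonds <- o$bonds
  if (length(bonds) == 0) bonds <- matrix(integer(0), ncol = 2)
  structure_model(as.data.frame(o$atoms), as.matrix(o$xyz),
                  bonds = as.matrix(bonds), hbond_roles = o$hbond_roles)
}

# named atom-index selections used throughout
BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Atom selections
#'
#' @param structure a `StructureModel`.
#' @param selection `"all"`, `"backbone"` (N, CA, C, O), `"calpha"` or
#'   `"heavy"` (non-hydrogen).
#' @param residues optional integer vector restricting to residue numbers.
#' @return integer vector of atom row indices.
#' @export
select_atoms <- function(structure, selection = c("all", "backbone", "calpha", "heavy"),
                         residues = NULL) {
  selection <- match.arg(selection)
  a <- structure$atoms
  idx <- switch(selection,
    all = seq_len(nrow(a)),
    backbone = which(a$atom_name %in% BACKBONE_NAMES),
    calpha = which(a$atom_name == "CA"),
    heavy = which(a$element != "H"))
  if (!is.null(residues)) idx <- idx[a$residue_number[idx] %in% residues]
  idx
}
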
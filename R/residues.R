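#' @keywords internal
"_PACKAGE"

# Canonical heavy-atom order for the 20 standard amino acids (PDB v3 naming).
# Mainchain atoms come first; everything after O is sidechain. OXT is handled
# separately (terminal oxygen, never part of a template).
.aa_atom_order <- list(
  ALA = c("N", "CA", "C", "O", "CB"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  CYS = c("N", "CA", "C", "O", "CB", "SG"),
  GLN = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
  GLY = c("N", "CA", "C", "O"),
  HIS = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
  LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  MET = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
  PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("N", "CA", "C", "O", "CB", "CG", "CD"),
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  THR = c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
  TRP = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2",
          "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
          "CZ", "OH"),
  VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2")
)

.mainchain_atoms <- c("N", "CA", "C", "O")

# Chemically indistinguishable atom pairs within a residue. Each entry is a
# list of pairs that must be swapped *together* (ring flips swap both pairs).
.equivalent_atom_groups <- list(
  ASP = list(list(c("OD1", "OD2"))),
  GLU = list(list(c("OE1", "OE2"))),
  ARG = list(list(c("NH1", "NH2"))),
  LEU = list(list(c("CD1", "CD2"))),
  VAL = list(list(c("CG1", "CG2"))),
  PHE = list(list(c("CD1", "CD2"), c("CE1", "CE2"))),
  TYR = list(list(c("CD1", "CD2"), c("CE1", "CE2")))
)

#' Sidechain atom names of a standard residue
#'
#' Heavy atoms excluding the mainchain set N, CA, C, O (and OXT). Hydrogens
#' are ignored throughout the package.
#'
#' @param residue_name Three-letter amino-acid code (e.g. `"SER"`).
#' @return Character vector of atom names, in canonical PDB order.
#' @export
sidechain_atoms <- function(residue_name) {
  ord <- .aa_atom_order[[toupper(residue_name)]]
  if (is.null(ord)) {
    stop("unknown residue name: ", residue_name, call. = FALSE)
  }
  setdiff(ord, .mainchain_atoms)
}

#' Mainchain atom names
#'
#' @return `c("N", "CA", "C", "O")`.
#' @export
mainchain_atoms <- function() .mainchain_atoms

# Order atom names canonically within one residue; unknown names sort last,
# alphabetically, so non-standard residues still serialize deterministically.
.canonical_atom_order <- function(residue_name, atom_names) {
  ord <- .aa_atom_order[[toupper(residue_name)]]
  if (is.null(ord)) {
    return(atom_names[order(atom_names)])
  }
  idx <- match(atom_names, ord)
  idx[is.na(idx)] <- length(ord) + rank(atom_names[is.na(idx)])
  atom_names[order(idx)]
}

# All admissible atom-name mappings for one residue given the required
# template atom names: the identity plus every combination of equivalent-group
# flips that touches at least one required atom. Returns a list of named
# character vectors mapping template atom name -> protein atom name.
.atom_name_variants <- function(residue_name, atom_names) {
  identity_map <- stats::setNames(atom_names, atom_names)
  groups <- .equivalent_atom_groups[[toupper(residue_name)]]
  if (is.null(groups)) {
    return(list(identity_map))
  }
  variants <- list(identity_map)
  for (grp in groups) {
    flipped <- identity_map
    touched <- FALSE
    for (pair in grp) {
      for (k in 1:2) {
        i <- which(atom_names == pair[k])
        if (length(i)) {
          flipped[i] <- pair[3 - k]
          touched <- TRUE
        }
      }
    }
    if (touched && !identical(unname(flipped), unname(identity_map))) {
      variants <- c(variants, list(flipped))
    }
  }
  variants
}
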
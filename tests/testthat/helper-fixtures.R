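# Fixture builders shared across tests. The residue table here is written
# out independently of the package's internal tables so that atom-selection
# tests check against a second source.

# heavy atoms of a few standard residues, PDB v3 names and order
fixture_residue_atoms <- list(
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  GLY = c("N", "CA", "C", "O"),
  HIS = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  TYR = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
          "CZ", "OH"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  THR = c("N", "CA", "C", "O", "CB", "OG1", "CG2")
)

# a full residue with every heavy atom at distinct jittered positions
fixture_full_residue <- function(resname, resno, chain = "A",
                                 origin = c(0, 0, 0)) {
  nm <- fixture_residue_atoms[[resname]]
  k <- length(nm)
  data.frame(
    atom_name = nm,
    residue_name = resname,
    residue_number = resno,
    insert = "",
    chain_id = chain,
    x = origin[1] + seq_len(k) * 1.3,
    y = origin[2] + (seq_len(k) %% 3) * 1.1,
    z = origin[3] + (seq_len(k) %% 2) * 0.9,
    stringsAsFactors = FALSE
  )
}

# a protein holding the template's residues at the given site coordinates
# (one sidechain atom per residue, as produced by make_template)
fixture_protein_from_coords <- function(template, coords,
                                        structure_id = "TESTP",
                                        resno_offset = 0L) {
  a <- template$atoms
  atoms <- data.frame(
    atom_name = a$atom_name,
    residue_name = a$residue_name,
    residue_number = a$residue_number + resno_offset,
    insert = "",
    chain_id = a$chain_id,
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
    stringsAsFactors = FALSE
  )
  protein_structure(structure_id, atoms)
}

# a random proper rotation for tests
fixture_rotation <- function() {
  q <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
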
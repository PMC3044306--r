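# Reading PDB structures and building/serializing active-site templates.
#
# A ProteinStructure is a list(structure_id, atoms) where atoms is a
# data.frame with one row per heavy atom: atom_name, residue_name,
# residue_number, insert, chain_id, x, y, z. Residue identity is the tuple
# (chain_id, residue_number, insert, residue_name).

.residue_id <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_number, atoms$insert,
        atoms$residue_name, sep = "|")
}

#' Read a PDB-format protein structure
#'
#' Parses ATOM/HETATM records of a PDB file (first model only for multi-model
#' entries). Alternate locations other than blank or 'A' are dropped;
#' insertion codes are kept as part of residue identity.
#'
#' @param path Path to a PDB-format text file.
#' @param structure_id Identifier for the structure; defaults to the file
#'   name without extension.
#' @return A `protein_structure` object: list with `structure_id`, `atoms`
#'   (data.frame) and `residues` (split of row indices by residue).
#' @export
read_pdb <- function(path, structure_id = NULL) {
  if (!file.exists(path)) {
    stop("PDB file not found: ", path, call. = FALSE)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) {
      stop("cannot parse PDB file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("empty structure: no ATOM/HETATM records in '", path, "'",
         call. = FALSE)
  }
  alt <- at$alt
  alt[is.na(alt)] <- ""
  at <- at[alt %in% c("", "A"), , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("empty structure after altloc filtering: '", path, "'",
         call. = FALSE)
  }
  ins <- at$insert
  ins[is.na(ins)] <- ""
  chain <- at$chain
  chain[is.na(chain)] <- " "
  atoms <- data.frame(
    atom_name = at$elety,
    residue_name = at$resid,
    residue_number = at$resno,
    insert = ins,
    chain_id = chain,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in '", path, "'", call. = FALSE)
  }
  if (is.null(structure_id)) {
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  }
  protein_structure(structure_id, atoms)
}

#' Construct a protein structure from an atom table
#'
#' @param structure_id Structure identifier string.
#' @param atoms data.frame with columns atom_name, residue_name,
#'   residue_number, insert, chain_id, x, y, z.
#' @return A `protein_structure` object.
#' @export
protein_structure <- function(structure_id, atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  if (is.null(atoms$insert)) atoms$insert <- ""
  rid <- .residue_id(atoms)
  structure(
    list(
      structure_id = structure_id,
      atoms = atoms,
      residues = split(seq_len(nrow(atoms)), factor(rid, levels = unique(rid)))
    ),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure", x$structure_id, "-", nrow(x$atoms), "atoms,",
      length(x$residues), "residues\n")
  invisible(x)
}

.valid_roles <- c("catalytic_site", "cofactor_binding_site", "modified",
                  "mainchain_catalytic")

#' Build an active-site template from a structure
#'
#' Selects atoms from annotated active-site residues according to their role:
#' catalytic-site and modified residues contribute sidechain atoms only,
#' cofactor-binding-site residues contribute all atoms, and mainchain
#' catalytic residues contribute only N, CA, C, O. Glycine annotated as a
#' catalytic-site residue has no sidechain and is treated as a mainchain
#' catalytic residue (with a warning).
#'
#' Atoms are ordered by the order of `residue_specs`, then by the canonical
#' PDB atom order within each residue; this order defines the atom
#' correspondence used by every downstream measurement.
#'
#' @param structure A `protein_structure`.
#' @param residue_specs data.frame (or list coercible to one) with columns
#'   `chain`, `residue_number`, `role` and optionally `insert`.
#' @param template_id Identifier for the template.
#' @param function_label Reaction-class label carried by the template.
#' @return A `site_template` object.
#' @export
build_template <- function(structure, residue_specs,
                           template_id = structure$structure_id,
                           function_label = "") {
  stopifnot(inherits(structure, "protein_structure"))
  specs <- as.data.frame(residue_specs, stringsAsFactors = FALSE)
  if (is.null(specs$insert)) specs$insert <- ""
  if (!all(specs$role %in% .valid_roles)) {
    stop("unknown residue role(s): ",
         paste(setdiff(specs$role, .valid_roles), collapse = ", "),
         call. = FALSE)
  }
  at <- structure$atoms
  rows <- list()
  for (i in seq_len(nrow(specs))) {
    sel <- at$chain_id == specs$chain[i] &
      at$residue_number == specs$residue_number[i] &
      at$insert == specs$insert[i]
    if (!any(sel)) {
      stop("missing residue: chain ", specs$chain[i], " number ",
           specs$residue_number[i], " not found in structure '",
           structure$structure_id, "'", call. = FALSE)
    }
    res_atoms <- at[sel, , drop = FALSE]
    resname <- res_atoms$residue_name[1L]
    role <- specs$role[i]
    if (role == "catalytic_site" && toupper(resname) == "GLY") {
      warning("GLY has no sidechain; treating catalytic_site residue ",
              specs$chain[i], " ", specs$residue_number[i],
              " as mainchain_catalytic", call. = FALSE)
      role <- "mainchain_catalytic"
    }
    keep <- switch(role,
      catalytic_site = ,
      modified = setdiff(res_atoms$atom_name,
                         c(.mainchain_atoms, "OXT")),
      cofactor_binding_site = setdiff(res_atoms$atom_name, "OXT"),
      mainchain_catalytic = intersect(res_atoms$atom_name, .mainchain_atoms)
    )
    keep <- .canonical_atom_order(resname, intersect(res_atoms$atom_name, keep))
    sel_rows <- res_atoms[match(keep, res_atoms$atom_name), , drop = FALSE]
    if (nrow(sel_rows) == 0L) {
      stop("residue ", specs$chain[i], " ", specs$residue_number[i],
           " contributes no atoms under role '", role, "'", call. = FALSE)
    }
    sel_rows$role <- role
    rows[[i]] <- sel_rows
  }
  atoms <- do.call(rbind, rows)
  site_template(template_id, function_label,
                atoms[, c("chain_id", "residue_number", "insert",
                          "residue_name", "atom_name", "role",
                          "x", "y", "z")])
}

#' Construct a template from an atom table
#'
#' @param template_id Template identifier.
#' @param function_label Reaction-class label.
#' @param atoms data.frame with columns chain_id, residue_number, insert,
#'   residue_name, atom_name, role, x, y, z, in the fixed template order.
#' @return A `site_template` object.
#' @export
site_template <- function(template_id, function_label, atoms) {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) < 2L) {
    stop("degenerate template: fewer than 2 atoms", call. = FALSE)
  }
  if (!all(atoms$role %in% .valid_roles)) {
    stop("template format error: unknown role token", call. = FALSE)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) {
    stop("template coordinates must be finite", call. = FALSE)
  }
  rownames(atoms) <- NULL
  structure(
    list(template_id = template_id, function_label = function_label,
         atoms = atoms),
    class = "site_template"
  )
}

#' Number of atoms in a template
#' @param template A `site_template`.
#' @return Integer atom count (m_k).
#' @export
template_size <- function(template) nrow(template$atoms)

#' Template coordinates as a matrix
#' @param template A `site_template`.
#' @return m x 3 numeric matrix of coordinates (Angstrom).
#' @export
template_coords <- function(template) {
  unname(as.matrix(template$atoms[, c("x", "y", "z")]))
}

#' @export
print.site_template <- function(x, ...) {
  cat("site_template", x$template_id, "-", nrow(x$atoms), "atoms,",
      length(unique(.residue_id(x$atoms))), "residues; function:",
      x$function_label, "\n")
  invisible(x)
}

#' Write a template to a text file
#'
#' The format is line-oriented: a version header, `template_id` and
#' `function_label` lines, then one `atom` line per template atom carrying
#' chain, residue number, insertion code (`-` if blank), residue name, atom
#' name, role and coordinates. The file round-trips losslessly, including
#' atom order.
#'
#' @param template A `site_template`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "site_template"))
  a <- template$atoms
  ins <- ifelse(a$insert == "" | is.na(a$insert), "-", a$insert)
  lines <- c(
    "# sitematch template v1",
    paste("template_id", template$template_id),
    paste("function_label",
          if (nzchar(template$function_label)) template$function_label else "-"),
    sprintf("atom %s %d %s %s %s %s %.6f %.6f %.6f",
            a$chain_id, a$residue_number, ins, a$residue_name,
            a$atom_name, a$role, a$x, a$y, a$z)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a template written by [write_template()]
#'
#' @param path Path to a template file.
#' @return A `site_template`.
#' @export
read_template <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !identical(lines[1L], "# sitematch template v1")) {
    stop("template format error: missing or unknown version header",
         call. = FALSE)
  }
  get_field <- function(key) {
    hit <- grep(paste0("^", key, " "), lines, value = TRUE)
    if (length(hit) != 1L) {
      stop("template format error: expected exactly one '", key, "' line",
           call. = FALSE)
    }
    sub(paste0("^", key, " "), "", hit)
  }
  template_id <- get_field("template_id")
  function_label <- get_field("function_label")
  if (function_label == "-") function_label <- ""
  atom_lines <- grep("^atom ", lines, value = TRUE)
  parts <- strsplit(atom_lines, "[[:space:]]+")
  if (any(vapply(parts, length, 1L) != 10L)) {
    stop("template format error: malformed atom line", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  atoms <- data.frame(
    chain_id = m[, 2L],
    residue_number = as.integer(m[, 3L]),
    insert = ifelse(m[, 4L] == "-", "", m[, 4L]),
    residue_name = m[, 5L],
    atom_name = m[, 6L],
    role = m[, 7L],
    x = as.numeric(m[, 8L]),
    y = as.numeric(m[, 9L]),
    z = as.numeric(m[, 10L]),
    stringsAsFactors = FALSE
  )
  site_template(template_id, function_label, atoms)
}
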
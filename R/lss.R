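# TESS-style local site search: enumerate candidate local sites in a protein
# matching a template's residue/atom composition, prune by pairwise-distance
# compatibility, and keep candidates passing the RMSD cutoff.
#
# The published searches (TESS/JESS) use geometric hashing as an index; at
# the scales handled here a constrained depth-first enumeration with a sound
# distance-compatibility bound returns the identical site set.

#' Construct a local site
#'
#' An ordered atom set in a target protein, aligned index-by-index to a
#' template's atoms.
#'
#' @param structure_id Identifier of the source structure.
#' @param template_id Identifier of the matching template.
#' @param atoms data.frame of atoms in template correspondence order
#'   (columns as in a `protein_structure` atom table).
#' @param label +1 (positive site), -1 (negative site) or NA (unknown).
#' @param rmsd Optional RMSD to the template, if already computed.
#' @return A `local_site` object.
#' @export
local_site <- function(structure_id, template_id, atoms, label = NA_real_,
                       rmsd = NA_real_) {
  structure(
    list(structure_id = structure_id, template_id = template_id,
         atoms = atoms, label = label, rmsd = rmsd),
    class = "local_site"
  )
}

#' Site coordinates as a matrix
#' @param site A `local_site`.
#' @return m x 3 numeric matrix.
#' @export
site_coords <- function(site) {
  unname(as.matrix(site$atoms[, c("x", "y", "z")]))
}

#' Canonical residue key of a local site
#'
#' Sorted `chain:residue_number[:insert]` tokens joined by `+`; the identity
#' under which sites are labeled and deduplicated.
#'
#' @param site A `local_site`, or a data.frame of atoms.
#' @return Character scalar.
#' @export
site_residue_key <- function(site) {
  atoms <- if (inherits(site, "local_site")) site$atoms else site
  ins <- atoms$insert
  if (is.null(ins)) ins <- rep("", nrow(atoms))
  tok <- unique(paste0(atoms$chain_id, ":", atoms$residue_number,
                       ifelse(ins == "", "", paste0(":", ins))))
  paste(sort(tok), collapse = "+")
}

#' @export
print.local_site <- function(x, ...) {
  cat("local_site", x$structure_id, "~", x$template_id, "[",
      site_residue_key(x), "] label:", x$label, "rmsd:",
      round(x$rmsd, 3), "\n")
  invisible(x)
}

.crossdist <- function(A, B) {
  sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B), 0))
}

# template atoms grouped by source residue; returns list of
# list(residue_name, atom_names, rows (template row indices))
.template_residue_groups <- function(template) {
  a <- template$atoms
  rid <- .residue_id(a)
  lapply(split(seq_len(nrow(a)), factor(rid, levels = unique(rid))),
         function(rows) {
           list(residue_name = a$residue_name[rows[1L]],
                atom_names = a$atom_name[rows],
                rows = rows)
         })
}

#' Search a protein for local sites matching a template
#'
#' Enumerates sets of distinct protein residues whose residue names match
#' the template's source residues and which contain all required atom names
#' (chemically equivalent sidechain atoms, e.g. ASP OD1/OD2, may stand in
#' for each other; when several mappings survive, the lowest-RMSD one is
#' kept). Partial candidates are pruned by inter-atom distance
#' compatibility, using the provably sound slack `2 * cutoff * sqrt(m)`;
#' surviving candidates are superposed and kept when RMSD <= `rmsd_cutoff`.
#'
#' Sites are returned in a canonical order (by residue key), independent of
#' the atom-record order of the input structure.
#'
#' @param protein A `protein_structure`.
#' @param template A `site_template`.
#' @param rmsd_cutoff RMSD filter in Angstrom (default 4.0).
#' @param slack Distance-compatibility slack in Angstrom; default
#'   `2 * rmsd_cutoff * sqrt(m)`, which never prunes a site passing the
#'   cutoff.
#' @return List of `local_site` objects (possibly empty), each carrying its
#'   RMSD.
#' @export
lss_search <- function(protein, template, rmsd_cutoff = 4.0, slack = NULL) {
  stopifnot(inherits(protein, "protein_structure"),
            inherits(template, "site_template"))
  m <- template_size(template)
  if (is.null(slack)) slack <- 2 * rmsd_cutoff * sqrt(m)
  groups <- .template_residue_groups(template)
  at <- protein$atoms
  tmpl_xyz <- template_coords(template)

  # candidate (residue, atom-name-variant) choices per template residue:
  # each choice is list(res_index, coords for that group's template rows)
  choices <- vector("list", length(groups))
  res_names <- vapply(protein$residues, function(rows) at$residue_name[rows[1L]], "")
  for (g in seq_along(groups)) {
    grp <- groups[[g]]
    variants <- .atom_name_variants(grp$residue_name, grp$atom_names)
    cand <- list()
    hit_res <- which(res_names == grp$residue_name)
    for (ri in hit_res) {
      rows <- protein$residues[[ri]]
      have <- at$atom_name[rows]
      for (v in variants) {
        pos <- match(unname(v), have)
        if (anyNA(pos)) next
        cand[[length(cand) + 1L]] <- list(
          res_index = ri,
          coords = as.matrix(at[rows[pos], c("x", "y", "z")])
        )
      }
    }
    if (length(cand) == 0L) return(list())
    choices[[g]] <- cand
  }

  n_groups <- length(groups)
  hits <- list()
  # depth-first assignment with pairwise-distance pruning
  assign_next <- function(level, used_res, coords_so_far, rows_so_far) {
    if (level > n_groups) {
      S <- matrix(NA_real_, m, 3L)
      S[unlist(lapply(groups, `[[`, "rows")), ] <- coords_so_far
      tr <- superpose(S, tmpl_xyz)
      r <- sqrt(tr$residual)
      if (r <= rmsd_cutoff) {
        hits[[length(hits) + 1L]] <<- list(rows = rows_so_far, rmsd = r)
      }
      return(invisible(NULL))
    }
    grp_rows <- groups[[level]]$rows
    for (cand in choices[[level]]) {
      if (cand$res_index %in% used_res) next
      ok <- TRUE
      if (level > 1L) {
        prev_rows <- unlist(lapply(groups[seq_len(level - 1L)], `[[`, "rows"))
        d_site <- .crossdist(cand$coords, coords_so_far)
        d_tmpl <- .crossdist(tmpl_xyz[grp_rows, , drop = FALSE],
                             tmpl_xyz[prev_rows, , drop = FALSE])
        if (any(abs(d_site - d_tmpl) > slack)) ok <- FALSE
      }
      if (ok) {
        assign_next(level + 1L,
                    c(used_res, cand$res_index),
                    rbind(coords_so_far, cand$coords),
                    c(rows_so_far, list(cand)))
      }
    }
    invisible(NULL)
  }
  assign_next(1L, integer(), matrix(numeric(), 0L, 3L), list())

  if (length(hits) == 0L) return(list())
  # materialize sites; dedupe by residue key keeping the lowest RMSD mapping
  sites <- list()
  for (h in hits) {
    ord <- order(unlist(lapply(groups, `[[`, "rows")))
    atom_rows <- do.call(rbind, lapply(seq_along(h$rows), function(g) {
      rows <- protein$residues[[h$rows[[g]]$res_index]]
      have <- at$atom_name[rows]
      v <- groups[[g]]$atom_names
      # reconstruct the chosen protein atoms by coordinates
      idx <- apply(h$rows[[g]]$coords, 1L, function(p) {
        rows[which.min((at$x[rows] - p[1])^2 + (at$y[rows] - p[2])^2 +
                         (at$z[rows] - p[3])^2)]
      })
      cbind(at[idx, , drop = FALSE])
    }))
    atom_rows <- atom_rows[ord, , drop = FALSE]
    key <- site_residue_key(atom_rows)
    if (is.null(sites[[key]]) || h$rmsd < sites[[key]]$rmsd) {
      sites[[key]] <- local_site(protein$structure_id, template$template_id,
                                 atom_rows, rmsd = h$rmsd)
    }
  }
  sites[order(names(sites))]
}

#' Label local sites against an annotation table
#'
#' A site is labeled +1 when its residue set matches an annotated
#' active-site residue set of its structure whose function label equals the
#' template's; -1 otherwise. Sites of structures absent from the annotation
#' table keep an unknown (NA) label.
#'
#' @param sites List of `local_site` objects.
#' @param annotations data.frame with columns `structure_id`, `residue_key`
#'   (as [site_residue_key()]) and `function_label`.
#' @param template The `site_template` the sites were searched with.
#' @return The input list with `label` fields filled in.
#' @export
label_sites <- function(sites, annotations, template) {
  stopifnot(is.data.frame(annotations))
  lapply(sites, function(s) {
    if (!s$structure_id %in% annotations$structure_id) {
      s$label <- NA_real_
      return(s)
    }
    key <- site_residue_key(s)
    hit <- annotations$structure_id == s$structure_id &
      annotations$residue_key == key &
      annotations$function_label == template$function_label
    s$label <- if (any(hit)) 1 else -1
    s
  })
}
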
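# Synthetic fixtures: templates, planted/decoy local sites and full
# PDB-format proteins with the statistical structure the learning
# algorithms assume — some template atoms positionally conserved in true
# sites, others variable, and decoys that pass the composition filter but
# deviate more. Everything is a pure function of (parameters, seed).

.catalytic_pool <- data.frame(
  residue_name = c("SER", "HIS", "ASP", "LYS", "TYR", "HIS"),
  atom_name    = c("OG",  "NE2", "OD1", "NZ",  "OH",  "ND1"),
  stringsAsFactors = FALSE
)

#' Noise profile for synthetic site generation
#'
#' @param per_atom_sigma Length-m vector of Gaussian displacement standard
#'   deviations (Angstrom) applied to positive sites.
#' @param decoy_sigma Displacement s.d. applied to every atom of decoy
#'   (negative) sites; should exceed the conserved-atom sigma.
#' @param n_conserved Number of leading atoms regarded as conserved
#'   (low-noise); informational, used by tests.
#' @return A `noise_profile` list.
#' @export
noise_profile <- function(per_atom_sigma, decoy_sigma, n_conserved) {
  stopifnot(all(per_atom_sigma >= 0), decoy_sigma >= 0,
            n_conserved <= length(per_atom_sigma))
  structure(list(per_atom_sigma = per_atom_sigma,
                 decoy_sigma = decoy_sigma,
                 n_conserved = n_conserved),
            class = "noise_profile")
}

#' The default heterogeneous-noise benchmark configuration
#'
#' Six template atoms of which two are strongly conserved (sigma 0.05 A) and
#' four variable (sigma 0.8 A) in positive sites; decoys perturb every atom
#' at 1.5 A. Fifty positives and five hundred negatives echo the strong
#' class skew of real template searches. Under this profile the unweighted
#' deviation is informative but imperfect, leaving measurable headroom for
#' the learned measurements.
#'
#' @return List with `m`, `profile` ([noise_profile()]), `n_pos`, `n_neg`.
#' @export
heterogeneous_benchmark <- function() {
  list(
    m = 6L,
    profile = noise_profile(c(0.05, 0.05, 0.8, 0.8, 0.8, 0.8),
                            decoy_sigma = 1.5, n_conserved = 2L),
    n_pos = 50L,
    n_neg = 500L
  )
}

# random proper rotation (uniform via QR of Gaussian matrix)
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Generate a synthetic active-site template
#'
#' Draws m atoms with all pairwise distances inside [2, span] Angstrom
#' (rejection sampling in a cube) and assigns residue/atom names from a
#' pool of common catalytic sidechain atoms, one residue per atom.
#'
#' @param m Number of atoms (>= 3).
#' @param span Maximum pairwise distance in Angstrom (default 10).
#' @param seed Integer seed.
#' @param template_id,function_label Identifiers for the template.
#' @return A `site_template`.
#' @export
make_template <- function(m, span = 10, seed = 1L,
                          template_id = sprintf("synth-%03d", seed),
                          function_label = "synthetic-reaction") {
  stopifnot(m >= 3L)
  if (span < 2 * 1.3) {
    stop("generation error: span too small for 2 A minimum separation",
         call. = FALSE)
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  box <- span / sqrt(3)
  for (attempt in seq_len(2000L)) {
    X <- matrix(stats::runif(3L * m, 0, box), m, 3L)
    d <- pair_distances(X)
    if (all(d >= 2) && all(d <= span)) break
    X <- NULL
  }
  if (is.null(X)) {
    stop("generation error: could not place ", m, " atoms with pairwise ",
         "distances in [2, ", span, "] A", call. = FALSE)
  }
  pool <- .catalytic_pool[1 + (seq_len(m) - 1L) %% nrow(.catalytic_pool), ]
  atoms <- data.frame(
    chain_id = "A",
    residue_number = 10L * seq_len(m),
    insert = "",
    residue_name = pool$residue_name,
    atom_name = pool$atom_name,
    role = "catalytic_site",
    x = X[, 1L], y = X[, 2L], z = X[, 3L],
    stringsAsFactors = FALSE
  )
  site_template(template_id, function_label, atoms)
}

# one noisy rigid-transformed copy of the template coordinates
.perturbed_copy <- function(tmpl_xyz, sigma) {
  m <- nrow(tmpl_xyz)
  A <- .random_rotation()
  b <- stats::rnorm(3, 0, 20)
  noise <- matrix(stats::rnorm(3L * m, 0, rep(sigma, 3L)), m, 3L)
  sweep(tmpl_xyz %*% t(A), 2, -b) + noise
}

#' Generate labeled positive and decoy local sites for a template
#'
#' Positives are random rigid transforms of the template with per-atom
#' Gaussian displacement (`per_atom_sigma`); negatives use the same
#' construction with `decoy_sigma` on every atom. Each site is assigned a
#' synthetic structure id; by default structures receive one positive and
#' `n_neg/n_pos` negatives each, mimicking the per-protein class skew.
#'
#' @param template A `site_template`.
#' @param n_pos,n_neg Numbers of positive and negative sites (>= 1 each).
#' @param profile A [noise_profile()] consistent with the template size.
#' @param seed Integer seed.
#' @return List of labeled `local_site` objects (positives first).
#' @export
make_sites <- function(template, n_pos, n_neg, profile, seed = 1L) {
  stopifnot(inherits(template, "site_template"),
            inherits(profile, "noise_profile"))
  if (n_pos < 1L || n_neg < 1L) {
    stop("generation error: need at least one site per class", call. = FALSE)
  }
  m <- template_size(template)
  if (length(profile$per_atom_sigma) != m) {
    stop("noise profile has ", length(profile$per_atom_sigma),
         " sigmas for a ", m, "-atom template", call. = FALSE)
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  tmpl_xyz <- template_coords(template)
  n_struct <- n_pos
  neg_per_struct <- ceiling(n_neg / n_struct)
  sites <- vector("list", n_pos + n_neg)
  k <- 0L
  for (i in seq_len(n_pos)) {
    sid <- sprintf("SYN%04d", i)
    X <- .perturbed_copy(tmpl_xyz, profile$per_atom_sigma)
    k <- k + 1L
    sites[[k]] <- .site_from_coords(template, X, sid, label = 1)
  }
  j <- 0L
  for (i in seq_len(n_neg)) {
    sid <- sprintf("SYN%04d", 1L + (j %/% neg_per_struct))
    j <- j + 1L
    X <- .perturbed_copy(tmpl_xyz, rep(profile$decoy_sigma, m))
    k <- k + 1L
    sites[[k]] <- .site_from_coords(template, X, sid, label = -1)
  }
  sites
}

.site_from_coords <- function(template, X, structure_id, label) {
  atoms <- template$atoms
  atoms$x <- X[, 1L]; atoms$y <- X[, 2L]; atoms$z <- X[, 3L]
  atoms$role <- NULL
  local_site(structure_id, template$template_id, atoms, label = label)
}

#' Generate a PDB-format fixture protein with an optional planted site
#'
#' Builds a structure containing (optionally) one noisy planted copy of the
#' template's residues plus decoy residues of the same residue types
#' scattered with realistic inter-residue separations. Each fixture residue
#' carries a small backbone (N, CA, C, O) around its sidechain atom so the
#' file is plausible PDB. Returns the structure, the PDB text path (if
#' `path` given) and the ground-truth annotation used by [label_sites()].
#'
#' @param template A `site_template`.
#' @param planted Plant one true (noisy) copy of the template?
#' @param n_decoy_residues Number of extra decoy residues (>= 0).
#' @param seed Integer seed.
#' @param structure_id Identifier; default derived from the seed.
#' @param plant_sigma Per-atom noise (Angstrom) on the planted copy
#'   (default 0.2).
#' @param path Optional file path; when given, the structure is written as
#'   PDB text.
#' @return List with `structure` (`protein_structure`), `annotation`
#'   (data.frame structure_id / residue_key / function_label; zero rows if
#'   nothing planted) and `path`.
#' @export
make_protein_fixture <- function(template, planted = TRUE,
                                 n_decoy_residues = 10L, seed = 1L,
                                 structure_id = sprintf("FIX%04d", seed),
                                 plant_sigma = 0.2, path = NULL) {
  stopifnot(n_decoy_residues >= 0L)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  tmpl <- template$atoms
  m <- nrow(tmpl)
  rows <- list()
  resno <- 0L
  add_residue <- function(resname, atomname, center) {
    resno <<- resno + 1L
    # minimal backbone scaffold around the sidechain atom
    ca <- center + stats::rnorm(3, 0, 0.3) + c(1.5, 0, 0)
    bb <- rbind(ca + c(-1.46, 0, 0), ca, ca + c(1.52, 0, 0),
                ca + c(2.1, 1.0, 0))
    df <- data.frame(
      atom_name = c("N", "CA", "C", "O", atomname),
      residue_name = resname,
      residue_number = resno,
      insert = "",
      chain_id = "A",
      x = c(bb[, 1L], center[1L]),
      y = c(bb[, 2L], center[2L]),
      z = c(bb[, 3L], center[3L]),
      stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1L]] <<- df
    resno
  }
  annotation <- data.frame(structure_id = character(),
                           residue_key = character(),
                           function_label = character(),
                           stringsAsFactors = FALSE)
  if (planted) {
    X <- .perturbed_copy(template_coords(template), rep(plant_sigma, m))
    planted_resno <- vapply(seq_len(m), function(i) {
      add_residue(tmpl$residue_name[i], tmpl$atom_name[i], X[i, ])
    }, 1L)
    key <- paste(sort(paste0("A:", planted_resno)), collapse = "+")
    annotation <- data.frame(structure_id = structure_id,
                             residue_key = key,
                             function_label = template$function_label,
                             stringsAsFactors = FALSE)
  }
  if (n_decoy_residues > 0L) {
    pool_idx <- 1 + (seq_len(n_decoy_residues) - 1L) %% m
    for (i in seq_len(n_decoy_residues)) {
      center <- stats::runif(3, 25, 70)   # away from the planted site
      add_residue(tmpl$residue_name[pool_idx[i]],
                  tmpl$atom_name[pool_idx[i]], center)
    }
  }
  if (length(rows) == 0L) {
    stop("fixture would contain no residues", call. = FALSE)
  }
  atoms <- do.call(rbind, rows)
  struct <- protein_structure(structure_id, atoms)
  if (!is.null(path)) write_pdb(struct, path)
  list(structure = struct, annotation = annotation, path = path)
}

#' Write a protein structure as PDB-format text
#'
#' Minimal fixed-width ATOM-record writer used for fixtures; round-trips
#' through [read_pdb()].
#'
#' @param structure A `protein_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  element <- sub("^[0-9]*", "", a$atom_name)
  element <- substr(element, 1L, 1L)
  name_field <- ifelse(nchar(a$atom_name) < 4L,
                       sprintf(" %-3s", a$atom_name),
                       a$atom_name)
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name_field, a$residue_name, a$chain_id,
    a$residue_number, ifelse(a$insert == "", " ", a$insert),
    a$x, a$y, a$z, 1.00, 0.00, element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
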
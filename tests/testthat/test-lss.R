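test_that("an exact planted copy is found once with zero RMSD", {
  tm <- make_template(4, seed = 31)
  p <- fixture_protein_from_coords(tm, template_coords(tm), "exact")
  hits <- lss_search(p, tm)
  expect_length(hits, 1L)
  expect_lt(hits[[1]]$rmsd, 1e-8)
  expect_equal(nrow(hits[[1]]$atoms), template_size(tm))
})

test_that("composition mismatch yields an empty result", {
  tm <- make_template(4, seed = 31)
  atoms <- rbind(fixture_full_residue("THR", 1),
                 fixture_full_residue("THR", 2, origin = c(6, 0, 0)))
  p <- protein_structure("nores", atoms)
  expect_length(lss_search(p, tm), 0L)
})

test_that("the RMSD cutoff excludes distorted copies in both directions", {
  tm <- make_template(4, seed = 32)
  T_ <- template_coords(tm)
  # construct distortions with known RMSD by scaling a perturbation
  set.seed(32)
  V <- matrix(rnorm(12), 4)
  scale_to_rmsd <- function(target) {
    f <- function(s) sqrt(umd(T_ + s * V, T_)) - target
    stats::uniroot(f, c(1e-6, 50))$root
  }
  s_bad <- scale_to_rmsd(5.1)
  p_bad <- fixture_protein_from_coords(tm, T_ + s_bad * V, "bad")
  expect_length(lss_search(p_bad, tm, rmsd_cutoff = 4.0), 0L)
  s_ok <- scale_to_rmsd(3.5)
  p_ok <- fixture_protein_from_coords(tm, T_ + s_ok * V, "ok")
  hits <- lss_search(p_ok, tm, rmsd_cutoff = 4.0)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$rmsd, 3.5, tolerance = 1e-4)
  # every returned site re-checks below the cutoff independently
  expect_lte(sqrt(umd(hits[[1]], tm)), 4.0)
})

test_that("search output is canonical and independent of atom record order", {
  tm <- make_template(4, seed = 33)
  fx <- make_protein_fixture(tm, planted = TRUE, n_decoy_residues = 12,
                             seed = 33)
  p <- fx$structure
  hits1 <- lss_search(p, tm)
  set.seed(1)
  perm <- sample(nrow(p$atoms))
  p2 <- protein_structure(p$structure_id, p$atoms[perm, ])
  hits2 <- lss_search(p2, tm)
  expect_equal(vapply(hits1, site_residue_key, ""),
               vapply(hits2, site_residue_key, ""))
  expect_equal(vapply(hits1, `[[`, 1, "rmsd"),
               vapply(hits2, `[[`, 1, "rmsd"), tolerance = 1e-10)
})

test_that("pruning never drops a site that exhaustive enumeration accepts", {
  tm <- make_template(3, seed = 34)
  fx <- make_protein_fixture(tm, planted = TRUE, n_decoy_residues = 9,
                             seed = 34, plant_sigma = 1.0)
  p <- fx$structure
  cutoff <- 4.0
  hits <- lss_search(p, tm, rmsd_cutoff = cutoff)
  got_keys <- vapply(hits, site_residue_key, "")

  # exhaustive reference: try every ordered assignment of distinct residues
  at <- p$atoms
  groups <- split(seq_len(nrow(at)),
                  factor(paste(at$chain_id, at$residue_number),
                         levels = unique(paste(at$chain_id,
                                               at$residue_number))))
  tmpl <- tm$atoms
  T_ <- template_coords(tm)
  want_keys <- character(0)
  res_ids <- seq_along(groups)
  for (a in res_ids) for (b in res_ids) for (c in res_ids) {
    pick <- c(a, b, c)
    if (anyDuplicated(pick)) next
    rows <- vapply(seq_len(3), function(i) {
      g <- groups[[pick[i]]]
      hit <- g[at$residue_name[g] == tmpl$residue_name[i] &
                 at$atom_name[g] == tmpl$atom_name[i]]
      if (length(hit) == 1L) hit else NA_integer_
    }, 1L)
    if (anyNA(rows)) next
    S <- as.matrix(at[rows, c("x", "y", "z")])
    if (sqrt(umd(S, T_)) <= cutoff) {
      want_keys <- c(want_keys,
                     site_residue_key(at[rows, , drop = FALSE]))
    }
  }
  expect_setequal(got_keys, unique(want_keys))
})

test_that("chemically equivalent sidechain atoms may stand in for each other", {
  # template uses ASP OD1; the protein's ASP has the matching oxygen named OD2
  atoms_t <- data.frame(
    chain_id = "A", residue_number = c(1L, 2L), insert = "",
    residue_name = c("ASP", "SER"), atom_name = c("OD1", "OG"),
    role = "catalytic_site",
    x = c(0, 4), y = c(0, 0), z = c(0, 0), stringsAsFactors = FALSE
  )
  tm <- site_template("asp-t", "lab", atoms_t)
  prot_atoms <- data.frame(
    atom_name = c("OD1", "OD2", "OG"),
    residue_name = c("ASP", "ASP", "SER"),
    residue_number = c(1L, 1L, 2L),
    insert = "", chain_id = "A",
    # OD2 sits where the template's OD1 is; OD1 is displaced
    x = c(2.5, 0, 4), y = c(2.5, 0, 0), z = c(0, 0, 0),
    stringsAsFactors = FALSE
  )
  p <- protein_structure("swap", prot_atoms)
  hits <- lss_search(p, tm, rmsd_cutoff = 1.0)
  expect_length(hits, 1L)
  expect_lt(hits[[1]]$rmsd, 1e-8)   # the OD2 mapping wins
})

test_that("labeling follows annotation residue sets and function labels", {
  tm <- make_template(4, seed = 35)
  fx <- make_protein_fixture(tm, planted = TRUE, n_decoy_residues = 8,
                             seed = 35)
  hits <- lss_search(fx$structure, tm)
  expect_gte(length(hits), 1L)
  lab <- label_sites(hits, fx$annotation, tm)
  keys <- vapply(lab, site_residue_key, "")
  planted_key <- fx$annotation$residue_key[1]
  expect_equal(unname(vapply(lab, `[[`, 1, "label")[keys == planted_key]), 1)
  expect_true(all(vapply(lab, `[[`, 1, "label")[keys != planted_key] == -1))

  # same residues but a different function label flips to negative
  ann2 <- fx$annotation
  ann2$function_label <- "some-other-reaction"
  lab2 <- label_sites(hits, ann2, tm)
  expect_true(all(vapply(lab2, `[[`, 1, "label") == -1))

  # structures absent from the annotation keep an unknown label
  ann3 <- fx$annotation
  ann3$structure_id <- "ELSEWHERE"
  lab3 <- label_sites(hits, ann3, tm)
  expect_true(all(is.na(vapply(lab3, `[[`, 1, "label"))))
})
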
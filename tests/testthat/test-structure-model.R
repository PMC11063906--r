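test_that("PDB and mmCIF round trips preserve coordinates and counts", {
  atoms <- make_sphere_cluster(rbind(c(1.234, -5.678, 9.012),
                                     c(0.001, 2.5, -3.75)), c("C", "O"))
  for (fmt in c("pdb", "cif")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_structure(atoms, path, fmt)
    back <- read_structure(path)
    expect_identical(nrow(back), nrow(atoms))
    expect_equal(cbind(back$x, back$y, back$z),
                 cbind(atoms$x, atoms$y, atoms$z), tolerance = 1e-3,
                 ignore_attr = TRUE)
    expect_identical(back$elety, atoms$elety)
    expect_identical(attr(back, "source_format"), fmt)
  }
})

test_that("a one-atom fixture reads as one chain, residue and atom", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_fixture(make_sphere_cluster(rbind(c(0, 0, 0)), "O"), path)
  s <- read_structure(path)
  expect_identical(nrow(s), 1L)
  expect_identical(length(unique(s$chain)), 1L)
  expect_identical(s$is_het, TRUE)
  expect_identical(nrow(select_atoms(s, atom_names = "all")), 1L)
})

test_that("unreadable and unknown-format files raise distinct errors", {
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("42", "not a structure"), bad)
  expect_error(read_structure(bad), class = "structcomp_format_error")
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")), "not found")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  base <- make_sphere_cluster(rbind(c(0, 0, 0), c(0.5, 0, 0)), c("C", "C"))
  base$resno <- c(1L, 1L)
  base$alt <- c("A", "B")
  base$o <- c(0.4, 0.6)
  sel <- select_atoms(base, altloc = "first")
  expect_identical(nrow(sel), 1L)
  expect_identical(sel$alt, "B")
  # tie broken A-first
  base$o <- c(0.5, 0.5)
  expect_identical(select_atoms(base, altloc = "first")$alt, "A")
  expect_identical(nrow(select_atoms(base, altloc = "all")), 2L)
})

test_that("selection respects windows, reports missing residues, errors when empty", {
  toy <- dense_enzyme_toy()$reference
  sel <- select_atoms(toy, chain = "A", seq_range = c(46, 386),
                      atom_names = "CA")
  expect_lte(nrow(sel), 341L)
  expect_identical(attr(sel, "n_missing"),
                   341L - length(unique(sel$resno)))
  expect_error(select_atoms(toy, chain = "A", seq_range = c(2000, 2100)),
               class = "structcomp_empty_selection")
  expect_error(select_atoms(toy, chain = "Z"),
               class = "structcomp_empty_selection")
})

test_that("select is idempotent and order-preserving", {
  toy <- toy_complex()
  s1 <- select_atoms(toy, chain = "A", seq_range = c(43, 547),
                     atom_names = "CA")
  s2 <- select_atoms(s1, chain = "A", seq_range = c(43, 547),
                     atom_names = "CA")
  expect_equal(structcomp:::coord_matrix(s1), structcomp:::coord_matrix(s2))
  expect_false(is.unsorted(s1$resno))
})

test_that("complex-copy pairing finds the nearest partner and ignores distant chains", {
  cx <- toy_complex(decoy = TRUE)
  pairs <- pair_complex_copies(cx)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$enzyme_chain, "A")
  expect_identical(pairs$partner_chain, "B")
  expect_lte(pairs$min_distance, 5)
})

test_that("pairing warns and returns empty for a single-chain structure", {
  lone <- dense_enzyme_toy()$reference
  expect_warning(pairs <- pair_complex_copies(lone), "no enzyme/partner")
  expect_identical(nrow(pairs), 0L)
})

test_that("pairing is invariant under chain relabelling", {
  cx <- toy_complex()
  relabel <- c(A = "Q", B = "D")
  cx2 <- dplyr::mutate(cx, chain = unname(relabel[chain]))
  p1 <- pair_complex_copies(cx)
  p2 <- pair_complex_copies(cx2)
  expect_identical(unname(relabel[p1$enzyme_chain]), p2$enzyme_chain)
  expect_identical(unname(relabel[p1$partner_chain]), p2$partner_chain)
  expect_equal(p1$min_distance, p2$min_distance)
})

test_that("per-domain B-factor means reproduce constructed values", {
  toy <- dense_enzyme_toy()$reference
  toy$b <- 20
  sc <- default_scheme("endos2")
  sm <- domain_bfactor_summary(toy, sc)
  expect_true(all(abs(sm$mean_b - 20) < 1e-12))
  toy$b <- ifelse(toy$resno <= 386, 10, 30)
  sm2 <- domain_bfactor_summary(toy, sc)
  expect_equal(sm2$mean_b[sm2$domain == "GH"], 10)
  expect_equal(sm2$mean_b[sm2$domain == "CBM"], 30)
  toy$b <- NA_real_
  expect_error(domain_bfactor_summary(toy, sc), "B factors")
})

test_that("domain schemes validate their windows", {
  expect_error(domain_scheme("x", list(A = c(5, 2))), "start <= end")
  expect_error(domain_scheme("x", list()), "at least one")
  sc <- default_scheme("endos2")
  expect_identical(scheme_window(sc, "GH"), c(43L, 386L))
  expect_identical(scheme_window(sc, "GH", align = TRUE), c(46L, 386L))
  expect_error(scheme_window(sc, "XX"), "not in scheme")
})
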
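test_that("constructed glycosidic torsions are recovered exactly", {
  for (case in list(c(5.9, -120), c(-74, -120), c(-59, 0), c(180, 57.3))) {
    d <- make_disaccharide(case[1], case[2])
    tor <- glycosidic_torsions(d, "A", donor = 2, acceptor = 1)
    expect_equal(unname(tor["phi"]), case[1], tolerance = 1e-3)
    expect_equal(unname(tor["psi"]), case[2], tolerance = 1e-3)
  }
  expect_error(make_disaccharide(200, 0), "-180")
})

test_that("dihedrals hit the anti-periplanar reference and behave under symmetry", {
  p <- list(c(1, 0, 0), c(0, 0, 0), c(0, 1.5, 0), c(-1, 2.5, 0))
  expect_equal(abs(dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])), 180)
  withr::local_seed(20)
  for (k in 1:10) {
    q <- lapply(1:4, function(i) rnorm(3))
    d0 <- dihedral_angle(q[[1]], q[[2]], q[[3]], q[[4]])
    # antisymmetric under order reversal is false; invariant under full
    # reversal, antisymmetric under mirror; check rigid invariance:
    R <- random_rotation(); tr <- rnorm(3)
    qt <- lapply(q, function(v) as.numeric(R %*% v) + tr)
    expect_equal(dihedral_angle(qt[[1]], qt[[2]], qt[[3]], qt[[4]]), d0,
                 tolerance = 1e-9)
    expect_equal(dihedral_angle(q[[4]], q[[3]], q[[2]], q[[1]]), d0,
                 tolerance = 1e-9)
    # mirroring flips the sign
    qm <- lapply(q, function(v) v * c(1, 1, -1))
    expect_equal(dihedral_angle(qm[[1]], qm[[2]], qm[[3]], qm[[4]]),
                 -d0, tolerance = 1e-9)
  }
})

test_that("a missing linkage atom is reported by name", {
  d <- make_disaccharide(5.9, -120)
  d2 <- dplyr::filter(d, !(resno == 2 & elety == "O5"))
  expect_error(glycosidic_torsions(d2, "A", donor = 2, acceptor = 1),
               "O5", class = "structcomp_missing_atom")
})

test_that("Cremer-Pople parameters invert the forward construction", {
  flat <- cbind(1.46 * cos(-2 * pi * (0:5) / 6),
                1.46 * sin(-2 * pi * (0:5) / 6), 0)
  expect_lt(cremer_pople(flat)$Q, 1e-9)
  chair <- cremer_pople(make_ring("4C1"))
  expect_lt(chair$theta, 5)
  expect_identical(chair$conformer, "4C1")
  # alternating +/- 0.25 A displacements are the textbook ideal chair
  zig <- cbind(1.46 * cos(-2 * pi * (0:5) / 6),
               1.46 * sin(-2 * pi * (0:5) / 6), 0.25 * (-1)^(0:5))
  zp <- cremer_pople(zig)
  expect_lt(zp$theta, 1)
  expect_identical(zp$conformer, "4C1")
  skew <- cremer_pople(make_ring(q = 0.6, theta = 90, phi2 = 210))
  expect_equal(skew$theta, 90, tolerance = 1)
  expect_equal(skew$phi2, 210, tolerance = 1)
  expect_equal(skew$Q, 0.6, tolerance = 0.01)
  expect_identical(skew$conformer, "1S3")
})

test_that("forward/inverse identity holds across the canonical conformer set", {
  tab <- structcomp:::cp_canonical()
  for (k in seq_len(nrow(tab))) {
    ring <- make_ring(tab$label[k], q = 0.57)
    cp <- cremer_pople(ring)
    expect_equal(cp$Q, 0.57, tolerance = 0.01)
    expect_equal(cp$theta, tab$theta[k], tolerance = 1)
    if (tab$theta[k] %% 180 != 0) {
      dphi <- abs(structcomp:::wrap_angle(cp$phi2 - tab$phi2[k]))
      expect_lt(dphi, 1)
    }
    expect_identical(cp$conformer, tab$label[k])
  }
  expect_error(cremer_pople(matrix(0, 5, 3)), "6 atoms")
  expect_error(make_ring("9Z9"), "unknown conformer")
})

test_that("glycan detection walks Asn -> GlcNAc -> GlcNAc with typed linkages", {
  one <- make_nglycan(phi = -97, psi = 178)
  t1 <- detect_glycan(one, "A", 297)
  expect_identical(nrow(t1$residues), 1L)
  expect_identical(t1$linkages$acceptor_atom, "ND2")
  two <- make_nglycan(phi = c(-97, -74), psi = c(178, -120))
  t2 <- detect_glycan(two, "A", 297)
  expect_identical(nrow(t2$residues), 2L)
  core <- dplyr::filter(t2$linkages, acceptor_atom == "O4")
  expect_identical(core$linkage, "1-4")
  expect_equal(core$phi, -74, tolerance = 1e-3)
  expect_equal(core$psi, -120, tolerance = 1e-3)
  fuc <- detect_glycan(make_nglycan(fucose = TRUE), "A", 297)
  expect_true("FUC" %in% fuc$residues$resid)
  expect_identical(
    dplyr::filter(fuc$linkages, donor_resid == "FUC")$acceptor_atom, "O6")
})

test_that("glycan detection errors cleanly without a glycan", {
  bare <- ser_og_stub()
  expect_error(detect_glycan(bare, "A", 1),
               class = "structcomp_no_glycan")
  asn_only <- dplyr::filter(make_nglycan(), resid == "ASN")
  expect_error(detect_glycan(asn_only, "A", 297),
               class = "structcomp_no_glycan")
})

test_that("detection is independent of atom record order", {
  g <- make_nglycan(phi = c(-97, 5.9), psi = c(178, -120), fucose = TRUE)
  t_fwd <- detect_glycan(g, "A", 297)
  withr::local_seed(21)
  g_shuf <- g[sample(nrow(g)), ]
  t_shuf <- detect_glycan(g_shuf, "A", 297)
  expect_identical(t_fwd$residues$resno, t_shuf$residues$resno)
  expect_equal(t_fwd$linkages$phi, t_shuf$linkages$phi, tolerance = 1e-9)
  expect_identical(t_fwd$linkages$acceptor_atom, t_shuf$linkages$acceptor_atom)
})

test_that("ring puckers report one row per detected sugar", {
  g <- make_nglycan(phi = c(-97, -74), psi = c(178, -120), fucose = TRUE)
  tree <- detect_glycan(g, "A", 297)
  pk <- ring_puckers(g, tree)
  expect_identical(nrow(pk), 3L)
  expect_true(all(pk$conformer == "4C1"))
})

test_that("active-site overlay reports constructed dyad distances", {
  # enzyme chain: GH window C-alphas plus Glu186/Asp184 carboxyl stubs
  toy <- dense_enzyme_toy()$reference
  dyad <- structcomp:::new_atom_tbl(
    "ATOM", c("CB", "CG", "OD1", "OD2", "CB", "CG", "CD", "OE1", "OE2"),
    c(rep("ASP", 4), rep("GLU", 5)), "A",
    c(rep(184L, 4), rep(186L, 5)),
    rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.1, 1.1, 0), c(2.1, -1.1, 0),
          c(10, 0, 0), c(11.5, 0, 0), c(13.0, 0, 0), c(13.6, 1.1, 0),
          c(13.6, -1.1, 0)),
    c("C", "C", "O", "O", "C", "C", "C", "O", "O"))
  enz <- dplyr::bind_rows(dplyr::filter(toy, !resno %in% c(184, 186)), dyad)
  # a disaccharide whose glycosidic O4 sits exactly 3.0 A from Glu OE1
  dsc <- make_disaccharide(5.9, -120, chain = "G")
  o4 <- structcomp:::atom_xyz(dplyr::filter(dsc, resno == 1), "O4")
  target <- c(13.6, 1.1, 0) + c(3, 0, 0)
  dsc$x <- dsc$x + (target[1] - o4[1])
  dsc$y <- dsc$y + (target[2] - o4[2])
  dsc$z <- dsc$z + (target[3] - o4[3])
  cx <- structcomp:::renumber_atoms(dplyr::bind_rows(enz, dsc))
  asg <- active_site_geometry(cx, cx, "A", "A", glycan_chain = "G",
                              donor = 2, acceptor = 1)
  expect_lt(attr(asg, "gh_fit_rmsd"), 1e-9)
  oe1 <- dplyr::filter(asg, dyad_atom == "OE1", target == "O_glycosidic")
  expect_equal(oe1$distance, 3, tolerance = 1e-9)
  # dyad without carboxyls errors
  no_ox <- dplyr::filter(cx, !elety %in% c("OE1", "OE2"))
  expect_error(active_site_geometry(cx, no_ox, "A", "A",
                                    glycan_chain = "G", donor = 2,
                                    acceptor = 1),
               class = "structcomp_missing_atom")
})
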
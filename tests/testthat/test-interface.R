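# Analytic SASA systems use an explicit element radii table (C 1.70,
# O 1.40) so expected areas come from closed forms, not the protein set.
rt <- radii_table("element", custom = c(C = 1.70, O = 1.40))

test_that("an isolated atom's SASA matches the analytic sphere", {
  o <- make_sphere_cluster(rbind(c(0, 0, 0)), "O")
  tot <- sum(shrake_rupley_sasa(o, rt)$sasa)
  expect_equal(tot, 4 * pi * 2.8^2, tolerance = 0.01)
})

test_that("well-separated atoms each expose a full sphere", {
  cc <- make_sphere_cluster(rbind(c(0, 0, 0), c(10, 0, 0)), c("C", "C"))
  s <- shrake_rupley_sasa(cc, rt)$sasa
  expect_equal(s, rep(4 * pi * 3.1^2, 2), tolerance = 0.01)
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  cc <- make_sphere_cluster(rbind(c(0, 0, 0), c(2, 0, 0)), c("C", "C"))
  s <- shrake_rupley_sasa(cc, rt)$sasa
  expected <- two_sphere_exposed_area(R = 3.1, d = 2)
  expect_equal(expected, 79.86, tolerance = 1e-3)
  expect_equal(s[1], expected, tolerance = 0.02)
  expect_equal(s[2], expected, tolerance = 0.02)
})

test_that("SASA is converged at the default point count", {
  withr::local_seed(10)
  cl <- make_sphere_cluster(matrix(rnorm(30, sd = 2.5), ncol = 3),
                            c("C", "O", "C", "N", "O", "C", "S", "C", "N",
                              "C"))
  t960 <- sum(shrake_rupley_sasa(cl, radii_table(), 960L)$sasa)
  t4000 <- sum(shrake_rupley_sasa(cl, radii_table(), 4000L)$sasa)
  expect_lt(abs(t960 - t4000) / t960, 0.01)
})

test_that("the SASA engine validates its inputs", {
  o <- make_sphere_cluster(rbind(c(0, 0, 0)), "O")
  expect_error(shrake_rupley_sasa(o, n_points = 32L), "at least 64")
  x <- make_sphere_cluster(rbind(c(0, 0, 0)), "XX")
  expect_error(shrake_rupley_sasa(x, rt), "no radius")
  expect_error(radii_table(probe = -1), "probe")
})

test_that("interface area is zero for distant sides and matches the cap-formula value", {
  a <- make_sphere_cluster(rbind(c(0, 0, 0)), "C")
  b_far <- make_sphere_cluster(rbind(c(50, 0, 0)), "C", chain = "B")
  expect_lt(abs(interface_area(a, b_far, rt)), 0.5)
  b <- make_sphere_cluster(rbind(c(2, 0, 0)), "C", chain = "B")
  full <- 4 * pi * 3.1^2
  capped <- two_sphere_exposed_area(3.1, 2)
  derived <- (2 * full - 2 * capped) / 2
  expect_equal(derived, 40.90, tolerance = 1e-2)
  expect_equal(interface_area(a, b, rt), derived, tolerance = 0.02)
})

test_that("interface area is symmetric and rejects overlapping sides", {
  withr::local_seed(11)
  a <- make_sphere_cluster(matrix(rnorm(15, sd = 2), ncol = 3),
                           c("C", "O", "N", "C", "C"))
  b <- make_sphere_cluster(sweep(matrix(rnorm(15, sd = 2), ncol = 3), 2,
                                 c(4, 0, 0), "+"),
                           c("C", "C", "O", "N", "C"), chain = "B")
  expect_identical(interface_area(a, b, rt), interface_area(b, a, rt))
  expect_error(interface_area(a, a, rt),
               class = "structcomp_overlap_error")
})

test_that("domain-restricted areas reduce to the total and partition it", {
  withr::local_seed(12)
  xa <- matrix(rnorm(36, sd = 3), ncol = 3)
  a <- make_sphere_cluster(xa, "C")
  a$resno <- 1:12
  b <- make_sphere_cluster(sweep(matrix(rnorm(24, sd = 3), ncol = 3), 2,
                                 c(5.5, 0, 0), "+"), "C", chain = "B")
  total <- interface_area(a, b, rt)
  expect_gt(total, 1)
  whole <- domain_restricted_interface(a, b, c(1, 12), rt)
  expect_equal(whole, total, tolerance = 1e-9)
  part1 <- domain_restricted_interface(a, b, c(1, 6), rt)
  part2 <- domain_restricted_interface(a, b, c(7, 12), rt)
  expect_lt(abs(part1 + part2 - total), 2)
})

test_that("solvation gain is zero without burial and negative for buried carbon", {
  a <- make_sphere_cluster(rbind(c(0, 0, 0)), "C")
  b_far <- make_sphere_cluster(rbind(c(50, 0, 0)), "C", chain = "B")
  expect_equal(solvation_energy_gain(a, b_far, radii = rt), 0,
               tolerance = 1e-6)
  b <- make_sphere_cluster(rbind(c(2, 0, 0)), "C", chain = "B")
  ds <- structcomp:::interface_dsasa(a, b, rt)
  dg <- solvation_energy_gain(a, b, radii = rt)
  sigma_c <- asp_table()$values[["C"]]
  expect_lt(dg, 0)
  expect_equal(dg, sigma_c * (sum(ds$d_a) + sum(ds$d_b)), tolerance = 1e-9)
})

test_that("contacts respect the distance cutoff exactly", {
  a <- make_sphere_cluster(rbind(c(0, 0, 0)), "C")
  near <- make_sphere_cluster(rbind(c(4.4, 0, 0)), "C", chain = "B")
  far <- make_sphere_cluster(rbind(c(4.6, 0, 0)), "C", chain = "B")
  expect_identical(nrow(find_contacts(a, near, 4.5)), 1L)
  expect_identical(nrow(find_contacts(a, far, 4.5)), 0L)
  expect_equal(find_contacts(a, near, 4.5)$min_distance, 4.4,
               tolerance = 1e-9)
})

test_that("hydrogen bonds require donor/acceptor typing and sane distance", {
  don <- ser_og_stub()
  acc <- asp_od1_stub(c(2.8, 0, 0))
  hb <- find_hydrogen_bonds(don, acc)
  expect_identical(nrow(hb), 1L)
  expect_identical(hb$donor_atom, "OG")
  expect_identical(hb$acceptor_atom, "OD1")
  expect_equal(hb$distance, 2.8, tolerance = 1e-9)
  expect_identical(nrow(find_hydrogen_bonds(don, asp_od1_stub(c(4, 0, 0)))),
                   0L)
})

test_that("the antecedent angle test rejects buried-side approaches", {
  # acceptor on the opposite side of the donor's covalent antecedent
  don <- ser_og_stub(with_cb = TRUE)           # CB at (-1.4, 0, 0)
  behind <- asp_od1_stub(c(-2.9, 0, 0))        # angle CB-OG-OD1 = 0 deg
  expect_identical(nrow(find_hydrogen_bonds(don, behind)), 0L)
  front <- asp_od1_stub(c(2.8, 0, 0))          # angle = 180 deg
  expect_identical(nrow(find_hydrogen_bonds(don, front)), 1L)
})

test_that("every hydrogen bond is also a contact at the same or larger cutoff", {
  g <- make_nglycan(phi = c(-97, -74), psi = c(178, -120), fucose = TRUE)
  side_a <- dplyr::filter(g, resid == "ASN")
  side_b <- dplyr::filter(g, resid != "ASN")
  hb <- find_hydrogen_bonds(side_a, side_b, 3.5)
  ct <- find_contacts(side_a, side_b, 4.5)
  if (nrow(hb)) {
    keys_ct <- paste(ct$resno_a, ct$resno_b)
    expect_true(all(paste(hb$donor_resno, hb$acceptor_resno) %in% keys_ct |
                      paste(hb$acceptor_resno, hb$donor_resno) %in% keys_ct))
  }
  expect_gte(nrow(ct), 1L)
})

test_that("interface_report bundles consistent numbers", {
  withr::local_seed(13)
  a <- make_sphere_cluster(matrix(rnorm(30, sd = 2.5), ncol = 3), "C")
  a$resno <- 1:10
  b <- make_sphere_cluster(sweep(matrix(rnorm(30, sd = 2.5), ncol = 3), 2,
                                 c(5, 0, 0), "+"), "C", chain = "B")
  rep <- interface_report(a, b, radii = rt)
  expect_s3_class(rep, "interface_report")
  expect_equal(rep$buried_area, interface_area(a, b, rt), tolerance = 1e-9)
  gl <- glance(rep)
  expect_identical(gl$n_contacts, nrow(rep$contacts))
  expect_identical(tidy(rep), rep$contacts)
})
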
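sc <- default_scheme("endos2")

test_that("self-comparison reports zero rotation and displacement everywhere", {
  toy <- dense_enzyme_toy()$reference
  rr <- domain_rearrangement(toy, toy, "A", "A", sc, reference = "GH")
  expect_true(all(rr$rotation_deg < 1e-5))
  expect_true(all(rr$displacement_rmsd < 1e-6))
  expect_lt(attr(rr, "reference_fit_rmsd"), 1e-9)
})

test_that("an applied single-domain rotation is recovered and others stay put", {
  toy <- dense_enzyme_toy(
    transforms = list(LRR = list(angle = 10, axis = c(0, 0, 1))))
  rr <- domain_rearrangement(toy$reference, toy$transformed, "A", "A", sc,
                             reference = "GH")
  expect_equal(rr$rotation_deg[rr$domain == "LRR"], 10, tolerance = 1e-6)
  expect_lt(rr$rotation_deg[rr$domain == "hIg"], 1e-5)
  expect_lt(rr$rotation_deg[rr$domain == "CBM"], 1e-5)
  expect_lt(rr$displacement_rmsd[rr$domain == "hIg"], 1e-6)
})

test_that("swapping the conformers leaves angles and RMSDs unchanged", {
  toy <- dense_enzyme_toy(
    transforms = list(LRR = list(angle = 10),
                      CBM = list(angle = 4, translation = c(3, 1, -2))))
  ab <- domain_rearrangement(toy$reference, toy$transformed, "A", "A", sc,
                             reference = "GH")
  ba <- domain_rearrangement(toy$transformed, toy$reference, "A", "A", sc,
                             reference = "GH")
  expect_equal(ab$rotation_deg, ba$rotation_deg, tolerance = 1e-6)
  expect_equal(ab$displacement_rmsd, ba$displacement_rmsd, tolerance = 1e-6)
})

test_that("angles recover within 3 sigma / sqrt(n) under coordinate noise", {
  sigma <- 0.3
  n <- 100L
  toy <- make_multidomain_toy(sc,
                              transforms = list(LRR = list(angle = 10)),
                              atoms_per_domain = n, noise_sigma = sigma,
                              seed = 42)
  rr <- domain_rearrangement(toy$reference, toy$transformed, "A", "A", sc,
                             reference = "GH")
  expect_lt(abs(rr$rotation_deg[rr$domain == "LRR"] - 10),
            3 * structcomp:::deg(sigma / 8) / sqrt(n) * 3)
  expect_lt(rr$displacement_rmsd[rr$domain == "hIg"], 3 * sigma)
})

test_that("inter-domain distances match construction and a brute-force loop", {
  two <- structcomp:::new_atom_tbl("ATOM", c("CA", "CA"), "GLY", "A",
                                   c(50L, 400L),
                                   rbind(c(0, 0, 0), c(7.5, 0, 0)), "C")
  d_min <- interdomain_distance(two, "A", "GH", "LRR", sc, metric = "min")
  d_cen <- interdomain_distance(two, "A", "GH", "LRR", sc,
                                metric = "centroid")
  expect_equal(d_min$distance, 7.5)
  expect_equal(d_cen$distance, 7.5)
  expect_identical(d_min$metric, "min")
  expect_equal(interdomain_distance(two, "A", "GH", "GH", sc,
                                    metric = "min")$distance, 0)
  withr::local_seed(8)
  cloud <- structcomp:::new_atom_tbl(
    "ATOM", rep("CA", 20), "GLY", "A",
    c(seq(43, 100, length.out = 10), seq(387, 500, length.out = 10)),
    matrix(rnorm(60, sd = 10), ncol = 3), "C")
  got <- interdomain_distance(cloud, "A", "GH", "LRR", sc,
                              metric = "min")$distance
  xa <- structcomp:::coord_matrix(cloud[cloud$resno <= 386, ])
  xb <- structcomp:::coord_matrix(cloud[cloud$resno > 386, ])
  expect_equal(got, min_distance_loop(xa, xb), tolerance = 1e-10)
})

test_that("Cgamma2 separation is the centroid distance of the two windows", {
  mk <- function(chain, centre) {
    withr::with_seed(9, {
      xyz <- matrix(rnorm(90, sd = 5), ncol = 3)
      xyz <- sweep(xyz, 2, colMeans(xyz))
      structcomp:::new_atom_tbl("ATOM", "CA", "GLY", chain,
                                round(seq(237, 340, length.out = 30)),
                                sweep(xyz, 2, centre, "+"), "C")
    })
  }
  both <- dplyr::bind_rows(mk("A", c(0, 0, 0)), mk("B", c(30, 0, 0)))
  expect_equal(cgamma2_separation(both, "A", "B"), 30, tolerance = 1e-9)
  same <- dplyr::bind_rows(mk("A", c(0, 0, 0)), mk("B", c(0, 0, 0)))
  expect_equal(cgamma2_separation(same, "A", "B"), 0, tolerance = 1e-9)
})

test_that("deviation profile is zero for identical chains and peaks at a displaced residue", {
  toy <- dense_enzyme_toy()$reference
  dev0 <- per_residue_deviation(toy, toy, "A", "A", align_window = c(46, 386))
  expect_true(all(dev0$deviation < 1e-9))
  moved <- toy
  target <- moved$resno[which(moved$resno > 500)[1]]
  hit <- moved$resno == target
  moved$x[hit] <- moved$x[hit] + 5
  dev <- per_residue_deviation(toy, moved, "A", "A",
                               align_window = c(46, 386))
  expect_identical(dev$resno[which.max(dev$deviation)], target)
  expect_equal(max(dev$deviation), 5, tolerance = 0.05)
})
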
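# Shared synthetic structures for tests. Everything is generated in code;
# nothing is read from disk except files the tests themselves write.

# An enzyme-like chain densely covering the endos2 domain windows, so that
# pair_complex_copies recognises it as an enzyme copy.
dense_enzyme_toy <- function(seed = 11, transforms = list()) {
  make_multidomain_toy(default_scheme("endos2"), transforms = transforms,
                       atoms_per_domain = 120L, seed = seed)
}

# A two-chain complex: enzyme chain "A" plus a small Fc-like partner chain
# "B" (C-alpha cloud numbered 237-443) placed near the CBM centroid, with
# an N-glycan at Asn 297 near the GH domain. Optionally a far-away decoy
# chain "C".
toy_complex <- function(seed = 11, decoy = FALSE) {
  toy <- dense_enzyme_toy(seed)
  enz <- toy$reference
  cbm <- dplyr::filter(enz, resno >= 681)
  ctr <- colMeans(cbind(cbm$x, cbm$y, cbm$z))
  withr::with_seed(seed + 1, {
    n <- 120L
    xyz <- matrix(rnorm(3 * n, sd = 7), ncol = 3)
    xyz <- sweep(xyz, 2, ctr + c(14, 0, 0), "+")
    fc <- structcomp:::new_atom_tbl("ATOM", "CA", "GLY", "B",
                                    round(seq(237, 443, length.out = n)),
                                    xyz, "C")
  })
  glyc <- make_nglycan(phi = c(-97, 5.9), psi = c(178, -120), chain = "B")
  gh <- dplyr::filter(enz, resno <= 386)
  gh_ctr <- colMeans(cbind(gh$x, gh$y, gh$z))
  shift <- gh_ctr + c(16, 0, 0) - colMeans(cbind(glyc$x, glyc$y, glyc$z))
  glyc$x <- glyc$x + shift[1]
  glyc$y <- glyc$y + shift[2]
  glyc$z <- glyc$z + shift[3]
  out <- dplyr::bind_rows(enz, fc, glyc)
  if (decoy) {
    dec <- structcomp:::new_atom_tbl("ATOM", "CA", "GLY", "C", 1:20,
                                     matrix(500 + rnorm(60), ncol = 3), "C")
    out <- dplyr::bind_rows(out, dec)
  }
  structcomp:::renumber_atoms(out)
}

# Minimal residue stubs for hydrogen-bond tests.
ser_og_stub <- function(og = c(0, 0, 0), with_cb = FALSE) {
  nm <- c("OG", if (with_cb) "CB")
  xyz <- rbind(og, if (with_cb) og + c(-1.4, 0, 0))
  structcomp:::new_atom_tbl("ATOM", nm, "SER", "A", 1L, xyz,
                            substr(nm, 1, 1))
}

asp_od1_stub <- function(od1 = c(2.8, 0, 0), chain = "B") {
  structcomp:::new_atom_tbl("ATOM", "OD1", "ASP", chain, 2L, rbind(od1), "O")
}
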
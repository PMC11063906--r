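# Synthetic-structure generators with exactly known ground truth. These
# are first-class inputs for validating every analysis stage: rigid-body
# recovery, analytic SASA, torsion construction and ring puckering all
# check the pipeline against values the generators set by construction.

new_atom_tbl <- function(type, elety, resid, chain, resno, xyz, elesy,
                         o = 1, b = 20) {
  xyz <- coord_matrix(xyz)
  tibble(type = type, eleno = seq_len(nrow(xyz)), elety = elety, alt = "",
         resid = resid, chain = chain, resno = as.integer(resno),
         insert = "", x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
         o = o, b = b, elesy = elesy, is_het = type == "HETATM")
}

renumber_atoms <- function(atoms) {
  atoms$eleno <- seq_len(nrow(atoms))
  atoms
}

#' Multi-domain C-alpha toy with known per-domain rigid transforms
#'
#' Builds a reference "protein" of Gaussian C-alpha clouds, one per domain
#' window of the scheme, centred on a smooth arc of domain centroids, and a
#' transformed copy in which selected domains are rotated about their own
#' centroid and translated by stated amounts (others untouched). Optional
#' iid Gaussian coordinate noise is added to the transformed copy. The
#' applied transforms are returned as ground truth, so rearrangement
#' recovery can be tested exactly (noiseless) or statistically (noisy).
#'
#' @param scheme A [domain_scheme()]; windows must hold `atoms_per_domain`
#'   distinct residue numbers.
#' @param transforms Named list, per domain: `list(angle = degrees,
#'   axis = 3-vector, translation = 3-vector)` (axis defaults to z,
#'   translation to zero). Unnamed domains stay put.
#' @param atoms_per_domain C-alpha count per domain (>= 4).
#' @param noise_sigma Std. dev. of added coordinate noise, angstrom.
#' @param seed Integer seed; fixes all randomness.
#' @return List: `reference`, `transformed` (atom tables, chain `"A"`),
#'   `truth` (list of applied per-domain transforms, plus `seed`).
#' @examples
#' toy <- make_multidomain_toy(
#'   transforms = list(LRR = list(angle = 10)), seed = 7)
#' toy$truth$LRR$angle
#' @export
make_multidomain_toy <- function(scheme = default_scheme("endos2"),
                                 transforms = list(),
                                 atoms_per_domain = 60L,
                                 noise_sigma = 0, seed = 1L) {
  if (atoms_per_domain < 4L) abort("atoms_per_domain must be >= 4")
  bad <- setdiff(names(transforms), names(scheme$windows))
  if (length(bad)) abort(paste0("transform for unknown domain: ", bad[1L]))
  doms <- names(scheme$windows)
  withr::with_seed(seed, {
    ref_list <- purrr::imap(scheme$windows, function(w, d) {
      k <- match(d, doms)
      if (w[2L] - w[1L] + 1L < atoms_per_domain) {
        abort(paste0("window ", d, " smaller than atoms_per_domain"))
      }
      centroid <- c(60 * cos(0.45 * k), 60 * sin(0.45 * k), 9 * k)
      xyz <- matrix(rnorm(3L * atoms_per_domain, sd = 8), ncol = 3L)
      xyz <- sweep(xyz, 2L, colMeans(xyz))       # exact centroid
      xyz <- sweep(xyz, 2L, centroid, "+")
      resno <- round(seq(w[1L], w[2L], length.out = atoms_per_domain))
      if (anyDuplicated(resno)) {
        resno <- seq(w[1L], length.out = atoms_per_domain)
      }
      new_atom_tbl("ATOM", "CA", "ALA", "A", resno, xyz, "C")
    })
    reference <- renumber_atoms(bind_rows(ref_list))
    truth <- list(seed = seed)
    mov_list <- purrr::imap(ref_list, function(a, d) {
      tr <- transforms[[d]]
      angle <- tr$angle %||% 0
      axis <- tr$axis %||% c(0, 0, 1)
      shift <- tr$translation %||% c(0, 0, 0)
      truth[[d]] <<- list(angle = angle, axis = axis, translation = shift)
      R <- rotation_about_axis(angle, axis)
      xyz <- coord_matrix(a)
      ctr <- colMeans(xyz)
      xyz <- sweep(sweep(xyz, 2L, ctr) %*% t(R), 2L, ctr + shift, "+")
      a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
      a
    })
    transformed <- renumber_atoms(bind_rows(mov_list))
    if (noise_sigma > 0) {
      n <- nrow(transformed)
      transformed$x <- transformed$x + rnorm(n, sd = noise_sigma)
      transformed$y <- transformed$y + rnorm(n, sd = noise_sigma)
      transformed$z <- transformed$z + rnorm(n, sd = noise_sigma)
    }
    list(reference = reference, transformed = transformed, truth = truth)
  })
}

#' Cluster of isolated atoms for analytic SASA checks
#'
#' One chain, one single-atom residue per position, written as HETATM
#' records, so accessible areas can be compared against closed-form sphere
#' and spherical-cap formulas.
#'
#' @param positions N x 3 matrix of centres (angstrom).
#' @param elements Character vector of element symbols, length N (or 1).
#' @param chain Chain identifier.
#' @return An atom table.
#' @export
make_sphere_cluster <- function(positions, elements, chain = "A") {
  positions <- coord_matrix(positions)
  elements <- rep_len(toupper(elements), nrow(positions))
  new_atom_tbl("HETATM", elements, "LIG", chain,
               seq_len(nrow(positions)), positions, elements)
}

#' Idealised six-membered ring at given Cremer-Pople coordinates
#'
#' Builds ring coordinates from the Cremer-Pople forward equations: atoms
#' on a circle of radius `radius` in the mean plane, displaced
#' perpendicular to it by
#' `z_j = sqrt(1/3) q2 cos(phi2 + 4 pi j / 6) + sqrt(1/6) q3 (-1)^j` with
#' `q2 = Q sin(theta)`, `q3 = Q cos(theta)`. The construction satisfies the
#' Cremer-Pople mean-plane conditions exactly, so [cremer_pople()] inverts
#' it to the requested parameters.
#'
#' @param conformer Canonical conformer label (e.g. `"4C1"`, `"1S3"`); its
#'   (theta, phi2) are looked up and used with `q`.
#' @param q Total puckering amplitude Q in angstrom (default 0.57, a
#'   typical pyranose value).
#' @param theta,phi2 Explicit Cremer-Pople angles in degrees (used when
#'   `conformer` is `NULL`).
#' @param radius In-plane ring radius, angstrom.
#' @return A 6 x 3 matrix with rows named O5, C1..C5.
#' @export
make_ring <- function(conformer = NULL, q = 0.57, theta = NULL, phi2 = NULL,
                      radius = 1.46) {
  if (!is.null(conformer)) {
    tab <- cp_canonical()
    hit <- match(conformer, tab$label)
    if (is.na(hit)) abort(paste0("unknown conformer label: ", conformer))
    theta <- tab$theta[hit]
    phi2 <- tab$phi2[hit]
  }
  if (is.null(theta) || is.null(phi2)) {
    abort("supply either a conformer label or (q, theta, phi2)")
  }
  j <- 0:5
  q2 <- q * sin(rad(theta))
  q3 <- q * cos(rad(theta))
  z <- sqrt(1 / 3) * q2 * cos(rad(phi2) + 4 * pi * j / 6) +
    sqrt(1 / 6) * q3 * (-1)^j
  # clockwise placement so the computed mean-plane normal is +z
  ang <- -2 * pi * j / 6
  ring <- cbind(radius * cos(ang), radius * sin(ang), z)
  rownames(ring) <- .ring_atoms
  ring
}

# Ideal pyranose residue (4C1 unless stated): ring plus the exocyclic
# substituents needed for linkage building and glycan detection.
ideal_pyranose <- function(resid = "NAG", resno = 1L, chain = "A",
                           conformer = "4C1") {
  ring <- make_ring(conformer)
  centroid <- colMeans(ring)
  radial <- function(at) unit_vec(c(ring[at, 1L] - centroid[1L],
                                    ring[at, 2L] - centroid[2L], 0))
  ex <- list()
  add <- function(name, pos) ex[[name]] <<- pos
  add("O3", ring["C3", ] + 1.43 * radial("C3"))
  add("O4", ring["C4", ] + 1.43 * radial("C4"))
  if (resid == "FUC") {
    add("C6", ring["C5", ] + 1.52 * radial("C5"))
    add("O2", ring["C2", ] + 1.43 * radial("C2"))
  } else {
    add("C6", ring["C5", ] + 1.52 * unit_vec(radial("C5") + c(0, 0, 1)))
    add("O6", ex[["C6"]] + 1.43 * unit_vec(radial("C5") + c(0, 0, -0.3)))
    if (resid %in% c("NAG", "NDG")) {
      add("N2", ring["C2", ] + 1.45 * radial("C2"))
    } else {
      add("O2", ring["C2", ] + 1.43 * radial("C2"))
    }
  }
  names_all <- c(rownames(ring), names(ex))
  xyz <- rbind(ring, do.call(rbind, ex))
  elesy <- substr(gsub("[0-9]", "", names_all), 1L, 1L)
  new_atom_tbl("HETATM", names_all, resid, chain, resno, xyz, elesy)
}

# NeRF internal-coordinate placement: point d with |c-d| = bond,
# angle(b,c,d) = ang (deg), dihedral(a,b,c,d) = dih (deg).
place_atom <- function(a, b, c, bond, ang, dih) {
  th <- rad(ang)
  ph <- rad(dih)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph),
          -bond * sin(th) * sin(ph))
  bc <- unit_vec(c - b)
  n <- unit_vec(vec_cross(b - a, bc))
  M <- cbind(bc, vec_cross(n, bc), n)
  as.numeric(M %*% d2 + c)
}

# Attach an ideal sugar (donor, provides C1) to an acceptor atom with
# exact glycosidic (phi, psi). Works for O-linkages and the N-glycosidic
# bond to Asn ND2.
attach_sugar <- function(atoms, acceptor_chain, acceptor_resno,
                         acceptor_atom, new_sugar, phi, psi) {
  acc <- residue_atoms(atoms, acceptor_chain, acceptor_resno)
  p_ox <- atom_xyz(acc, acceptor_atom)
  if (acceptor_atom == "ND2") {
    p_cx <- atom_xyz(acc, "CG"); p_cn <- atom_xyz(acc, "CB")
  } else {
    x <- as.integer(gsub("[^0-9]", "", acceptor_atom))
    p_cx <- atom_xyz(acc, paste0("C", x))
    cn_name <- if (paste0("C", x + 1L) %in% acc$elety &&
                   vec_norm(atom_xyz(acc, paste0("C", x + 1L)) - p_cx) <= 1.8)
      paste0("C", x + 1L) else paste0("C", x - 1L)
    p_cn <- atom_xyz(acc, cn_name)
  }
  # psi places C1; phi then places the donor O5 direction
  c1_t <- place_atom(p_cn, p_cx, p_ox, 1.41, 117, psi)
  o5_t <- place_atom(p_cx, p_ox, c1_t, 1.43, 108, phi)
  # rigid-map the ideal sugar so C1 sits at c1_t and its O5 points at o5_t
  loc <- new_sugar
  l_c1 <- atom_xyz(loc, "C1"); l_o5 <- atom_xyz(loc, "O5")
  l_c2 <- atom_xyz(loc, "C2")
  frame <- function(p0, p1, p2) {
    u <- unit_vec(p1 - p0)
    w <- unit_vec(vec_cross(u, p2 - p0))
    cbind(u, vec_cross(w, u), w)
  }
  t_aux <- if (abs(sum(unit_vec(o5_t - c1_t) * c(0, 0, 1))) < 0.9) {
    c1_t + c(0, 0, 1)
  } else c1_t + c(0, 1, 0)
  R <- frame(c1_t, o5_t, t_aux) %*% t(frame(l_c1, l_o5, l_c2))
  xyz <- coord_matrix(loc)
  xyz <- sweep(sweep(xyz, 2L, l_c1) %*% t(R), 2L, c1_t, "+")
  loc$x <- xyz[, 1L]; loc$y <- xyz[, 2L]; loc$z <- xyz[, 3L]
  renumber_atoms(bind_rows(atoms, loc))
}

#' Idealised disaccharide with exact glycosidic torsions
#'
#' Two idealised 4C1 pyranoses joined so that [glycosidic_torsions()]
#' returns exactly the requested `(phi, psi)` for the linkage through
#' `linkage_oxygen` of residue 1 (the donor, residue 2, provides C1).
#'
#' @param phi,psi Glycosidic torsions in degrees, in (-180, 180].
#' @param linkage_oxygen Acceptor oxygen name, e.g. `"O4"` (beta-1,4 core)
#'   or `"O6"`.
#' @param resid Saccharide code for both rings.
#' @param chain Chain identifier.
#' @return An atom table of the two residues.
#' @examples
#' d <- make_disaccharide(5.9, -120)
#' glycosidic_torsions(d, "A", donor = 2, acceptor = 1)
#' @export
make_disaccharide <- function(phi, psi, linkage_oxygen = "O4",
                              resid = "NAG", chain = "A") {
  if (phi <= -180 || phi > 180 || psi <= -180 || psi > 180) {
    abort("torsions must lie in (-180, 180]")
  }
  base <- ideal_pyranose(resid, 1L, chain)
  attach_sugar(base, chain, 1L, linkage_oxygen,
               ideal_pyranose(resid, 2L, chain), phi, psi)
}

#' Idealised N-glycan on an asparagine stub
#'
#' An Asn side-chain stub (CA, CB, CG, OD1, ND2; author number 297 by
#' default) carrying a chain of idealised GlcNAc residues linked beta-1,4
#' at exact torsions, optionally with a fucose alpha-1,6 on the first
#' GlcNAc -- the chitobiose core every IgG Fc N-glycan shares.
#'
#' @param phi,psi Vectors of torsions: element 1 is the Asn--GlcNAc1 bond,
#'   element k > 1 the GlcNAc(k-1)--GlcNAc(k) 1,4-linkage.
#' @param asn_resno Residue number of the asparagine.
#' @param fucose If `TRUE`, add FUC on O6 of the first GlcNAc.
#' @param fucose_phi,fucose_psi Torsions of the fucose linkage.
#' @param chain Chain identifier.
#' @return An atom table (ATOM records for Asn, HETATM for sugars).
#' @export
make_nglycan <- function(phi = c(-97, -74), psi = c(178, -120),
                         asn_resno = 297L, fucose = FALSE,
                         fucose_phi = -80, fucose_psi = 175, chain = "A") {
  stopifnot(length(phi) == length(psi), length(phi) >= 1L)
  asn_xyz <- rbind(CA = c(0, 0, 0), CB = c(1.53, 0, 0),
                   CG = c(2.05, 1.42, 0), OD1 = c(1.35, 2.32, -0.48),
                   ND2 = c(3.32, 1.62, 0.48))
  atoms <- new_atom_tbl("ATOM", rownames(asn_xyz), "ASN", chain, asn_resno,
                        asn_xyz, substr(rownames(asn_xyz), 1L, 1L))
  atoms <- attach_sugar(atoms, chain, asn_resno, "ND2",
                        ideal_pyranose("NAG", 1L, chain), phi[1L], psi[1L])
  if (length(phi) > 1L) {
    for (k in 2:length(phi)) {
      atoms <- attach_sugar(atoms, chain, k - 1L, "O4",
                            ideal_pyranose("NAG", k, chain), phi[k], psi[k])
    }
  }
  if (fucose) {
    atoms <- attach_sugar(atoms, chain, 1L, "O6",
                          ideal_pyranose("FUC", length(phi) + 1L, chain),
                          fucose_phi, fucose_psi)
  }
  atoms
}

#' Write a fixture structure (with optional ground-truth sidecar)
#'
#' Thin wrapper over [write_structure()] that can also serialise the
#' generator's ground truth next to the coordinate file (as
#' `<path>.json`), so tests read the applied parameters instead of
#' re-deriving them.
#'
#' @inheritParams write_structure
#' @param truth Optional list written as a JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(atoms, path, format = c("auto", "pdb", "cif"),
                          truth = NULL) {
  write_structure(atoms, path, format)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
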
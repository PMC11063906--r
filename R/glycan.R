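# Pyranose ring atoms in Cremer-Pople order.
.ring_atoms <- c("O5", "C1", "C2", "C3", "C4", "C5")

residue_atoms <- function(atoms, chain, resno) {
  filter(atoms, .data$chain == !!chain, .data$resno == !!resno)
}

atom_xyz <- function(res_atoms, name) {
  row <- filter(res_atoms, .data$elety == name)
  if (!nrow(row)) {
    abort(paste0("atom ", name, " missing from ", res_atoms$resid[1L], " ",
                 res_atoms$resno[1L]), class = "structcomp_missing_atom")
  }
  c(row$x[1L], row$y[1L], row$z[1L])
}

is_pyranose <- function(res_atoms) {
  res_atoms$is_het[1L] && all(.ring_atoms %in% res_atoms$elety)
}

#' Detect an N-linked glycan by covalent walk from an asparagine
#'
#' Starting at the Asn side-chain nitrogen (ND2), performs a breadth-first
#' walk over pyranose HETATM residues using covalent anomeric bonds: a
#' sugar joins the tree when its C1 lies within `bond_cutoff` of the Asn
#' ND2 or of an oxygen of a sugar already in the tree. Each inter-sugar
#' linkage is typed by its acceptor oxygen (O4 for the beta-1,4 chitobiose
#' core, O6 for alpha-1,6 fucosylation, ...) and annotated with glycosidic
#' phi/psi torsions. The result is independent of atom record order.
#'
#' @param atoms Atom table.
#' @param chain Chain carrying the asparagine (glycan HETATMs must share
#'   it).
#' @param asn Author residue number of the asparagine (e.g. 297 for the
#'   IgG1 Fc glycosylation site).
#' @param bond_cutoff Covalent C--O / C--N upper bound in angstrom; 1.8 is
#'   a safe single-bond bound at typical crystallographic resolution.
#' @return Object of class `glycan_tree`: list with `residues` (tibble:
#'   `resno`, `resid`, `level`) and `linkages` (tibble: donor/acceptor
#'   residue, `acceptor_atom`, `linkage` label, `phi`, `psi`).
#' @examples
#' g <- make_nglycan(phi = c(-74, -102), psi = c(-120, -130))
#' detect_glycan(g, chain = "A", asn = 297)
#' @export
detect_glycan <- function(atoms, chain, asn, bond_cutoff = 1.8) {
  asn_atoms <- residue_atoms(atoms, chain, asn)
  if (!nrow(asn_atoms) || !"ND2" %in% asn_atoms$elety) {
    abort("asparagine with an ND2 atom not found",
          class = "structcomp_no_glycan")
  }
  het <- filter(atoms, .data$chain == !!chain, .data$is_het)
  sugars <- split(het, het$resno)
  sugars <- sugars[vapply(sugars, is_pyranose, logical(1))]
  if (!length(sugars)) {
    abort("no saccharide residues on the chain", class = "structcomp_no_glycan")
  }
  sugar_resno <- sort(as.integer(names(sugars)))

  # acceptor atom pool, grown as residues join the tree
  acceptors <- asn_atoms |>
    filter(.data$elety == "ND2") |>
    mutate(owner = asn)
  residues <- tibble(resno = integer(), resid = character(),
                     level = integer())
  linkages <- tibble(donor_resno = integer(), donor_resid = character(),
                     acceptor_resno = integer(), acceptor_resid = character(),
                     acceptor_atom = character(), linkage = character(),
                     phi = numeric(), psi = numeric())
  remaining <- sugar_resno
  level <- 0L
  repeat {
    # candidate bonds: C1 of any remaining sugar vs current acceptor pool
    cand <- purrr::map(remaining, function(rn) {
      c1 <- tryCatch(atom_xyz(sugars[[as.character(rn)]], "C1"),
                     structcomp_missing_atom = function(e) NULL)
      if (is.null(c1)) return(NULL)
      d <- sqrt((acceptors$x - c1[1L])^2 + (acceptors$y - c1[2L])^2 +
                  (acceptors$z - c1[3L])^2)
      k <- which.min(d)
      if (d[k] > bond_cutoff) return(NULL)
      tibble(donor_resno = rn, acceptor_resno = acceptors$owner[k],
             acceptor_atom = acceptors$elety[k], d = d[k])
    })
    cand <- bind_rows(cand)
    if (!nrow(cand)) break
    cand <- arrange(cand, .data$d, .data$donor_resno)
    level <- level + 1L
    for (k in seq_len(nrow(cand))) {
      rn <- cand$donor_resno[k]
      res <- sugars[[as.character(rn)]]
      residues <- bind_rows(residues,
                            tibble(resno = rn, resid = res$resid[1L],
                                   level = level))
      tor <- glycosidic_torsions(atoms, chain = chain, donor = rn,
                                 acceptor = cand$acceptor_resno[k],
                                 acceptor_atom = cand$acceptor_atom[k],
                                 quiet = TRUE)
      ox <- cand$acceptor_atom[k]
      linkages <- bind_rows(linkages, tibble(
        donor_resno = rn, donor_resid = res$resid[1L],
        acceptor_resno = cand$acceptor_resno[k],
        acceptor_resid = if (cand$acceptor_resno[k] == asn) "ASN" else
          sugars[[as.character(cand$acceptor_resno[k])]]$resid[1L],
        acceptor_atom = ox,
        linkage = if (ox == "ND2") "N-glycosidic" else
          paste0("1-", gsub("[^0-9]", "", ox)),
        phi = tor[["phi"]], psi = tor[["psi"]]))
      # this sugar's oxygens become acceptors for the next shell
      new_acc <- filter(res, .data$elesy == "O", .data$elety != "O5")
      if (nrow(new_acc)) {
        acceptors <- bind_rows(acceptors, mutate(new_acc, owner = rn))
      }
    }
    remaining <- setdiff(remaining, cand$donor_resno)
    if (!length(remaining)) break
  }
  if (!nrow(residues)) {
    abort("no saccharide within bond distance of the asparagine",
          class = "structcomp_no_glycan")
  }
  structure(list(asn = asn, chain = chain,
                 residues = arrange(residues, .data$level, .data$resno),
                 linkages = arrange(linkages, .data$donor_resno)),
            class = "glycan_tree")
}

#' @export
print.glycan_tree <- function(x, ...) {
  cat("<glycan_tree> at Asn", x$asn, "chain", x$chain, "-",
      nrow(x$residues), "saccharides,", nrow(x$linkages), "linkages\n")
  print(x$linkages)
  invisible(x)
}

#' @rdname detect_glycan
#' @param x A `glycan_tree`.
#' @param ... Unused.
#' @method tidy glycan_tree
#' @export
tidy.glycan_tree <- function(x, ...) x$linkages

#' Glycosidic phi/psi torsion angles of one linkage
#'
#' Heavy-atom convention: `phi = O5-C1-Ox-Cx` and `psi = C1-Ox-Cx-C(x+1)`,
#' where Ox is the acceptor oxygen, Cx the ring carbon bearing it and
#' C(x+1) the next ring carbon (C5 is used for 1,6-linkages, where C7 does
#' not exist; CG/CB are used for the N-glycosidic bond to Asn ND2). This
#' matches the convention of crystallographic linkage surveys, e.g. a core
#' GlcNAc-beta-1,4-GlcNAc phi of -74 +/- 8.4 degrees. An explicit-hydrogen
#' (NMR) convention `phi = H1-C1-Ox-Cx` is available when hydrogens are
#' present.
#'
#' @param atoms Atom table.
#' @param chain Chain identifier.
#' @param donor Residue number of the sugar providing C1.
#' @param acceptor Residue number of the residue providing the linkage
#'   oxygen (or the Asn providing ND2).
#' @param acceptor_atom Name of the linkage atom on the acceptor (e.g.
#'   `"O4"`, `"O6"`, `"ND2"`).
#' @param convention `"heavy"` (default) or `"nmr"`.
#' @param quiet Return `NA` rather than erroring when atoms are missing.
#' @return Named numeric `c(phi = , psi = )` in degrees, in (-180, 180].
#' @export
glycosidic_torsions <- function(atoms, chain, donor, acceptor,
                                acceptor_atom = "O4",
                                convention = c("heavy", "nmr"),
                                quiet = FALSE) {
  convention <- match.arg(convention)
  don <- residue_atoms(atoms, chain, donor)
  acc <- residue_atoms(atoms, chain, acceptor)
  get <- function(res, name) {
    if (quiet) {
      tryCatch(atom_xyz(res, name),
               structcomp_missing_atom = function(e) NULL)
    } else atom_xyz(res, name)
  }
  first_atom <- if (convention == "heavy") "O5" else "H1"
  p_first <- get(don, first_atom)
  p_c1 <- get(don, "C1")
  p_ox <- get(acc, acceptor_atom)
  if (acceptor_atom == "ND2") {
    cx_name <- "CG"; cnext_name <- "CB"
  } else {
    x <- as.integer(gsub("[^0-9]", "", acceptor_atom))
    cx_name <- paste0("C", x)
    # psi reference: the next carbon covalently bonded to Cx (exocyclic C6
    # links back to ring C5; the acetamido C7 of GlcNAc is bonded to N2,
    # never to C6, so a plain name lookup would mislead)
    cx_here <- get(acc, cx_name)
    cnext_name <- NULL
    for (cand in c(paste0("C", x + 1L), paste0("C", x - 1L))) {
      p <- tryCatch(atom_xyz(acc, cand),
                    structcomp_missing_atom = function(e) NULL)
      if (!is.null(p) && !is.null(cx_here) && vec_norm(p - cx_here) <= 1.8) {
        cnext_name <- cand
        break
      }
    }
    if (is.null(cnext_name)) {
      if (quiet) return(c(phi = NA_real_, psi = NA_real_))
      abort(paste0("no ring carbon bonded to ", cx_name, " found"),
            class = "structcomp_missing_atom")
    }
  }
  p_cx <- get(acc, cx_name)
  p_cn <- get(acc, cnext_name)
  pts <- list(p_first, p_c1, p_ox, p_cx, p_cn)
  if (any(vapply(pts, is.null, logical(1)))) {
    return(c(phi = NA_real_, psi = NA_real_))
  }
  c(phi = dihedral_angle(p_first, p_c1, p_ox, p_cx),
    psi = dihedral_angle(p_c1, p_ox, p_cx, p_cn))
}

# Canonical pyranose conformers on the Cremer-Pople sphere,
# (theta, phi2) in degrees; labels use ring-atom numbering with O5 = O.
cp_canonical <- function() {
  tab <- tibble(
    label = c("4C1", "1C4",
              "3,OB", "B1,4", "2,5B", "B3,O", "1,4B", "B2,5",
              "3S1", "5S1", "2SO", "1S3", "1S5", "OS2",
              "OE", "OH1", "E1", "2H1", "2E", "2H3",
              "E3", "4H3", "4E", "4H5", "E5", "OH5",
              "3E", "3H2", "E2", "1H2", "1E", "1HO",
              "EO", "5HO", "5E", "5H4", "E4", "3H4"),
    theta = c(0, 180,
              rep(90, 12),
              rep(54.7, 12),
              rep(125.3, 12)),
    phi2 = c(0, 0,
             seq(0, 300, by = 60), seq(30, 330, by = 60),
             seq(0, 330, by = 30),
             seq(0, 330, by = 30)))
  tab
}

#' Cremer-Pople puckering parameters of a six-membered ring
#'
#' Computes the total puckering amplitude `Q` (angstrom), the polar angle
#' `theta` (0 = one chair, 180 = the inverted chair, 90 = boats and skew
#' boats) and the pseudorotation phase `phi2` from the out-of-mean-plane
#' displacements of the six ring atoms, which must be ordered
#' O5, C1, C2, C3, C4, C5. The nearest canonical conformer on the
#' (theta, phi2) sphere is reported as a label; rings with `Q` below 0.05
#' angstrom are labelled `"planar"`.
#'
#' @param ring A 6 x 3 coordinate matrix in ring order, or an atom table of
#'   one ring from which the six ring atoms are extracted.
#' @return One-row tibble: `Q`, `theta`, `phi2`, `conformer`.
#' @examples
#' cremer_pople(make_ring("4C1"))
#' cremer_pople(make_ring(q = 0.6, theta = 90, phi2 = 210))
#' @export
cremer_pople <- function(ring) {
  if (is.data.frame(ring)) {
    idx <- match(.ring_atoms, ring$elety)
    if (anyNA(idx)) abort("ring atoms O5,C1..C5 not all present")
    ring <- coord_matrix(ring)[idx, , drop = FALSE]
  }
  ring <- coord_matrix(ring)
  if (nrow(ring) != 6L) abort("a pyranose ring has exactly 6 atoms")
  x <- sweep(ring, 2L, colMeans(ring))
  j <- 0:5
  rp <- colSums(x * sin(2 * pi * j / 6))
  rpp <- colSums(x * cos(2 * pi * j / 6))
  nrm <- unit_vec(vec_cross(rp, rpp))
  z <- as.numeric(x %*% nrm)
  q2c <- sqrt(1 / 3) * sum(z * cos(4 * pi * j / 6))
  q2s <- -sqrt(1 / 3) * sum(z * sin(4 * pi * j / 6))
  q2 <- sqrt(q2c^2 + q2s^2)
  phi2 <- deg(atan2(q2s, q2c)) %% 360
  q3 <- sqrt(1 / 6) * sum((-1)^j * z)
  Q <- sqrt(q2^2 + q3^2)
  theta <- deg(atan2(q2, q3))
  tibble(Q = Q, theta = theta, phi2 = phi2,
         conformer = cp_label(Q, theta, phi2))
}

cp_label <- function(Q, theta, phi2) {
  if (Q < 0.05) return("planar")
  tab <- cp_canonical()
  # great-circle distance on the puckering sphere
  gc <- acos(clamp(
    cos(rad(theta)) * cos(rad(tab$theta)) +
      sin(rad(theta)) * sin(rad(tab$theta)) * cos(rad(phi2 - tab$phi2)),
    -1, 1))
  tab$label[which.min(gc)]
}

#' Puckering of every sugar ring in a glycan
#'
#' @param atoms Atom table.
#' @param glycan A `glycan_tree` from [detect_glycan()].
#' @return Tibble with one row per sugar: `resno`, `resid`, `Q`, `theta`,
#'   `phi2`, `conformer`.
#' @export
ring_puckers <- function(atoms, glycan) {
  stopifnot(inherits(glycan, "glycan_tree"))
  purrr::map2(glycan$residues$resno, glycan$residues$resid, function(rn, rd) {
    res <- residue_atoms(atoms, glycan$chain, rn)
    mutate(cremer_pople(res), resno = rn, resid = rd, .before = 1L)
  }) |> bind_rows()
}

#' Catalytic-dyad geometry around a bound glycosidic linkage
#'
#' Superposes a wild-type enzyme onto the (catalytically inactivated)
#' complex on the C-alpha atoms of the catalytic-domain window, then
#' measures the distances from the wild-type dyad's side-chain carboxyl
#' oxygens (Asp OD1/OD2, Glu OE1/OE2) to the glycosidic oxygen and the
#' anomeric carbon of a target linkage in the complex. Short distances
#' (a few angstrom) indicate the acid/base and nucleophile are positioned
#' for attack on the observed, distorted linkage.
#'
#' @param complex_atoms,wt_atoms Atom tables of complex and wild-type
#'   structures.
#' @param complex_chain,wt_chain Enzyme chain identifiers.
#' @param scheme [domain_scheme()] providing the catalytic (`GH`) window.
#' @param dyad Residue numbers of the catalytic dyad in the wild type.
#' @param glycan_chain Chain carrying the target glycan in the complex.
#' @param donor,acceptor,acceptor_atom Target linkage in the complex (the
#'   donor sugar's C1 and the acceptor oxygen are the measured targets).
#' @param reference_domain Domain used for the superposition.
#' @return Tibble: `dyad_resno`, `dyad_resid`, `dyad_atom`, `target`,
#'   `distance`; attribute `gh_fit_rmsd`.
#' @export
active_site_geometry <- function(complex_atoms, wt_atoms, complex_chain,
                                 wt_chain, scheme = default_scheme("endos2"),
                                 dyad = c(184L, 186L), glycan_chain,
                                 donor, acceptor, acceptor_atom = "O4",
                                 reference_domain = "GH") {
  w <- scheme_window(scheme, reference_domain, align = TRUE)
  m <- match_residues(
    select_atoms(wt_atoms, chain = wt_chain, seq_range = w, atom_names = "CA"),
    select_atoms(complex_atoms, chain = complex_chain, seq_range = w,
                 atom_names = "CA"))
  fit <- kabsch_fit(m$xyz_a, m$xyz_b)
  wt_moved <- apply_transform(wt_atoms, fit)

  don <- residue_atoms(complex_atoms, glycan_chain, donor)
  acc <- residue_atoms(complex_atoms, glycan_chain, acceptor)
  targets <- list(O_glycosidic = atom_xyz(acc, acceptor_atom),
                  C1_anomeric = atom_xyz(don, "C1"))

  carboxyl <- c("OD1", "OD2", "OE1", "OE2")
  rows <- purrr::map(dyad, function(rn) {
    res <- residue_atoms(wt_moved, wt_chain, rn)
    oxy <- filter(res, .data$elety %in% carboxyl)
    if (!nrow(oxy)) {
      abort(paste0("dyad residue ", rn, " has no side-chain carboxyl ",
                   "oxygens"), class = "structcomp_missing_atom")
    }
    purrr::map(seq_len(nrow(oxy)), function(k) {
      p <- c(oxy$x[k], oxy$y[k], oxy$z[k])
      tibble(dyad_resno = rn, dyad_resid = oxy$resid[k],
             dyad_atom = oxy$elety[k],
             target = names(targets),
             distance = unname(vapply(targets, function(t) vec_norm(t - p),
                                      numeric(1))))
    }) |> bind_rows()
  })
  out <- bind_rows(rows)
  attr(out, "gh_fit_rmsd") <- fit$rmsd
  out
}
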
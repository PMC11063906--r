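#' Atomic solvation parameter table
#'
#' Eisenberg-McLachlan-style atomic solvation parameters, expressed as the
#' free-energy gain per buried square angstrom (kcal/mol/A^2): burying
#' apolar surface is favourable (negative), burying polar/charged surface
#' is unfavourable (positive). Classes: `C` (apolar carbon), `S` (sulfur),
#' `N/O` (neutral nitrogen/oxygen), `O-` (carboxylate/terminal oxygens),
#' `N+` (charged nitrogens of Lys/Arg).
#'
#' @param values Optional named numeric vector overriding the defaults.
#' @return An object of class `asp_table`.
#' @export
asp_table <- function(values = NULL) {
  default <- c("C" = -0.016, "S" = -0.021, "N/O" = 0.006,
               "O-" = 0.024, "N+" = 0.050)
  if (!is.null(values)) default[names(values)] <- values
  structure(list(values = default), class = "asp_table")
}

.charged_o <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.charged_n <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))

atom_asp_class <- function(atoms) {
  cls <- rep(NA_character_, nrow(atoms))
  cls[atoms$elesy == "C"] <- "C"
  cls[atoms$elesy == "S"] <- "S"
  cls[atoms$elesy %in% c("N", "O")] <- "N/O"
  co <- purrr::map2_lgl(atoms$resid, atoms$elety,
                        function(r, a) a %in% .charged_o[[r]] || a == "OXT")
  cls[co] <- "O-"
  cn <- purrr::map2_lgl(atoms$resid, atoms$elety,
                        function(r, a) a %in% .charged_n[[r]])
  cls[cn] <- "N+"
  cls[atoms$elesy %in% c("P", "SE")] <- "N/O"
  cls[atoms$elesy == "H"] <- "C"
  if (anyNA(cls)) {
    bad <- which(is.na(cls))[1L]
    abort(paste0("cannot classify atom ", atoms$elety[bad], " (",
                 atoms$elesy[bad], ") in ", atoms$resid[bad], " ",
                 atoms$resno[bad], " for solvation"))
  }
  cls
}

check_disjoint_sides <- function(side_a, side_b) {
  key <- function(s) paste(s$chain, s$resno, s$insert, s$elety, sep = "|")
  if (length(intersect(key(side_a), key(side_b)))) {
    abort("interface sides share atoms", class = "structcomp_overlap_error")
  }
}

# Per-atom accessible-area loss on complexation, in full-chain context.
interface_dsasa <- function(side_a, side_b, radii = radii_table(),
                            n_points = 960L) {
  check_disjoint_sides(side_a, side_b)
  sa <- shrake_rupley_sasa(side_a, radii, n_points)$sasa
  sb <- shrake_rupley_sasa(side_b, radii, n_points)$sasa
  both <- shrake_rupley_sasa(bind_rows(side_a, side_b), radii, n_points)$sasa
  na <- nrow(side_a)
  d_a <- sa - both[seq_len(na)]
  d_b <- sb - both[-seq_len(na)]
  list(d_a = d_a, d_b = d_b,
       buried = (sum(d_a) + sum(d_b)) / 2)
}

#' Buried interface area between two sides
#'
#' PISA-convention buried area: half the total solvent-accessible surface
#' lost when the two sides are considered together rather than separately,
#' `(SASA(A) + SASA(B) - SASA(A+B)) / 2`.
#'
#' @param side_a,side_b Atom tables (disjoint; typically two chains with
#'   solvent removed).
#' @param radii A [radii_table()].
#' @param n_points Sphere points per atom for the SASA engine.
#' @return Buried area in angstrom^2.
#' @examples
#' a <- make_sphere_cluster(rbind(c(0, 0, 0)), "C")
#' b <- make_sphere_cluster(rbind(c(2, 0, 0)), "C", chain = "B")
#' interface_area(a, b, radii_table("element", custom = c(C = 1.70)))
#' @export
interface_area <- function(side_a, side_b, radii = radii_table(),
                           n_points = 960L) {
  interface_dsasa(side_a, side_b, radii, n_points)$buried
}

#' Interface area attributed to a domain window of side A
#'
#' Side A atoms are limited to the author-numbering window, but every SASA
#' term is computed in the context of the full chains, so occlusion by the
#' rest of side A is preserved. The window's share of side A's buried
#' surface is then scaled to the total interface area, which makes
#' restricted areas over a partition of side A sum exactly to the total.
#'
#' @inheritParams interface_area
#' @param window Inclusive `c(start, end)` residue window applied to side A.
#' @return Buried area in angstrom^2 attributed to the window.
#' @export
domain_restricted_interface <- function(side_a, side_b, window,
                                        radii = radii_table(),
                                        n_points = 960L) {
  ds <- interface_dsasa(side_a, side_b, radii, n_points)
  in_w <- side_a$resno >= window[1L] & side_a$resno <= window[2L]
  tot_a <- sum(ds$d_a)
  if (tot_a <= 0) return(0)
  sum(ds$d_a[in_w]) / tot_a * ds$buried
}

#' Solvation free-energy gain of an interface
#'
#' Sum over all buried atoms (both sides) of the atomic solvation
#' parameter of the atom's class times its buried accessible area. A
#' negative value means the interface buries predominantly apolar surface
#' and is hydrophobically favourable. Parameter sets for this quantity
#' differ between programs, so magnitudes are comparable only within one
#' convention; the sign and rough scale are robust.
#'
#' @inheritParams interface_area
#' @param asp An [asp_table()].
#' @return Free-energy gain in kcal/mol.
#' @export
solvation_energy_gain <- function(side_a, side_b, asp = asp_table(),
                                  radii = radii_table(), n_points = 960L) {
  ds <- interface_dsasa(side_a, side_b, radii, n_points)
  cls <- c(atom_asp_class(side_a), atom_asp_class(side_b))
  dA <- c(ds$d_a, ds$d_b)
  sum(asp$values[cls] * dA)
}

#' Residue-residue contacts across an interface
#'
#' Residue pairs with any heavy-atom distance at or below the cutoff, with
#' the closest atom pair recorded, sorted by minimum distance.
#'
#' @inheritParams interface_area
#' @param cutoff Heavy-atom distance cutoff in angstrom (default 4.5).
#' @return Tibble: `chain_a`, `resno_a`, `resid_a`, `chain_b`, `resno_b`,
#'   `resid_b`, `atom_a`, `atom_b`, `min_distance`, `n_atom_pairs`.
#' @export
find_contacts <- function(side_a, side_b, cutoff = 4.5) {
  if (cutoff <= 0) abort("cutoff must be positive")
  a <- filter(side_a, .data$elesy != "H")
  b <- filter(side_b, .data$elesy != "H")
  hits <- pairs_within(coord_matrix(a), coord_matrix(b), cutoff)
  if (!nrow(hits)) {
    return(tibble(chain_a = character(), resno_a = integer(),
                  resid_a = character(), chain_b = character(),
                  resno_b = integer(), resid_b = character(),
                  atom_a = character(), atom_b = character(),
                  min_distance = numeric(), n_atom_pairs = integer()))
  }
  i <- hits[, "i"]; j <- hits[, "j"]
  tibble(chain_a = a$chain[i], resno_a = a$resno[i], resid_a = a$resid[i],
         atom_a = a$elety[i], chain_b = b$chain[j], resno_b = b$resno[j],
         resid_b = b$resid[j], atom_b = b$elety[j], d = hits[, "d"]) |>
    group_by(.data$chain_a, .data$resno_a, .data$resid_a,
             .data$chain_b, .data$resno_b, .data$resid_b) |>
    summarise(atom_a = .data$atom_a[which.min(.data$d)],
              atom_b = .data$atom_b[which.min(.data$d)],
              min_distance = min(.data$d), n_atom_pairs = dplyr::n(),
              .groups = "drop") |>
    arrange(.data$min_distance)
}

# Hydrogen-bond donor / acceptor heavy atoms per residue type. Backbone N
# donates, backbone O (and OXT) accepts, for every amino acid; sugars use
# their hydroxyls. Unlisted residues fall back to: N donates, O both.
.hb_donors <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", TRP = "NE1",
  ASN = "ND2", GLN = "NE2", LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2"),
  NAG = c("O3", "O4", "O6", "N2"), NDG = c("O3", "O4", "O6", "N2"),
  BMA = c("O2", "O3", "O4", "O6"), MAN = c("O2", "O3", "O4", "O6"),
  GAL = c("O2", "O3", "O4", "O6"), GLC = c("O2", "O3", "O4", "O6"),
  FUC = c("O2", "O3", "O4"))
.hb_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD",
  CYS = "SG",
  NAG = c("O3", "O4", "O5", "O6", "O7", "O1"),
  NDG = c("O3", "O4", "O5", "O6", "O7", "O1"),
  BMA = c("O2", "O3", "O4", "O5", "O6", "O1"),
  MAN = c("O2", "O3", "O4", "O5", "O6", "O1"),
  GAL = c("O2", "O3", "O4", "O5", "O6", "O1"),
  GLC = c("O2", "O3", "O4", "O5", "O6", "O1"),
  FUC = c("O2", "O3", "O4", "O5"))
.amino3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL", "MSE", "SEC", "PYL")

hb_role <- function(atoms, role = c("donor", "acceptor")) {
  role <- match.arg(role)
  tab <- if (role == "donor") .hb_donors else .hb_acceptors
  known <- atoms$resid %in% c(.amino3, names(tab))
  side <- purrr::map2_lgl(atoms$resid, atoms$elety,
                          function(r, a) a %in% tab[[r]])
  backbone <- if (role == "donor") {
    atoms$elety == "N" & atoms$resid %in% .amino3 & atoms$resid != "PRO"
  } else {
    atoms$elety %in% c("O", "OXT") & atoms$resid %in% .amino3
  }
  fallback <- !known & (if (role == "donor") atoms$elesy %in% c("N", "O")
                        else atoms$elesy %in% c("O", "N"))
  side | backbone | fallback
}

# Heavy-atom antecedents of a donor: covalently bonded atoms (< 1.8 A)
# in the same residue, used for the geometric plausibility test.
donor_antecedents <- function(donor_row, residue_atoms) {
  xyz <- coord_matrix(residue_atoms)
  d <- sqrt(rowSums(sweep(xyz, 2L,
                          c(donor_row$x, donor_row$y, donor_row$z))^2))
  keep <- d > 1e-6 & d <= 1.8 & residue_atoms$elesy != "H"
  residue_atoms[keep, , drop = FALSE]
}

#' Hydrogen bonds across an interface
#'
#' Donor-acceptor heavy-atom pairs at 2.2--`cutoff` angstrom, typed from
#' per-residue donor/acceptor templates (backbone N/O for every amino
#' acid, side-chain and sugar hydroxyls as listed). No explicit-hydrogen
#' angle test is applied -- appropriate at the ~3 angstrom resolutions
#' where hydrogens are not modelled -- but when a donor's covalent
#' antecedent is present, the antecedent-donor-acceptor angle must be at
#' least 90 degrees to exclude geometrically impossible pairs.
#'
#' @inheritParams interface_area
#' @param cutoff Donor-acceptor heavy-atom distance cutoff (default 3.5).
#' @return Tibble: donor chain/resno/resid/atom, acceptor
#'   chain/resno/resid/atom, `distance`. Every bond also appears in
#'   [find_contacts()] at any cutoff >= `cutoff`.
#' @export
find_hydrogen_bonds <- function(side_a, side_b, cutoff = 3.5) {
  one_direction <- function(sa, sb) {
    don <- filter(sa, hb_role(sa, "donor"))
    acc <- filter(sb, hb_role(sb, "acceptor"))
    if (!nrow(don) || !nrow(acc)) return(NULL)
    hits <- pairs_within(coord_matrix(don), coord_matrix(acc), cutoff)
    hits <- hits[hits[, "d"] >= 2.2, , drop = FALSE]
    if (!nrow(hits)) return(NULL)
    rows <- purrr::map(seq_len(nrow(hits)), function(k) {
      dr <- don[hits[k, "i"], ]
      ar <- acc[hits[k, "j"], ]
      res_atoms <- filter(sa, .data$chain == dr$chain,
                          .data$resno == dr$resno, .data$insert == dr$insert)
      ante <- donor_antecedents(dr, res_atoms)
      if (nrow(ante)) {
        angs <- vapply(seq_len(nrow(ante)), function(m) {
          vertex_angle(c(ante$x[m], ante$y[m], ante$z[m]),
                       c(dr$x, dr$y, dr$z), c(ar$x, ar$y, ar$z))
        }, numeric(1))
        if (min(angs) < 90) return(NULL)
      }
      tibble(donor_chain = dr$chain, donor_resno = dr$resno,
             donor_resid = dr$resid, donor_atom = dr$elety,
             acceptor_chain = ar$chain, acceptor_resno = ar$resno,
             acceptor_resid = ar$resid, acceptor_atom = ar$elety,
             distance = unname(hits[k, "d"]))
    })
    bind_rows(rows)
  }
  out <- bind_rows(one_direction(side_a, side_b),
                   one_direction(side_b, side_a))
  if (is.null(out) || !nrow(out)) {
    return(tibble(donor_chain = character(), donor_resno = integer(),
                  donor_resid = character(), donor_atom = character(),
                  acceptor_chain = character(), acceptor_resno = integer(),
                  acceptor_resid = character(), acceptor_atom = character(),
                  distance = numeric()))
  }
  arrange(distinct(out), .data$distance)
}

#' Full interface report for a chain (or domain-restricted) pair
#'
#' Bundles buried area, solvation-energy gain, residue contacts and
#' hydrogen bonds for one pair of sides. With `restriction`, the buried
#' area is additionally attributed to that window of side A (contacts and
#' bonds are then limited to residues in the window).
#'
#' @inheritParams interface_area
#' @inheritParams solvation_energy_gain
#' @param restriction Optional `c(start, end)` window applied to side A.
#' @param contact_cutoff,hbond_cutoff Distance cutoffs in angstrom.
#' @return Object of class `interface_report`: list with `buried_area`,
#'   `delta_g_solv`, `contacts`, `hbonds`, `restriction`, `n_points`.
#' @export
interface_report <- function(side_a, side_b, restriction = NULL,
                             radii = radii_table(), asp = asp_table(),
                             n_points = 960L, contact_cutoff = 4.5,
                             hbond_cutoff = 3.5) {
  side_a <- drop_solvent(side_a)
  side_b <- drop_solvent(side_b)
  ds <- interface_dsasa(side_a, side_b, radii, n_points)
  buried <- if (is.null(restriction)) {
    ds$buried
  } else {
    in_w <- side_a$resno >= restriction[1L] & side_a$resno <= restriction[2L]
    if (sum(ds$d_a) > 0) sum(ds$d_a[in_w]) / sum(ds$d_a) * ds$buried else 0
  }
  ca <- if (is.null(restriction)) side_a else {
    filter(side_a, .data$resno >= restriction[1L],
           .data$resno <= restriction[2L])
  }
  contacts <- find_contacts(ca, side_b, contact_cutoff)
  hbonds <- find_hydrogen_bonds(ca, side_b, hbond_cutoff)
  cls <- c(atom_asp_class(side_a), atom_asp_class(side_b))
  dg <- sum(asp$values[cls] * c(ds$d_a, ds$d_b))
  structure(list(buried_area = buried, delta_g_solv = dg,
                 contacts = contacts, hbonds = hbonds,
                 restriction = restriction, n_points = n_points),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf(paste0("<interface_report> buried area %.1f A^2, ",
                     "dG(solv) %.2f kcal/mol, %d contacts, %d H-bonds\n"),
              x$buried_area, x$delta_g_solv, nrow(x$contacts),
              nrow(x$hbonds)))
  if (!is.null(x$restriction)) {
    cat("  side A restricted to residues ", x$restriction[1L], "-",
        x$restriction[2L], "\n", sep = "")
  }
  invisible(x)
}

#' @rdname interface_report
#' @param x An `interface_report`.
#' @param ... Unused.
#' @method tidy interface_report
#' @export
tidy.interface_report <- function(x, ...) x$contacts

#' @rdname interface_report
#' @method glance interface_report
#' @export
glance.interface_report <- function(x, ...) {
  tibble(buried_area = x$buried_area, delta_g_solv = x$delta_g_solv,
         n_contacts = nrow(x$contacts), n_hbonds = nrow(x$hbonds))
}
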
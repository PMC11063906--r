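#' Van der Waals radii tables for SASA
#'
#' The default `"chothia"` set is the NACCESS/Chothia-style table used by
#' PISA-family interface calculations: aliphatic C 1.87, aromatic and
#' carbonyl C 1.76, N 1.65, O 1.40, S 1.85, P 1.90 angstrom, with a
#' per-element fallback for anything unclassified. The `"element"` set is a
#' plain Bondi-style element table (C 1.70, N 1.55, O 1.52, S 1.80), handy
#' for analytic test systems. `custom` entries (named by element or by
#' `"RESID:ATOM"`) override either set.
#'
#' @param set `"chothia"` or `"element"`.
#' @param probe Probe (solvent) radius in angstrom; 1.4 is a water probe.
#' @param custom Named numeric vector of radius overrides.
#' @return An object of class `radii_table`.
#' @examples
#' radii_table()
#' radii_table("element", custom = c(C = 1.70, O = 1.40))
#' @export
radii_table <- function(set = c("chothia", "element"), probe = 1.4,
                        custom = NULL) {
  set <- match.arg(set)
  if (probe < 0) abort("probe radius must be >= 0")
  elements <- switch(set,
    chothia = c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90, H = 1.00,
                SE = 1.90, FE = 1.47, ZN = 1.39, MG = 1.73, F = 1.47,
                CL = 1.75, BR = 1.85, I = 1.98),
    element = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.09,
                SE = 1.90, FE = 1.47, ZN = 1.39, MG = 1.73, F = 1.47,
                CL = 1.75, BR = 1.85, I = 1.98))
  if (any(elements <= 0) || (!is.null(custom) && any(custom <= 0))) {
    abort("all radii must be positive")
  }
  structure(list(set = set, probe = probe, elements = elements,
                 custom = custom %||% numeric(0)),
            class = "radii_table")
}

# Aromatic-ring and carbonyl carbons (Chothia class 1.76 A). Backbone
# carbonyl C plus sp2 side-chain carbons of the standard residues, and the
# acetamido carbonyl of N-acetyl sugars.
.sp2_carbons <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "CD2", "CE1"),
  ARG = "CZ", ASP = "CG", GLU = "CD", ASN = "CG", GLN = "CD",
  NAG = "C7", NDG = "C7", SIA = c("C1", "C10"))

atom_radii <- function(atoms, radii) {
  stopifnot(inherits(radii, "radii_table"))
  r <- rep(NA_real_, nrow(atoms))
  if (length(radii$custom)) {
    key <- paste0(atoms$resid, ":", atoms$elety)
    hit <- match(key, names(radii$custom))
    r[!is.na(hit)] <- radii$custom[hit[!is.na(hit)]]
    hit <- match(atoms$elesy, names(radii$custom))
    r[is.na(r) & !is.na(hit)] <- radii$custom[hit[is.na(r) & !is.na(hit)]]
  }
  el <- match(atoms$elesy, names(radii$elements))
  r[is.na(r)] <- radii$elements[el[is.na(r)]]
  if (radii$set == "chothia" && !length(radii$custom)) {
    sp2 <- atoms$elety == "C" |
      purrr::map2_lgl(atoms$resid, atoms$elety, function(res, at) {
        at %in% .sp2_carbons[[res]]
      })
    r[atoms$elesy == "C" & sp2] <- 1.76
  }
  if (anyNA(r)) {
    bad <- which(is.na(r))[1L]
    abort(paste0("no radius for atom ", atoms$elety[bad], " (element '",
                 atoms$elesy[bad], "') in residue ", atoms$resid[bad], " ",
                 atoms$resno[bad]))
  }
  r
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Places a deterministic golden-spiral point set on the solvent-expanded
#' sphere (radius `r + probe`) of every atom and counts the points not
#' buried inside any neighbour's expanded sphere; each atom's accessible
#' area is the accessible fraction times `4 * pi * (r + probe)^2`. No
#' randomness is involved, so results are exactly reproducible for a fixed
#' `n_points`.
#'
#' @param atoms Atom table.
#' @param radii A [radii_table()].
#' @param n_points Sphere points per atom (>= 64); 960 gives areas
#'   converged to well under 1 percent on protein-sized systems.
#' @return `atoms` with an added `sasa` column (angstrom^2); attributes
#'   `n_points`, `probe` and `total`.
#' @examples
#' o <- make_sphere_cluster(rbind(c(0, 0, 0)), "O")
#' sum(shrake_rupley_sasa(o)$sasa)  # ~ 4 * pi * 2.8^2
#' @export
shrake_rupley_sasa <- function(atoms, radii = radii_table(),
                               n_points = 960L) {
  if (n_points < 64L) abort("n_points must be at least 64")
  r <- atom_radii(atoms, radii) + radii$probe
  xyz <- coord_matrix(atoms)
  n <- nrow(xyz)
  pts <- golden_spiral_points(n_points)
  area <- numeric(n)
  # neighbour lists via chunked pair search at the largest possible overlap
  nb <- pairs_within(xyz, xyz, cutoff = 2 * max(r))
  nb <- nb[nb[, "i"] != nb[, "j"], , drop = FALSE]
  keep <- nb[, "d"] < r[nb[, "i"]] + r[nb[, "j"]]
  nb <- nb[keep, , drop = FALSE]
  nb_split <- split(nb[, "j"], factor(nb[, "i"], levels = seq_len(n)))
  for (i in seq_len(n)) {
    js <- nb_split[[i]]
    surf <- sweep(pts * r[i], 2L, xyz[i, ], "+")
    if (length(js)) {
      acc <- rep(TRUE, n_points)
      for (j in js) {
        dj <- sweep(surf, 2L, xyz[j, ])
        acc <- acc & (rowSums(dj * dj) >= r[j]^2)
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    area[i] <- frac * 4 * pi * r[i]^2
  }
  atoms$sasa <- area
  attr(atoms, "n_points") <- as.integer(n_points)
  attr(atoms, "probe") <- radii$probe
  attr(atoms, "total") <- sum(area)
  atoms
}
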
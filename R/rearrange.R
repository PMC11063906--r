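#' Quantify inter-domain rearrangement between two conformers
#'
#' Aligns conformer A onto conformer B on the C-alpha atoms of a reference
#' domain, then reports, for every other domain of the scheme: the RMSD of
#' its matched C-alpha positions *without re-fitting* (how far the domain
#' moved as a rigid body carried by the reference frame) and the rotation
#' angle of a local Kabsch fit of that domain (how much it reoriented).
#' This is the standard way to express statements such as "aligned on the
#' catalytic domain, the adjacent domain is offset by 10 degrees and the
#' distal domains are displaced by 8.2 and 19.4 angstrom".
#'
#' The reported angle is the total rotation magnitude of the best-fit
#' domain-to-domain transform; no projection onto a hinge axis is applied,
#' since published "tilt" values rarely state an axis convention.
#'
#' @param atoms_a,atoms_b Atom tables for the two conformers.
#' @param chain_a,chain_b Chain identifiers within each table.
#' @param scheme A [domain_scheme()].
#' @param reference Name of the reference domain (its alignment window is
#'   used when the scheme defines one).
#' @return A tibble of class `domain_rearrangement` with columns `domain`,
#'   `rotation_deg`, `displacement_rmsd`, `n_matched`; attributes
#'   `reference`, `reference_fit_rmsd`, `reference_n`. Domains with fewer
#'   than 3 matched C-alpha are skipped with a warning.
#' @examples
#' toy <- make_multidomain_toy(
#'   transforms = list(LRR = list(angle = 10, axis = c(0, 0, 1))),
#'   seed = 1)
#' domain_rearrangement(toy$reference, toy$transformed, "A", "A",
#'                      default_scheme("endos2"), reference = "GH")
#' @export
domain_rearrangement <- function(atoms_a, atoms_b, chain_a = NULL,
                                 chain_b = NULL, scheme, reference) {
  stopifnot(inherits(scheme, "domain_scheme"))
  ca <- function(atoms, chain, window) {
    select_atoms(atoms, chain = chain, seq_range = window, atom_names = "CA")
  }
  ref_w <- scheme_window(scheme, reference, align = TRUE)
  ref <- match_residues(ca(atoms_a, chain_a, ref_w), ca(atoms_b, chain_b, ref_w))
  fit <- kabsch_fit(ref$xyz_a, ref$xyz_b)

  rows <- purrr::map(setdiff(names(scheme$windows), reference), function(d) {
    w <- scheme_window(scheme, d)
    m <- tryCatch(
      match_residues(ca(atoms_a, chain_a, w), ca(atoms_b, chain_b, w)),
      structcomp_empty_selection = function(e) NULL,
      structcomp_no_overlap = function(e) NULL)
    if (is.null(m) || m$n_matched < 3L) {
      warn(paste0("domain ", d, " has fewer than 3 matched C-alpha; skipped"))
      return(NULL)
    }
    moved <- apply_transform(m$xyz_a, fit)
    local <- kabsch_fit(moved, m$xyz_b)
    tibble(domain = d,
           rotation_deg = rotation_angle(local),
           displacement_rmsd = rmsd_noalign(moved, m$xyz_b),
           n_matched = m$n_matched)
  })
  out <- bind_rows(rows)
  attr(out, "reference") <- reference
  attr(out, "reference_fit_rmsd") <- fit$rmsd
  attr(out, "reference_n") <- ref$n_matched
  class(out) <- c("domain_rearrangement", class(out))
  out
}

#' Distance between two domains of one chain
#'
#' `min` is the smallest heavy-atom pairwise distance (used to classify
#' open/closed enzyme states); `centroid` is the distance between C-alpha
#' centroids. Both are reported with the metric labelled so downstream
#' tables are unambiguous.
#'
#' @param atoms Atom table.
#' @param chain Chain identifier.
#' @param domain_a,domain_b Domain names in `scheme`.
#' @param scheme A [domain_scheme()].
#' @param metric `"min"` or `"centroid"`.
#' @return One-row tibble: `domain_a`, `domain_b`, `metric`, `distance`.
#' @export
interdomain_distance <- function(atoms, chain, domain_a, domain_b, scheme,
                                 metric = c("min", "centroid")) {
  metric <- match.arg(metric)
  get <- function(d) {
    w <- scheme_window(scheme, d)
    if (metric == "min") {
      sel <- select_atoms(atoms, chain = chain, seq_range = w)
      filter(sel, .data$elesy != "H")
    } else {
      select_atoms(atoms, chain = chain, seq_range = w, atom_names = "CA")
    }
  }
  a <- get(domain_a)
  b <- get(domain_b)
  d <- if (metric == "min") {
    min_pair_distance(coord_matrix(a), coord_matrix(b))
  } else {
    vec_norm(colMeans(coord_matrix(a)) - colMeans(coord_matrix(b)))
  }
  tibble(domain_a = domain_a, domain_b = domain_b, metric = metric,
         distance = d)
}

#' Separation between the two C-gamma-2 domains of an Fc homodimer
#'
#' Distance between the C-alpha centroids of the C-gamma-2 windows of the
#' two Fc gamma chains: a larger value means a more "open" Fc conformation.
#'
#' @param atoms Atom table containing both chains.
#' @param chain_a,chain_b The two Fc gamma chain identifiers.
#' @param window Inclusive residue window of the C-gamma-2 domain.
#' @return Distance in angstrom.
#' @export
cgamma2_separation <- function(atoms, chain_a, chain_b,
                               window = c(237L, 340L)) {
  ca <- function(ch) coord_matrix(
    select_atoms(atoms, chain = ch, seq_range = window, atom_names = "CA"))
  vec_norm(colMeans(ca(chain_a)) - colMeans(ca(chain_b)))
}

#' Per-residue C-alpha deviation profile after local alignment
#'
#' Superposes chain A onto chain B on the C-alpha atoms of `align_window`,
#' then reports the C-alpha distance for every residue the two chains
#' share, in sequence order. Peaks localise conformational differences
#' (e.g. a rearranged loop) that a single RMSD number would hide.
#'
#' @inheritParams domain_rearrangement
#' @param align_window Inclusive residue range used for the fit.
#' @return Tibble of class `residue_deviation`: `resno`, `deviation`
#'   (angstrom); attribute `fit_rmsd`.
#' @export
per_residue_deviation <- function(atoms_a, atoms_b, chain_a = NULL,
                                  chain_b = NULL, align_window) {
  ca_a <- select_atoms(atoms_a, chain = chain_a, atom_names = "CA")
  ca_b <- select_atoms(atoms_b, chain = chain_b, atom_names = "CA")
  win <- function(s) filter(s, .data$resno >= align_window[1L],
                            .data$resno <= align_window[2L])
  mw <- match_residues(win(ca_a), win(ca_b))
  fit <- kabsch_fit(mw$xyz_a, mw$xyz_b)
  all_m <- match_residues(ca_a, ca_b)
  moved <- apply_transform(all_m$xyz_a, fit)
  out <- tibble(resno = all_m$resno,
                deviation = sqrt(rowSums((moved - all_m$xyz_b)^2)))
  attr(out, "fit_rmsd") <- fit$rmsd
  attr(out, "align_window") <- as.integer(align_window)
  class(out) <- c("residue_deviation", class(out))
  out
}
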
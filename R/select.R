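#' Select atoms from an atom table
#'
#' Restricts an atom table to a chain, an inclusive author-residue-number
#' range and a set of atom names, resolving alternate locations by keeping
#' the highest-occupancy conformer (ties broken A-first). Residue numbers
#' requested but absent from the model are silently skipped; their count is
#' reported in the `n_missing` attribute so callers can log coverage.
#'
#' @param atoms An atom table from [read_structure()].
#' @param chain Chain identifier, or `NULL` for all chains.
#' @param seq_range Inclusive `c(start, end)` residue-number pair, or `NULL`.
#' @param atom_names Character vector of atom names (e.g. `"CA"`), or
#'   `"all"`.
#' @param altloc `"first"` keeps one conformer per atom (highest occupancy,
#'   then altloc letter); `"all"` keeps every record.
#' @param hetero `"keep"` retains HETATM records, `"exclude"` drops them.
#' @return The selected atom rows (a tibble), with attribute `n_missing`.
#'   An empty result raises a `structcomp_empty_selection` error, distinct
#'   from parse errors.
#' @examples
#' toy <- make_sphere_cluster(rbind(c(0, 0, 0), c(3, 0, 0)), c("C", "C"))
#' select_atoms(toy, chain = "A")
#' @export
select_atoms <- function(atoms, chain = NULL, seq_range = NULL,
                         atom_names = "all",
                         altloc = c("first", "all"),
                         hetero = c("keep", "exclude")) {
  altloc <- match.arg(altloc)
  hetero <- match.arg(hetero)
  out <- atoms
  if (!is.null(chain)) {
    if (!chain %in% out$chain) {
      abort(paste0("chain '", chain, "' not present"),
            class = "structcomp_empty_selection")
    }
    out <- filter(out, .data$chain == !!chain)
  }
  n_missing <- 0L
  if (!is.null(seq_range)) {
    seq_range <- as.integer(seq_range)
    stopifnot(length(seq_range) == 2L)
    present <- unique(out$resno[out$resno >= seq_range[1L] &
                                  out$resno <= seq_range[2L]])
    n_missing <- (seq_range[2L] - seq_range[1L] + 1L) - length(present)
    out <- filter(out, .data$resno >= seq_range[1L],
                  .data$resno <= seq_range[2L])
  }
  if (!identical(atom_names, "all")) {
    out <- filter(out, .data$elety %in% atom_names)
  }
  if (hetero == "exclude") out <- filter(out, !.data$is_het)
  if (altloc == "first" && any(nzchar(out$alt))) {
    out <- out |>
      arrange(.data$chain, .data$resno, .data$insert, .data$elety,
              dplyr::desc(.data$o), .data$alt) |>
      distinct(.data$chain, .data$resno, .data$insert, .data$elety,
               .keep_all = TRUE)
  }
  out <- arrange(out, .data$chain, .data$resno, .data$insert, .data$eleno)
  if (!nrow(out)) {
    abort("selection matched no atoms", class = "structcomp_empty_selection")
  }
  attr(out, "n_missing") <- n_missing
  out
}

# Water and common-ion residue codes excluded from interface/pairing sides.
.solvent_codes <- c("HOH", "WAT", "DOD", "NA", "CL", "K", "MG", "CA", "ZN",
                    "SO4", "PO4", "GOL", "EDO", "PEG", "ACT")

drop_solvent <- function(atoms) {
  filter(atoms, !(.data$is_het & .data$resid %in% .solvent_codes))
}

#' Pair enzyme copies with their binding partners
#'
#' Crystal asymmetric units often contain several copies of a complex.
#' Chains whose residue numbering covers most of the enzyme domain scheme
#' are treated as enzyme copies; each is paired with the non-enzyme,
#' non-solvent chain at the smallest minimum inter-atomic distance.
#'
#' @param atoms An atom table.
#' @param enzyme_scheme A [domain_scheme()] describing the enzyme; a chain
#'   is called an enzyme copy when at least `min_coverage` of the scheme's
#'   overall span is resolved.
#' @param max_dist Chains with no partner within this distance (angstrom)
#'   are dropped with a warning.
#' @param min_coverage Fraction of the scheme span that must be present.
#' @return A tibble with columns `enzyme_chain`, `partner_chain`,
#'   `min_distance`, ordered by enzyme chain. Zero rows (with a warning)
#'   when no pairing is possible.
#' @export
pair_complex_copies <- function(atoms, enzyme_scheme = default_scheme("endos2"),
                                max_dist = 5, min_coverage = 0.5) {
  atoms <- drop_solvent(atoms)
  span <- range(unlist(enzyme_scheme$windows))
  by_chain <- split(atoms, atoms$chain)
  cover <- vapply(by_chain, function(a) {
    length(unique(a$resno[a$resno >= span[1L] & a$resno <= span[2L] &
                            !a$is_het]))
  }, integer(1)) / (span[2L] - span[1L] + 1L)
  enz <- sort(names(cover)[cover >= min_coverage])
  others <- setdiff(names(by_chain), enz)
  if (!length(enz) || !length(others)) {
    warn("no enzyme/partner chain pairs found")
    return(tibble(enzyme_chain = character(), partner_chain = character(),
                  min_distance = numeric()))
  }
  rows <- purrr::map(enz, function(e) {
    xe <- coord_matrix(by_chain[[e]])
    d <- vapply(others, function(p) {
      min_pair_distance(xe, coord_matrix(by_chain[[p]]))
    }, numeric(1))
    best <- which.min(d)
    if (d[best] > max_dist) {
      warn(paste0("enzyme chain ", e, " has no partner within ", max_dist,
                  " A; omitted"))
      return(NULL)
    }
    tibble(enzyme_chain = e, partner_chain = others[best],
           min_distance = unname(d[best]))
  })
  bind_rows(rows)
}

#' Mean B factor per chain and domain
#'
#' Averages C-alpha B factors over each domain window of a scheme, one row
#' per (chain, domain) with at least one C-alpha in the window. Different
#' asymmetric-unit copies of the same molecule typically show different
#' mean B, reflecting their different lattice environments.
#'
#' @inheritParams pair_complex_copies
#' @param scheme A [domain_scheme()].
#' @return Tibble with columns `chain`, `domain`, `mean_b`, `n_atoms`.
#' @export
domain_bfactor_summary <- function(atoms, scheme) {
  ca <- filter(atoms, .data$elety == "CA", !.data$is_het)
  if (!nrow(ca) || all(is.na(ca$b))) {
    abort("no C-alpha B factors present")
  }
  rows <- purrr::imap(scheme$windows, function(w, d) {
    sub <- filter(ca, .data$resno >= w[1L], .data$resno <= w[2L])
    if (!nrow(sub)) return(NULL)
    sub |>
      group_by(.data$chain) |>
      summarise(mean_b = mean(.data$b), n_atoms = dplyr::n(),
                .groups = "drop") |>
      mutate(domain = d)
  })
  bind_rows(rows) |>
    select("chain", "domain", "mean_b", "n_atoms") |>
    arrange(.data$chain, .data$domain)
}
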
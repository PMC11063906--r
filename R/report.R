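#' Configuration for a full reproduction run
#'
#' Collects the coordinate files and parameters [run_report()] needs. Any
#' file may be `NULL`; analyses that need a missing input are skipped with
#' an explicit log line rather than failing the run. No file is ever
#' fetched from the network: users supply local copies of the deposited
#' entries.
#'
#' @param complex Path to the enzyme--Fc complex (e.g. entry 8Q5U).
#' @param unliganded Path to the unliganded enzyme (e.g. 6E58).
#' @param endos_complex Path to the homolog's Fc complex (e.g. 8A49).
#' @param wt_enzyme Path to the wild-type enzyme with glycan (e.g. 6MDS).
#' @param wt_fc Path to a wild-type Fc (e.g. 3AVE).
#' @param enzyme_scheme,endos_scheme,fc_scheme [domain_scheme()]s (or
#'   shipped scheme names) for the enzyme, the homolog and the Fc.
#' @param glycan_asn Author residue number of the Fc glycosylation site.
#' @param dyad Catalytic-dyad residue numbers in the wild-type enzyme.
#' @param contact_cutoff,hbond_cutoff,n_points Interface parameters.
#' @param out_dir Optional output directory for TSV/JSON artefacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(complex = NULL, unliganded = NULL,
                       endos_complex = NULL, wt_enzyme = NULL, wt_fc = NULL,
                       enzyme_scheme = "endos2", endos_scheme = "endos",
                       fc_scheme = "fc_cgamma2", glycan_asn = 297L,
                       dyad = c(184L, 186L), contact_cutoff = 4.5,
                       hbond_cutoff = 3.5, n_points = 960L, out_dir = NULL) {
  as_scheme <- function(s) if (inherits(s, "domain_scheme")) s else
    default_scheme(s)
  paths <- list(complex = complex, unliganded = unliganded,
                endos_complex = endos_complex, wt_enzyme = wt_enzyme,
                wt_fc = wt_fc)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("config file for '", nm, "' does not exist: ", p))
    }
  }
  structure(c(paths, list(
    enzyme_scheme = as_scheme(enzyme_scheme),
    endos_scheme = as_scheme(endos_scheme),
    fc_scheme = as_scheme(fc_scheme),
    glycan_asn = as.integer(glycan_asn), dyad = as.integer(dyad),
    contact_cutoff = contact_cutoff, hbond_cutoff = hbond_cutoff,
    n_points = as.integer(n_points), out_dir = out_dir)),
    class = "run_config")
}

# Published reference values the reproduction table is compared against
# (units as printed; NA where a row is a new measurement).
reference_values <- function() {
  tibble::tribble(
    ~quantity, ~published_value, ~units,
    "rearrangement_GH_LRR_rotation", 10, "deg",
    "rearrangement_GH_hIg_rmsd", 8.2, "A",
    "rearrangement_GH_CBM_rmsd", 19.4, "A",
    "rearrangement_CBM_hIg_rotation", 4.2, "deg",
    "rearrangement_CBM_LRR_rmsd", 5.1, "A",
    "rearrangement_CBM_GH_rmsd", 6.3, "A",
    "rearrangement_LRR_hIg_rotation", 11.6, "deg",
    "interface_total", 978, "A^2",
    "interface_CBM", 608, "A^2",
    "interface_GH", 369, "A^2",
    "interface_dg_solv", -8.6, "kcal/mol",
    "endos_interface_total", 1324, "A^2",
    "endos_interface_CBM", 751, "A^2",
    "endos_interface_GH", 545, "A^2",
    "endos_interface_dg_solv", -9.1, "kcal/mol",
    "glycan_core_phi", 5.9, "deg",
    "endos_glycan_core_phi", -59, "deg",
    "gh_cbm_min_distance", 25, "A")
}

#' Run the full structural-comparison report
#'
#' Orchestrates every analysis of the pipeline over the supplied coordinate
#' files: per-copy domain rearrangement of the complexed enzyme against the
#' unliganded enzyme (referenced on each of GH, CBM and LRR in turn),
#' total and domain-restricted interface areas with solvation-energy gain,
#' contacts and hydrogen bonds, glycan torsions and ring puckers at the Fc
#' glycosylation site, the GH--CBM inter-domain distance (both metrics),
#' C-gamma-2 separation, the per-residue deviation of the interfacing
#' C-gamma-2 against a wild-type Fc, and the wild-type dyad overlay onto
#' the distorted linkage. Analyses whose inputs are missing are skipped and
#' logged. Re-running an identical config gives identical output (no
#' randomness anywhere in the production analyses).
#'
#' @param config A [run_config()].
#' @return A tibble of class `reproduction_table` with columns `quantity`,
#'   `value`, `units`, `published_value`, `provenance`; attribute `log` holds
#'   the skip/progress messages. When `config$out_dir` is set, also writes
#'   `reproduction.tsv`, `interfaces.json`, `rearrangement.tsv`,
#'   `glycan.tsv` and `run.log` there.
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }
  rows <- list()
  add_row <- function(quantity, value, units, provenance) {
    rows[[length(rows) + 1L]] <<- tibble(quantity = quantity, value = value,
                                         units = units,
                                         provenance = provenance)
  }
  rearr_rows <- list()
  glycan_rows <- list()
  iface_json <- list()

  sc <- config$enzyme_scheme
  fc_sc <- config$fc_scheme
  cg2 <- scheme_window(fc_sc, "Cgamma2")

  cx <- if (!is.null(config$complex)) read_structure(config$complex) else {
    note("skip: no complex file; all complex analyses disabled")
    NULL
  }
  unl <- if (!is.null(config$unliganded)) {
    read_structure(config$unliganded)
  } else {
    note("skip: no unliganded enzyme; rearrangement rows disabled")
    NULL
  }

  pairs <- NULL
  if (!is.null(cx)) {
    pairs <- pair_complex_copies(cx, sc)
    note("complex: ", nrow(pairs), " enzyme-partner chain pairs")

    for (k in seq_len(nrow(pairs))) {
      e_ch <- pairs$enzyme_chain[k]
      p_ch <- pairs$partner_chain[k]
      prov <- paste0("complex chains ", e_ch, "/", p_ch)

      if (!is.null(unl)) {
        u_ch <- pair_chain_like(unl, sc)
        for (ref in intersect(c("GH", "CBM", "LRR"), names(sc$windows))) {
          rr <- domain_rearrangement(cx, unl, e_ch, u_ch, sc, reference = ref)
          rr2 <- mutate(rr, reference = ref, enzyme_chain = e_ch)
          rearr_rows[[length(rearr_rows) + 1L]] <- rr2
          for (i in seq_len(nrow(rr))) {
            add_row(paste0("rearrangement_", ref, "_", rr$domain[i],
                           "_rotation"),
                    rr$rotation_deg[i], "deg", prov)
            add_row(paste0("rearrangement_", ref, "_", rr$domain[i], "_rmsd"),
                    rr$displacement_rmsd[i], "A", prov)
          }
        }
      }

      enz <- drop_solvent(filter(cx, .data$chain == e_ch))
      fcp <- drop_solvent(filter(cx, .data$chain == p_ch))
      rep_tot <- interface_report(enz, fcp, radii = radii_table(),
                                  n_points = config$n_points,
                                  contact_cutoff = config$contact_cutoff,
                                  hbond_cutoff = config$hbond_cutoff)
      add_row("interface_total", rep_tot$buried_area, "A^2", prov)
      add_row("interface_dg_solv", rep_tot$delta_g_solv, "kcal/mol", prov)
      for (d in intersect(c("CBM", "GH"), names(sc$windows))) {
        a <- domain_restricted_interface(enz, fcp, scheme_window(sc, d),
                                         n_points = config$n_points)
        add_row(paste0("interface_", d), a, "A^2", prov)
      }
      iface_json[[prov]] <- list(
        buried_area = rep_tot$buried_area,
        delta_g_solv = rep_tot$delta_g_solv,
        contacts = rep_tot$contacts, hbonds = rep_tot$hbonds)

      gl <- tryCatch(detect_glycan(cx, p_ch, config$glycan_asn),
                     structcomp_no_glycan = function(e) NULL)
      if (is.null(gl)) {
        note("skip: no glycan at Asn ", config$glycan_asn, " on chain ", p_ch)
      } else {
        lk <- gl$linkages
        pk <- ring_puckers(cx, gl)
        glycan_rows[[length(glycan_rows) + 1L]] <-
          mutate(lk, enzyme_chain = e_ch, fc_chain = p_ch)
        core <- filter(lk, .data$acceptor_atom == "O4")
        if (nrow(core)) {
          add_row("glycan_core_phi", core$phi[1L], "deg", prov)
          add_row("glycan_core_psi", core$psi[1L], "deg", prov)
          second <- filter(pk, .data$resno == core$donor_resno[1L])
          if (nrow(second)) {
            add_row("glycan_second_glcnac_theta", second$theta[1L], "deg",
                    paste0(prov, " conformer ", second$conformer[1L]))
          }
        }
      }

      dd <- interdomain_distance(cx, e_ch, "GH", "CBM", sc, metric = "min")
      add_row("gh_cbm_min_distance", dd$distance, "A", prov)
      dc <- interdomain_distance(cx, e_ch, "GH", "CBM", sc,
                                 metric = "centroid")
      add_row("gh_cbm_centroid_distance", dc$distance, "A", prov)
    }
  }

  if (!is.null(cx)) {
    sep <- tryCatch(fc_dimer_separation(cx, pairs, cg2),
                    error = function(e) NULL)
    if (!is.null(sep)) {
      add_row("cgamma2_separation", sep$distance, "A", sep$provenance)
    } else note("skip: could not identify an Fc dimer in the complex")
  }

  if (!is.null(config$endos_complex)) {
    es <- read_structure(config$endos_complex)
    esc <- config$endos_scheme
    ep <- pair_complex_copies(es, esc)
    if (nrow(ep)) {
      e_ch <- ep$enzyme_chain[1L]
      p_ch <- ep$partner_chain[1L]
      prov <- paste0("homolog complex chains ", e_ch, "/", p_ch)
      enz <- drop_solvent(filter(es, .data$chain == e_ch))
      fcp <- drop_solvent(filter(es, .data$chain == p_ch))
      add_row("endos_interface_total",
              interface_area(enz, fcp, n_points = config$n_points), "A^2",
              prov)
      add_row("endos_interface_dg_solv",
              solvation_energy_gain(enz, fcp, n_points = config$n_points),
              "kcal/mol", prov)
      for (d in intersect(c("CBM", "GH"), names(esc$windows))) {
        add_row(paste0("endos_interface_", d),
                domain_restricted_interface(enz, fcp,
                                            scheme_window(esc, d),
                                            n_points = config$n_points),
                "A^2", prov)
      }
      gl <- tryCatch(detect_glycan(es, p_ch, config$glycan_asn),
                     structcomp_no_glycan = function(e) NULL)
      if (!is.null(gl)) {
        core <- filter(gl$linkages, .data$acceptor_atom == "O4")
        if (nrow(core)) {
          add_row("endos_glycan_core_phi", core$phi[1L], "deg", prov)
        }
      }
      sep <- tryCatch(fc_dimer_separation(es, ep, cg2),
                      error = function(e) NULL)
      if (!is.null(sep)) {
        add_row("endos_cgamma2_separation", sep$distance, "A",
                sep$provenance)
      }
    }
  } else note("skip: no homolog complex; comparison rows disabled")

  if (!is.null(config$wt_fc) && !is.null(cx) && !is.null(pairs) &&
      nrow(pairs)) {
    wtfc <- read_structure(config$wt_fc)
    wch <- chain_with_window(wtfc, cg2)
    aw <- scheme_window(fc_sc, "Cgamma2", align = TRUE)
    dev <- per_residue_deviation(cx, wtfc, pairs$partner_chain[1L], wch,
                                 align_window = aw)
    in_cg2 <- filter(dev, .data$resno >= cg2[1L], .data$resno <= cg2[2L])
    peak <- in_cg2$resno[which.max(in_cg2$deviation)]
    add_row("ce_loop_peak_resno", peak, "residue",
            paste0("complex chain ", pairs$partner_chain[1L],
                   " vs wild-type Fc chain ", wch, ", aligned ",
                   aw[1L], "-", aw[2L]))
  } else note("skip: C'E-loop deviation needs both complex and wt_fc")

  if (!is.null(config$wt_enzyme) && !is.null(cx) && !is.null(pairs) &&
      nrow(pairs)) {
    wte <- read_structure(config$wt_enzyme)
    wch <- chain_with_window(wte, scheme_window(sc, "GH"))
    gl <- tryCatch(detect_glycan(cx, pairs$partner_chain[1L],
                                 config$glycan_asn),
                   structcomp_no_glycan = function(e) NULL)
    core <- if (!is.null(gl)) filter(gl$linkages,
                                     .data$acceptor_atom == "O4") else NULL
    if (!is.null(core) && nrow(core)) {
      asg <- active_site_geometry(
        cx, wte, pairs$enzyme_chain[1L], wch, sc, dyad = config$dyad,
        glycan_chain = pairs$partner_chain[1L],
        donor = core$donor_resno[1L], acceptor = core$acceptor_resno[1L],
        acceptor_atom = "O4")
      nuc <- filter(asg, .data$dyad_resno == max(config$dyad),
                    .data$target == "O_glycosidic")
      add_row("dyad_to_glycosidic_o_min", min(nuc$distance), "A",
              paste0("wt enzyme chain ", wch, " overlaid on complex chain ",
                     pairs$enzyme_chain[1L]))
    } else note("skip: active-site overlay needs a detected core linkage")
  } else note("skip: active-site overlay needs complex and wt_enzyme")

  out <- bind_rows(rows)
  if (nrow(out)) {
    out <- left_join(out, reference_values(), by = c("quantity", "units"))
    out <- select(out, "quantity", "value", "units", "published_value",
                  "provenance")
  } else {
    out <- tibble(quantity = character(), value = numeric(),
                  units = character(), published_value = numeric(),
                  provenance = character())
  }
  attr(out, "log") <- log_lines
  class(out) <- c("reproduction_table", class(out))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    utils::write.table(out, p("reproduction.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(iface_json, p("interfaces.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (length(rearr_rows)) {
      utils::write.table(bind_rows(rearr_rows), p("rearrangement.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (length(glycan_rows)) {
      utils::write.table(bind_rows(glycan_rows), p("glycan.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    writeLines(log_lines, p("run.log"))
  }
  out
}

# The chain of a single-molecule structure best covering a scheme/window.
pair_chain_like <- function(atoms, scheme) {
  span <- range(unlist(scheme$windows))
  chain_with_window(atoms, span)
}

chain_with_window <- function(atoms, window) {
  atoms <- drop_solvent(atoms)
  by_chain <- split(atoms, atoms$chain)
  cover <- vapply(by_chain, function(a) {
    length(unique(a$resno[a$resno >= window[1L] & a$resno <= window[2L] &
                            !a$is_het]))
  }, integer(1))
  if (!any(cover > 0L)) abort("no chain covers the requested window")
  names(cover)[which.max(cover)]
}

# Identify the two Fc gamma chains of one homodimer (the two non-enzyme
# chains closest to each other) and their C-gamma-2 centroid separation.
fc_dimer_separation <- function(atoms, pairs, cg2_window) {
  atoms <- drop_solvent(atoms)
  enzyme_chains <- if (!is.null(pairs)) pairs$enzyme_chain else character()
  cand <- setdiff(unique(atoms$chain), enzyme_chains)
  cand <- cand[vapply(cand, function(ch) {
    sum(atoms$chain == ch & atoms$elety == "CA" &
          atoms$resno >= cg2_window[1L] & atoms$resno <= cg2_window[2L]) >= 20
  }, logical(1))]
  if (length(cand) < 2L) abort("fewer than two Fc gamma chains")
  combos <- utils::combn(cand, 2L)
  seps <- apply(combos, 2L, function(p) {
    cgamma2_separation(atoms, p[1L], p[2L], cg2_window)
  })
  k <- which.min(seps)
  list(distance = seps[k],
       provenance = paste0("Fc chains ", combos[1L, k], "/", combos[2L, k]))
}

#' @export
print.reproduction_table <- function(x, ...) {
  cat("<reproduction_table> ", nrow(x), " quantities\n", sep = "")
  NextMethod()
}
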
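#' Read a macromolecular coordinate file into a tidy atom table
#'
#' Parses a PDB (fixed-column) or mmCIF (PDBx) file via \pkg{bio3d} and
#' returns one row per atom record. ATOM and HETATM records are both
#' retained, alternate locations are preserved (resolve them later with
#' [select_atoms()]), and residue numbers are the author numbering
#' (`auth_seq_id`), which is what published domain windows refer to.
#'
#' @param path Path to a coordinate file.
#' @param format `"auto"` (sniff from extension, then content), `"pdb"` or
#'   `"cif"`.
#' @return A tibble with columns `type` (ATOM/HETATM), `eleno`, `elety`
#'   (atom name), `alt` (altloc, `""` when absent), `resid` (3-letter or
#'   saccharide code), `chain`, `resno`, `insert`, `x`, `y`, `z` (angstrom),
#'   `o` (occupancy), `b` (B factor, angstrom^2), `elesy` (element symbol)
#'   and `is_het`. The attributes `identifier` (file stem) and
#'   `source_format` record provenance.
#' @examples
#' pdb <- write_fixture(make_sphere_cluster(rbind(c(0, 0, 0)), "O"),
#'                      tempfile(fileext = ".pdb"))
#' read_structure(pdb)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") format <- sniff_format(path)
  parsed <- tryCatch(
    switch(format,
      pdb = bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                            verbose = FALSE),
      cif = suppressWarnings(bio3d::read.cif(path, verbose = FALSE))),
    error = function(e) {
      abort(paste0("could not parse '", path, "' as ", toupper(format),
                   ": ", conditionMessage(e)),
            class = "structcomp_parse_error")
    })
  atoms <- as_tibble(parsed$atom)
  if (!nrow(atoms)) {
    abort(paste0("no atom records in ", path), class = "structcomp_parse_error")
  }
  atoms <- mutate(atoms,
    alt = ifelse(is.na(.data$alt), "", .data$alt),
    insert = ifelse(is.na(.data$insert), "", .data$insert),
    chain = ifelse(is.na(.data$chain), "", .data$chain),
    o = ifelse(is.na(.data$o), 1, .data$o),
    elesy = ifelse(is.na(.data$elesy) | !nzchar(.data$elesy),
                   guess_element(.data$elety), .data$elesy),
    is_het = .data$type == "HETATM")
  atoms <- select(atoms, "type", "eleno", "elety", "alt", "resid", "chain",
                  "resno", "insert", "x", "y", "z", "o", "b", "elesy",
                  "is_het")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite coordinates in file", class = "structcomp_parse_error")
  }
  attr(atoms, "identifier") <- sub("\\.[^.]*$", "", basename(path))
  attr(atoms, "source_format") <- format
  atoms
}

sniff_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("cif", "mmcif")) return("cif")
  first <- readLines(path, n = 20L, warn = FALSE)
  if (any(grepl("^data_|^loop_", first))) return("cif")
  if (any(grepl("^(ATOM|HETATM|HEADER|CRYST1)", first))) return("pdb")
  abort(paste0("cannot determine coordinate format of ", path),
        class = "structcomp_format_error")
}

# Element symbol from an atom name: strip digits/primes, take the leading
# letter(s); two-letter symbols only when unambiguous from PDB conventions.
guess_element <- function(elety) {
  nm <- toupper(gsub("[0-9']", "", elety))
  two <- c("FE", "ZN", "MG", "MN", "CA", "NA", "CL", "BR", "CU", "NI", "SE")
  # bare "CA"/"NA" as a full atom name in a HETATM ion is ambiguous with
  # C-alpha / N-alpha; protein atom names resolve to their first letter.
  out <- substr(nm, 1L, 1L)
  ion <- nm %in% two & nchar(elety) == nchar(nm) & nm != "CA" & nm != "NA"
  out[ion] <- nm[ion]
  out
}

#' Write an atom table to a coordinate file
#'
#' PDB output goes through [bio3d::write.pdb()]; mmCIF output writes a
#' minimal `atom_site` loop (no R package in common use writes PDBx, so the
#' loop is emitted directly). Output is byte-stable for identical input.
#'
#' @param atoms An atom table (see [read_structure()]).
#' @param path Output path.
#' @param format `"auto"` (from extension), `"pdb"` or `"cif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!is.data.frame(atoms) || !nrow(atoms)) {
    abort("cannot write an empty structure", class = "structcomp_empty_error")
  }
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  atoms <- mutate(atoms,
                  alt = ifelse(nzchar(.data$alt), .data$alt, NA_character_),
                  insert = ifelse(nzchar(.data$insert), .data$insert,
                                  NA_character_))
  if (format == "pdb") {
    bio3d::write.pdb(pdb = NULL, file = path,
                     xyz = as.numeric(t(coord_matrix(atoms))),
                     type = atoms$type, resno = atoms$resno,
                     resid = atoms$resid, eleno = atoms$eleno,
                     elety = atoms$elety, chain = atoms$chain,
                     insert = atoms$insert, alt = atoms$alt,
                     o = atoms$o, b = atoms$b, elesy = atoms$elesy)
  } else {
    write_mmcif(atoms, path)
  }
  invisible(path)
}

write_mmcif <- function(atoms, path) {
  num <- function(v) formatC(v, format = "f", digits = 3)
  q <- function(v) ifelse(is.na(v) | !nzchar(v), ".", v)
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_-]", "_",
                         sub("\\.[^.]*$", "", basename(path)))),
    "#", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
      "label_atom_id", "label_alt_id", "label_comp_id", "label_asym_id",
      "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
      "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv",
      "pdbx_formal_charge", "auth_seq_id", "auth_comp_id", "auth_asym_id",
      "auth_atom_id", "pdbx_PDB_model_num")),
    paste(atoms$type, atoms$eleno, q(atoms$elesy), q(atoms$elety),
          q(atoms$alt), q(atoms$resid), q(atoms$chain), 1L, atoms$resno,
          q(atoms$insert), num(atoms$x), num(atoms$y), num(atoms$z),
          formatC(atoms$o, format = "f", digits = 2),
          formatC(atoms$b, format = "f", digits = 2), "?",
          atoms$resno, q(atoms$resid), q(atoms$chain), q(atoms$elety), 1L),
    "#")
  writeLines(lines, path)
}
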
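# Locations searched for user-supplied copies of the deposited coordinate
# files (8Q5U, 6E58, 8A49, 6MDS, 3AVE). The package never downloads them;
# place mmCIF or PDB files named <accession>.cif / <accession>.pdb in one
# of these directories to enable the reproduction checks.
deposited_entry_path <- function(accession) {
  dirs <- c(Sys.getenv("STRUCTCOMP_DATA_DIR", unset = ""),
            getOption("structcomp.data_dir", default = ""),
            "pdb", file.path("..", "..", "pdb"),
            file.path(path.expand("~"), "structcomp_pdb"))
  for (d in dirs[nzchar(dirs)]) {
    for (ext in c(".cif", ".pdb", ".ent")) {
      p <- file.path(d, paste0(accession, ext))
      if (file.exists(p)) return(p)
      p <- file.path(d, paste0(tolower(accession), ext))
      if (file.exists(p)) return(p)
    }
  }
  # returned unconditionally: read_structure() reports the missing file
  file.path("pdb", paste0(accession, ".cif"))
}
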
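#' Domain schemes
#'
#' A domain scheme names residue-number windows (author numbering, inclusive)
#' that define the structural domains of a protein. Superpositions sometimes
#' use a slightly trimmed "alignment" window; these can be attached per
#' domain and are used by [domain_rearrangement()] for the reference fit.
#'
#' Three schemes ship with the package:
#' \describe{
#'   \item{`endos2`}{The four-domain EndoS2 endoglycosidase: glycosyl
#'     hydrolase `GH` 43--386 (alignment window 46--386), leucine-rich
#'     repeat `LRR` 387--547, hybrid immunoglobulin `hIg` 548--680,
#'     carbohydrate-binding module `CBM` 681--843.}
#'   \item{`endos`}{The homologous EndoS enzyme; approximate windows from
#'     its deposited complex: `GH` 113--445, `LRR` 446--631, `hIg`
#'     632--764, `CBM` 765--923.}
#'   \item{`fc_cgamma2`}{IgG1 Fc constant domains: `Cgamma2` 237--340
#'     (alignment window 238--340) and `Cgamma3` 341--443.}
#' }
#'
#' @param name Scheme name (a label carried in reports).
#' @param windows Named list of integer pairs `c(start, end)`, inclusive.
#' @param align_windows Optional named list overriding the window used for
#'   superposition for specific domains.
#' @return An object of class `domain_scheme`.
#' @examples
#' sc <- domain_scheme("toy", list(A = c(1, 50), B = c(51, 100)))
#' scheme_window(sc, "A")
#' default_scheme("endos2")
#' @export
domain_scheme <- function(name, windows, align_windows = NULL) {
  if (!length(windows)) abort("a domain scheme needs at least one window")
  if (is.null(names(windows)) || any(!nzchar(names(windows)))) {
    abort("all windows must be named")
  }
  windows <- lapply(windows, function(w) {
    w <- as.integer(w)
    if (length(w) != 2L || anyNA(w) || w[1L] > w[2L]) {
      abort("each window must be c(start, end) with start <= end")
    }
    w
  })
  if (!is.null(align_windows)) {
    bad <- setdiff(names(align_windows), names(windows))
    if (length(bad)) abort(paste0("alignment window for unknown domain: ", bad[1L]))
    align_windows <- lapply(align_windows, as.integer)
  }
  structure(list(name = name, windows = windows,
                 align_windows = align_windows %||% list()),
            class = "domain_scheme")
}

#' @rdname domain_scheme
#' @param scheme A `domain_scheme`.
#' @param domain Domain name.
#' @param align If `TRUE`, return the alignment window when one is defined.
#' @export
scheme_window <- function(scheme, domain, align = FALSE) {
  stopifnot(inherits(scheme, "domain_scheme"))
  if (!domain %in% names(scheme$windows)) {
    abort(paste0("domain '", domain, "' not in scheme '", scheme$name, "'"))
  }
  if (align && domain %in% names(scheme$align_windows)) {
    return(scheme$align_windows[[domain]])
  }
  scheme$windows[[domain]]
}

#' @rdname domain_scheme
#' @export
default_scheme <- function(name = c("endos2", "endos", "fc_cgamma2")) {
  name <- match.arg(name)
  switch(name,
    endos2 = domain_scheme("endos2",
      windows = list(GH = c(43L, 386L), LRR = c(387L, 547L),
                     hIg = c(548L, 680L), CBM = c(681L, 843L)),
      align_windows = list(GH = c(46L, 386L))),
    endos = domain_scheme("endos",
      windows = list(GH = c(113L, 445L), LRR = c(446L, 631L),
                     hIg = c(632L, 764L), CBM = c(765L, 923L))),
    fc_cgamma2 = domain_scheme("fc_cgamma2",
      windows = list(Cgamma2 = c(237L, 340L), Cgamma3 = c(341L, 443L)),
      align_windows = list(Cgamma2 = c(238L, 340L))))
}

#' Read a domain scheme from a YAML config
#'
#' Each key maps a domain name to `[start, end]`; an optional `align:`
#' mapping supplies trimmed superposition windows.
#'
#' @param path Path to a YAML file.
#' @param name Scheme label; defaults to the file stem.
#' @return A `domain_scheme`.
#' @export
read_scheme <- function(path, name = NULL) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading scheme files requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  align <- raw[["align"]]
  raw[["align"]] <- NULL
  domain_scheme(name %||% sub("\\.[^.]*$", "", basename(path)),
                windows = raw, align_windows = align)
}

#' @export
print.domain_scheme <- function(x, ...) {
  cat("<domain_scheme> ", x$name, "\n", sep = "")
  for (d in names(x$windows)) {
    w <- x$windows[[d]]
    a <- if (d %in% names(x$align_windows)) {
      aw <- x$align_windows[[d]]
      paste0("  (align ", aw[1], "-", aw[2], ")")
    } else ""
    cat(sprintf("  %-8s %d-%d%s\n", d, w[1], w[2], a))
  }
  invisible(x)
}
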
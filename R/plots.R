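#' Plot a domain-rearrangement report
#'
#' Side-by-side bars of per-domain rotation angle and displacement RMSD,
#' relative to the reference domain named in the subtitle.
#'
#' @param object A `domain_rearrangement` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot domain_rearrangement
#' @export
autoplot.domain_rearrangement <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("rotation_deg", "displacement_rmsd"),
    names_to = "measure", values_to = "value")
  long$measure <- factor(long$measure,
                         levels = c("rotation_deg", "displacement_rmsd"),
                         labels = c("rotation (deg)",
                                    "displacement RMSD (Å)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$domain, y = .data$value)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "Inter-domain rearrangement",
      subtitle = paste0("reference domain: ", attr(object, "reference"),
                        " (fit RMSD ",
                        sprintf("%.2f", attr(object, "reference_fit_rmsd")),
                        " Å)")) +
    ggplot2::theme_minimal()
}

#' Plot a per-residue deviation profile
#'
#' @param object A `residue_deviation` tibble from
#'   [per_residue_deviation()].
#' @param highlight Optional `c(start, end)` residue window to shade (e.g.
#'   a loop of interest).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot residue_deviation
#' @export
autoplot.residue_deviation <- function(object, highlight = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$resno, y = .data$deviation))
  if (!is.null(highlight)) {
    p <- p + ggplot2::annotate("rect", xmin = highlight[1L],
                               xmax = highlight[2L], ymin = -Inf,
                               ymax = Inf, alpha = 0.15, fill = "orange")
  }
  p + ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "residue number",
                  y = "Cα deviation (Å)",
                  title = "Per-residue deviation after local alignment") +
    ggplot2::theme_minimal()
}

#' Contact map of an interface report
#'
#' Tile map of residue-residue minimum distances, hydrogen-bonded pairs
#' outlined.
#'
#' @param object An `interface_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interface_report
#' @export
autoplot.interface_report <- function(object, ...) {
  ct <- object$contacts
  if (!nrow(ct)) abort("no contacts to plot")
  ct <- mutate(ct,
               res_a = paste0(.data$resid_a, .data$resno_a),
               res_b = paste0(.data$resid_b, .data$resno_b))
  hb <- object$hbonds
  hb_key <- if (nrow(hb)) paste(hb$donor_resno, hb$acceptor_resno) else
    character()
  ct$hbond <- paste(ct$resno_a, ct$resno_b) %in% hb_key |
    paste(ct$resno_b, ct$resno_a) %in% hb_key
  ggplot2::ggplot(ct, ggplot2::aes(
    x = stats::reorder(.data$res_a, .data$resno_a),
    y = stats::reorder(.data$res_b, .data$resno_b),
    fill = .data$min_distance)) +
    ggplot2::geom_tile(ggplot2::aes(colour = .data$hbond),
                       linewidth = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = NA),
                                 guide = "none") +
    ggplot2::scale_fill_viridis_c(name = "min distance (Å)",
                                  direction = -1) +
    ggplot2::labs(x = "side A residue", y = "side B residue",
                  title = "Interface contacts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
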
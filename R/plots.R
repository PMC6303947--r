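#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_boxplot
#'   geom_point labs theme_minimal scale_y_log10
#' @export
ggplot2::autoplot

#' Plot a conservation profile
#'
#' Modal-residue frequency along the alignment, with the gap fraction shown
#' underneath.
#'
#' @param object A [conservation()] profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conservation_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$column)) +
    geom_line(aes(y = .data$modal_freq), colour = "#2c7fb8") +
    geom_line(aes(y = -.data$gap_fraction), colour = "grey60") +
    labs(x = "alignment column",
         y = "modal residue frequency (up) / gap fraction (down)",
         title = "Column conservation") +
    theme_minimal()
}

#' Plot subfamily sizes
#'
#' @param object A `subfam_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subfam_partition <- function(object, ...) {
  sizes <- count(as_tibble(object), .data$subfamily, name = "n")
  ggplot(sizes, aes(x = stats::reorder(.data$subfamily, -.data$n),
                    y = .data$n)) +
    geom_col(fill = "#2c7fb8") +
    labs(x = NULL, y = "members", title = "Subfamily sizes") +
    theme_minimal()
}

#' Plot per-subfamily catalytic efficiencies
#'
#' Box plot of kcat/KM by subfamily on a log scale, best substrates
#' highlighted.
#'
#' @param object A [family_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.family_summary <- function(object, ...) {
  rec <- filter(object$records, !is.na(.data$kcat_over_km_per_M_per_s))
  ggplot(rec, aes(x = .data$subfamily, y = .data$kcat_over_km_per_M_per_s)) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_point(aes(colour = .data$best),
               position = ggplot2::position_jitter(width = 0.15, height = 0)) +
    scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d7301f",
                                            `FALSE` = "grey50"),
                                 name = "best substrate") +
    labs(x = NULL, y = "kcat/KM [1/(M s)]",
         title = "Catalytic efficiency by subfamily") +
    theme_minimal()
}

#' Plot a contact map
#'
#' Minimum heavy-atom distance per contacting residue.
#'
#' @param object A [substrate_contacts()] map.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_map <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = factor(.data$resno), y = .data$min_dist,
             colour = .data$other_subunit)) +
    geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = attr(object, "radius"),
                        linetype = "dashed") +
    labs(x = "residue", y = "min heavy-atom distance [A]",
         title = sprintf("Contacts of %s within %.1f A",
                         attr(object, "ligand")$resname %||% "ligand",
                         attr(object, "radius"))) +
    theme_minimal()
}
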
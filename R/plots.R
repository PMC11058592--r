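#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_hline labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' Plot an RMSD histogram
#'
#' @param object A `loopshift_histogram`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.loopshift_histogram <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                y = .data$prob)) +
    geom_col(width = attr(object, "bin_width"), fill = "steelblue",
             colour = NA) +
    labs(x = "RMSD to reference (Å)", y = "probability") +
    theme_minimal()
}

#' Plot a free-energy profile along the energy gap
#'
#' @param object A `free_energy_profile`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.free_energy_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(.data$bin_center, .data$dg)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = expression(paste("energy gap ", E[1] - E[2], " (kcal/mol)")),
         y = expression(paste(Delta, "g (kcal/mol)"))) +
    theme_minimal()
}

#' Per-residue delta-RMSF significance plot
#'
#' Mean delta-RMSF per residue with significant residues marked, mirroring
#' the usual presentation of per-residue flexibility comparisons.
#'
#' @param report A `delta_rmsf_report`.
#' @return A ggplot.
#' @export
plot_delta_rmsf <- function(report) {
  tab <- as_tibble(report)
  ggplot(tab, aes(.data$residue_index, .data$mean_delta)) +
    geom_hline(yintercept = 0, colour = "grey60") +
    geom_line(colour = "grey40") +
    geom_point(data = tab[tab$significant, ], colour = "black", size = 1.2) +
    labs(x = "residue", y = expression(paste(Delta, "RMSF (Å), A - B"))) +
    theme_minimal()
}

#' Plot the top interaction-network differences
#'
#' @param object A `network_diff`.
#' @param n Number of top-ranked interactions to show (default 15).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.network_diff <- function(object, n = 15, ...) {
  tab <- as_tibble(object) |> slice_min(.data$rank, n = n)
  tab$label <- sprintf("%s %d:%s-%d:%s", tab$kind, tab$res_i, tab$atom_i,
                       tab$res_j, tab$atom_j)
  ggplot(tab, aes(x = stats::reorder(.data$label, abs(.data$delta)),
                  y = .data$delta)) +
    geom_col(aes(fill = .data$delta > 0)) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "magenta3",
                                          `FALSE` = "goldenrod2"),
                               guide = "none") +
    labs(x = NULL, y = "occupancy difference (A - B)") +
    theme_minimal()
}

#' Plot pooled state populations with between-replica error bars
#'
#' @param object A `state_populations`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.state_populations <- function(object, ...) {
  tab <- as_tibble(object)
  ggplot(tab, aes(.data$state, .data$pooled_fraction)) +
    geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(aes(ymin = .data$pooled_fraction - .data$se,
                               ymax = .data$pooled_fraction + .data$se),
                           width = 0.2) +
    labs(x = NULL, y = "population fraction") +
    theme_minimal()
}
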
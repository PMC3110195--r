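#' Plot methods for result objects
#'
#' `autoplot()` methods give a quick ggplot2 view of each result type:
#' the screening score against the self-rotation angle, the (RMSD, Rg)
#' free-energy landscape, the contact / hydrogen-bond residue map
#' (contacts upper-left triangle, hydrogen bonds lower-right), the
#' per-residue RMSF profile with mobility bands, the dimer-count time
#' series, and the PC-space dimer clusters.
#'
#' @param object a result object.
#' @param ... unused.
#' @return A ggplot.
#' @name globulomer-plots
NULL

#' @rdname globulomer-plots
#' @export
autoplot.ab_screen <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$angle, y = .data$total)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "self-rotation angle (deg)",
                  y = "screening score (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' @rdname globulomer-plots
#' @export
autoplot.ab_landscape <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rmsd_mid, y = .data$rg_mid,
                                       fill = .data$free_energy)) +
    ggplot2::geom_tile(width = object$rmsd_hi - object$rmsd_lo,
                       height = object$rg_hi - object$rg_lo) +
    ggplot2::scale_fill_viridis_c(name = "free energy\n(kcal/mol)",
                                  direction = -1) +
    ggplot2::labs(x = "backbone RMSD (Å)", y = "Rg (Å)") +
    ggplot2::theme_minimal()
}

#' @rdname globulomer-plots
#' @export
autoplot.ab_contact_map <- function(object, ...) {
  df <- tidy(object)
  df$value <- ifelse(df$res_i < df$res_j, df$contact_freq,
                     ifelse(df$res_i > df$res_j, df$hbond_freq, NA_real_))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$res_j, y = .data$res_i,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "frequency", na.value = "white") +
    ggplot2::labs(x = "residue", y = "residue",
                  subtitle = "contacts upper-left, hydrogen bonds lower-right") +
    ggplot2::theme_minimal()
}

#' @rdname globulomer-plots
#' @export
autoplot.ab_rmsf <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$resno, y = .data$rmsf,
                               colour = .data$chain)) +
    ggplot2::geom_hline(yintercept = c(3, 6), linetype = 2, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}

#' @rdname globulomer-plots
#' @export
autoplot.ab_dimer_calls <- function(object, ...) {
  ggplot2::ggplot(object$counts, ggplot2::aes(x = .data$frame,
                                              y = .data$n_dimers)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "frame", y = "dimers") +
    ggplot2::theme_minimal()
}

#' @rdname globulomer-plots
#' @export
autoplot.ab_dimer_clusters <- function(object, ...) {
  df <- object$assignments
  df$medoid <- df$config %in% object$medoids
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = df[df$medoid, ], shape = 8, size = 3,
                        colour = "black") +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "cluster") +
    ggplot2::theme_minimal()
}

#' @rdname globulomer-plots
#' @param x result object (base-plot style alias).
#' @export
plot_landscape <- function(x, ...) autoplot.ab_landscape(x, ...)

#' @rdname globulomer-plots
#' @export
plot_contact_map <- function(x, ...) autoplot.ab_contact_map(x, ...)
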
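#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-bit probability profile
#'
#' Needle plot of the per-bit set probability, the fingerprint-level view of
#' a library's feature usage.
#'
#' @param object An `fp_profile` from [bit_probabilities()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fp_profile
#' @export
autoplot.fp_profile <- function(object, ...) {
  lbl <- attr(object, "source_label", exact = TRUE)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bit, y = .data$p)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$bit, yend = 0),
                          linewidth = 0.3, colour = "steelblue4") +
    ggplot2::labs(x = "bit position", y = "set probability",
                  title = if (nzchar(lbl)) lbl else NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot per-bit Shannon entropy
#'
#' @param object An `entropy_report` from [shannon_entropy()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot entropy_report
#' @export
autoplot.entropy_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bit, y = .data$h)) +
    ggplot2::geom_col(width = 1, fill = "grey35") +
    ggplot2::labs(x = "bit position", y = "entropy (bits)",
                  subtitle = sprintf("total SE = %.2f bits (%s mode)",
                                     attr(object, "total", exact = TRUE),
                                     attr(object, "mode", exact = TRUE))) +
    ggplot2::theme_minimal()
}

#' Plot per-bit differential Shannon entropy
#'
#' @param object A `dse_report` from [differential_shannon_entropy()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dse_report
#' @export
autoplot.dse_report <- function(object, ...) {
  labs <- attr(object, "labels", exact = TRUE)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bit, y = .data$dse)) +
    ggplot2::geom_col(width = 1, fill = "firebrick4") +
    ggplot2::labs(x = "bit position", y = "DSE (bits)",
                  subtitle = paste(labs, collapse = " vs ")) +
    ggplot2::theme_minimal()
}

#' Heatmap of an inter-set distance matrix
#'
#' @param object A `dfp_dist` from [inter_set_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dfp_dist
#' @export
autoplot.dfp_dist <- function(object, ...) {
  long <- tidy.dfp_dist(object)
  diag_rows <- tibble::tibble(from = rownames(object),
                              to = rownames(object), distance = 0)
  long <- dplyr::bind_rows(long,
                           dplyr::rename(long, from = "to", to = "from"),
                           diag_rows)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$from, y = .data$to,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = attr(object, "metric", exact = TRUE)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Entropy-versus-similarity map of libraries
#'
#' The diversity plane: mean per-bit Shannon entropy against mean
#' molecule-to-DFP Tanimoto similarity, one point per library, coloured by
#' cluster when plotting a clustering result.
#'
#' @param object A `library_summary` from [summarize_libraries()] or a
#'   `library_clusters` from [kmeans_libraries()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot library_summary
#' @export
autoplot.library_summary <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$se_mean,
                                    y = .data$dfp_similarity_mean)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "mean per-bit Shannon entropy (bits)",
                  y = "mean molecule-vs-DFP Tanimoto") +
    ggplot2::theme_minimal()
  p
}

#' @rdname autoplot.library_summary
#' @method autoplot library_clusters
#' @export
autoplot.library_clusters <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$se_mean,
                               y = .data$dfp_similarity_mean,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "mean per-bit Shannon entropy (bits)",
                  y = "mean molecule-vs-DFP Tanimoto",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}
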
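#' Plot helpers for quadcoloc results
#'
#' `plot_reldist()` draws the relative-distance histogram against the
#' uniform-independence expectation; `plot_profile()` draws a metaplot of
#' signal density around anchor midpoints; `autoplot()` methods cover Kd
#' fits and permutation tests.
#'
#' @param reldist Output of [relative_distances()].
#' @param n_bins Histogram bins on `[0, 0.5]`.
#' @param object A fitted object (`kd_fit` or `qc_permtest`).
#' @param profile Output of [profile_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @name plot_quadcoloc
NULL

#' @rdname plot_quadcoloc
#' @export
plot_reldist <- function(reldist, n_bins = 25) {
  h <- reldist_histogram(reldist, n_bins)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$frequency)) +
    ggplot2::geom_col(fill = "grey65", colour = "grey35", width = 0.5 / n_bins) +
    ggplot2::geom_hline(yintercept = 1 / n_bins, linetype = 2, colour = "red") +
    ggplot2::labs(x = "relative distance", y = "frequency",
                  title = "Relative-distance distribution",
                  subtitle = "dashed line: uniform expectation under independence") +
    ggplot2::theme_minimal()
}

#' @rdname plot_quadcoloc
#' @export
plot_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$offset_bp, y = .data$mean_signal)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "distance from anchor midpoint (bp)",
                  y = "fraction of windows with signal",
                  title = "Metaplot profile") +
    ggplot2::theme_minimal()
}
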
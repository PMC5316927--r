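# ggplot2 autoplot methods for the main result types.

#' Plot a k-mer multiplicity histogram
#' @param object a `kmer_histogram`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot kmer_histogram
#' @export
autoplot.kmer_histogram <- function(object, ...) {
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(x = .data$multiplicity, y = .data$n_kmers)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::labs(x = "k-mer multiplicity (depth)", y = "distinct k-mers",
                  title = sprintf("%d-mer frequency histogram", object$k)) +
    ggplot2::theme_minimal()
}

#' Plot a Ks proportion histogram with optional modal peaks
#' @param object a [ks_histogram()].
#' @param peaks optional peak tibble from [find_modal_peaks()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ks_histogram
#' @export
autoplot.ks_histogram <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$bin_mid, y = .data$proportion)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "Ks (synonymous substitutions per synonymous site)",
                  y = "proportion of block medians") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_vline(data = peaks,
                                 ggplot2::aes(xintercept = .data$ks_mode),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot three-mode coverage tracks along a sequence
#' @param object a `coverage_tracks`.
#' @param seq_id sequence to plot (default: first).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot coverage_tracks
#' @export
autoplot.coverage_tracks <- function(object, seq_id = NULL, ...) {
  seq_id <- seq_id %||% names(object$tracks)[1]
  t <- object$tracks[[seq_id]]
  df <- tibble(pos = rep(seq_along(t$r0), 3),
               mode = rep(c("r0 (unique)", "r1 (random-one)", "r2 (all hits)"),
                          each = length(t$r0)),
               coverage = c(t$r0, t$r1, t$r2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$coverage,
                                   colour = .data$mode)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::labs(x = sprintf("position on %s (bp)", seq_id), y = "coverage") +
    ggplot2::theme_minimal()
}

#' Plot a synteny depth profile summary
#' @param object a [depth_profile()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot depth_profile
#' @export
autoplot.depth_profile <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = factor(.data$depth), y = 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::labs(x = "synteny coverage depth", y = "% of genome") +
    ggplot2::theme_minimal()
}
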
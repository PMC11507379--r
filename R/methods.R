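#' @export
print.numt_annotation <- function(x, ...) {
  cat("<numt_annotation> vs", x$mito_name, "(L =", x$L, "bp)\n")
  cat("  HSPs:", nrow(x$hsps), " loci:", nrow(x$loci),
      " unconfirmed:", sum(x$loci$unconfirmed), "\n")
  print(x$summary)
  invisible(x)
}

#' Tidy a Numt annotation into its locus table
#'
#' @param x A `numt_annotation` object.
#' @param ... Unused.
#' @return Locus tibble without the `members` list-column.
#' @exportS3Method generics::tidy
tidy.numt_annotation <- function(x, ...) {
  select(x$loci, -"members")
}

#' One-row summary of a Numt annotation
#'
#' @param x A `numt_annotation` object.
#' @param ... Unused.
#' @return Tibble with one row: HSP and locus counts, total aligned
#'   mitochondrial bp, length-weighted mean identity, unconfirmed locus
#'   count.
#' @exportS3Method generics::glance
glance.numt_annotation <- function(x, ...) {
  tibble(
    n_hsps = nrow(x$hsps),
    n_loci = nrow(x$loci),
    n_unconfirmed = sum(x$loci$unconfirmed),
    total_aligned_bp = sum(x$hsps$aligned_bp),
    mean_identity = if (nrow(x$hsps)) {
      stats::weighted.mean(x$hsps$pident, x$hsps$aligned_bp)
    } else NA_real_,
    mito_length = x$L
  )
}

#' Plot per-base Numt coverage along the mitochondrial circle
#'
#' @param cov Integer coverage vector from [coverage_profile()], or a
#'   `numt_annotation` object.
#' @param dloop Optional two-element vector (0-based half-open) shading a
#'   region such as the D-loop.
#' @return A ggplot object.
#' @export
plot_coverage_profile <- function(cov, dloop = NULL) {
  if (inherits(cov, "numt_annotation")) {
    cov <- coverage_profile(cov$hsps, cov$L)
  }
  df <- tibble(pos = seq_along(cov) - 1L, coverage = cov)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$coverage)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::labs(x = "mitochondrial position (bp)", y = "Numt HSP coverage") +
    ggplot2::theme_minimal()
  if (!is.null(dloop)) {
    p <- p + ggplot2::annotate("rect", xmin = dloop[1], xmax = dloop[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "pink")
  }
  p
}

#' @rdname plot_coverage_profile
#' @param object A `numt_annotation` object.
#' @param ... Passed to [plot_coverage_profile()].
#' @exportS3Method ggplot2::autoplot
autoplot.numt_annotation <- function(object, ...) {
  plot_coverage_profile(object, ...)
}

#' Plot percent-identity distributions by Numt class
#'
#' @param df Data frame with columns `group` and `identity`.
#' @return A ggplot object (jittered points with median crossbar).
#' @export
plot_identity_groups <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$identity)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "red") +
    ggplot2::labs(x = NULL, y = "percent identity to mitochondrial reference") +
    ggplot2::theme_minimal()
}

#' Plot per-sample Numt counts by sample category
#'
#' @param counts Tibble from [per_sample_counts()] with a `category`
#'   column.
#' @return A ggplot object (violin + boxplot).
#' @export
plot_sample_counts <- function(counts) {
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$category, y = .data$n_numts)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "Numt insertions per sample") +
    ggplot2::theme_minimal()
}
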
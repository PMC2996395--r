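#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot spectra, optionally colored by subgroup
#'
#' @param object A `spectral_matrix`.
#' @param labels Optional named grouping (sample -> subgroup); when given,
#'   per-group mean spectra are drawn instead of individual spectra.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spectral_matrix
#' @export
autoplot.spectral_matrix <- function(object, labels = NULL, ...) {
  df <- tidy(object)
  if (!is.null(labels)) {
    df$group <- factor(labels[df$sample_id])
    df <- df |>
      dplyr::group_by(.data$group, .data$ppm) |>
      dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$ppm, .data$intensity,
                                          color = .data$group)) +
      ggplot2::geom_line()
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$ppm, .data$intensity,
                                          group = .data$sample_id)) +
      ggplot2::geom_line(alpha = 0.4)
  }
  p + ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Mean spectra of two groups with significant points flagged
#'
#' Reproduces the usual between-group spectral comparison display: the two
#' group mean spectra with vertical marks at points where the point-wise
#' test is significant.
#'
#' @param object A `pointwise_tests` result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pointwise_tests
#' @export
autoplot.pointwise_tests <- function(object, ...) {
  pair <- attr(object, "pair")
  long <- tidyr::pivot_longer(object, c("mean_g1", "mean_g2"),
                              names_to = "group", values_to = "intensity")
  long$group <- ifelse(long$group == "mean_g1", paste0("group ", pair[1L]),
                       paste0("group ", pair[2L]))
  sig <- object[object$significant, ]
  ggplot2::ggplot(long, ggplot2::aes(.data$ppm, .data$intensity,
                                     color = .data$group)) +
    ggplot2::geom_vline(data = sig, ggplot2::aes(xintercept = .data$ppm),
                        color = "grey80", linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "mean intensity",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' MDS embedding scatterplot
#'
#' @param embedding Tibble from [mds_embed()].
#' @param labels Optional named grouping used for point color.
#' @return A ggplot.
#' @export
plot_mds <- function(embedding, labels = NULL) {
  df <- embedding
  if (!is.null(labels)) df$group <- factor(labels[df$sample_id])
  aes <- if (is.null(labels)) {
    ggplot2::aes(.data$dim1, .data$dim2)
  } else {
    ggplot2::aes(.data$dim1, .data$dim2, color = .data$group)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2") +
    ggplot2::theme_minimal()
}

#' Enrichment summary table in the five-column style
#'
#' Formats an `enrichment_result` as the familiar report layout: term,
#' p-value, enrichment fold, and the `(N, B, n, b)` tuple.
#'
#' @param enr An `enrichment_result`.
#' @param significant_only Keep only terms under the FDR threshold.
#' @return Tibble with columns `category`, `term`, `p_value`, `enrichment`,
#'   `tuple`.
#' @export
enrichment_table <- function(enr, significant_only = TRUE) {
  df <- tibble::as_tibble(enr)
  if (significant_only) df <- df[df$significant, ]
  tibble::tibble(
    category = df$category,
    term = df$term,
    p_value = signif(df$p_value, 2),
    enrichment = round(df$fold, 2),
    tuple = sprintf("(%d,%d,%d,%d)", df$N, df$B, df$n_opt, df$b_opt)
  )
}
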
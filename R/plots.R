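#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_col geom_step
#'   geom_vline labs theme_minimal autoplot facet_wrap
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a windowed divergence landscape
#'
#' @param wins tibble from [windowed_divergence()].
#' @param post optional [bcp_posterior()] result fitted to the unmasked
#'   windows (posterior mean overlaid).
#' @return A ggplot object.
#' @export
plot_landscape <- function(wins, post = NULL) {
  p <- ggplot(wins, aes(x = (.data$start + .data$end) / 2, y = .data$h)) +
    geom_point(aes(shape = .data$masked), size = 0.8, colour = "grey40") +
    labs(x = "position (bp)", y = "heterozygosity H",
         shape = "masked") +
    theme_minimal()
  if (!is.null(post)) {
    un <- wins[!wins$masked & wins$callable > 0, , drop = FALSE]
    un$post_mean <- post$windows$post_mean
    p <- p + geom_line(data = un,
                       aes(x = (.data$start + .data$end) / 2,
                           y = .data$post_mean),
                       colour = "firebrick", linewidth = 0.7)
  }
  p
}

#' @rdname plot_landscape
#' @param object,... autoplot arguments.
#' @export
autoplot.bcp_result <- function(object, ...) {
  ggplot(object$windows, aes(x = .data$index, y = .data$value)) +
    geom_point(size = 0.8, colour = "grey40") +
    geom_line(aes(y = .data$post_mean), colour = "firebrick") +
    labs(x = "window", y = "value",
         title = "Posterior mean under the change-point model") +
    theme_minimal()
}

#' Plot a folded variant-type spectrum against the neutral expectation
#'
#' @param spec a [folded_spectrum()].
#' @param expected optional [neutral_type_expectation()] tibble (matched by
#'   type key; scaled to the observed total).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spec, expected = NULL) {
  d <- as_tibble(spec)[, c("key", "size", "count")]
  d$key <- factor(d$key, levels = d$key[order(d$size, d$key)])
  p <- ggplot(d, aes(x = .data$key, y = .data$count,
                     fill = factor(.data$size))) +
    geom_col() +
    labs(x = "folded variant type", y = "count", fill = "size") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(expected)) {
    e <- expected
    e$expected <- e$expected / sum(e$expected) * sum(d$count)
    e$key <- factor(e$key, levels = levels(d$key))
    p <- p + geom_point(data = e[!is.na(e$key), ],
                        aes(x = .data$key, y = .data$expected),
                        inherit.aes = FALSE, size = 0.7)
  }
  p
}

#' @rdname plot_spectrum
#' @param object,... autoplot arguments.
#' @export
autoplot.variant_spectrum <- function(object, ...) plot_spectrum(object)

#' @export
autoplot.genotype_pca <- function(object, ...) {
  d <- object$scores
  d$sex <- object$sexes %||% "unknown"
  ggplot(d, aes(x = .data$PC1, y = .data$PC2, colour = .data$sex)) +
    geom_point(size = 2) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    theme_minimal()
}

#' @export
autoplot.plateau_set <- function(object, ...) {
  d <- as_tibble(object)
  ggplot(d) +
    ggplot2::geom_segment(aes(x = .data$start_win, xend = .data$end_win,
                              y = .data$mean_div, yend = .data$mean_div,
                              colour = factor(.data$plateau)),
                          linewidth = 1.2) +
    labs(x = "window", y = "mean divergence", colour = "plateau") +
    theme_minimal()
}
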
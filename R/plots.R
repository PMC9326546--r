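# ggplot2 displays for the result objects.

#' Dot plot of an enrichment table
#'
#' Terms ordered by significance; point size is the overlap count, colour
#' the BH q-value on a -log10 scale.
#'
#' @param object A `mirhost_enrichment` tibble.
#' @param top Number of top terms shown (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirhost_enrichment <- function(object, top = 15, ...) {
  df <- object |>
    slice_head(n = top) |>
    mutate(term_id = factor(.data$term_id, levels = rev(.data$term_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_enrichment, y = .data$term_id)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$k,
                                     colour = -log10(pmax(.data$qvalue, 1e-300)))) +
    ggplot2::scale_colour_viridis_c(name = expression(-log[10] ~ q)) +
    ggplot2::scale_size_continuous(name = "overlap") +
    ggplot2::labs(x = "fold enrichment", y = NULL,
                  title = sprintf("%s-gene over-representation",
                                  if (nrow(df) > 0) df$mode[1] else "")) +
    ggplot2::theme_minimal()
}

#' Bar chart of miRNA genomic contexts
#'
#' @param object A `mirhost_assignments` tibble from [classify_contexts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirhost_assignments <- function(object, ...) {
  df <- object |>
    count(.data$context, .data$sublocation)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$context, y = .data$n,
                                   fill = .data$sublocation)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "precursors", fill = "sublocation",
                  title = "miRNA genomic context") +
    ggplot2::theme_minimal()
}

#' Side-by-side host- vs target-mode significance comparison
#'
#' Compares how many terms each interpretation mode calls significant across
#' q-value thresholds; the motivating observation is that the diffuse
#' target-gene query tends to light up many loosely related terms while the
#' compact host-gene query concentrates on few.
#'
#' @param host,target `mirhost_enrichment` tibbles for the two modes.
#' @param thresholds q-value thresholds to compare at.
#' @return A ggplot object.
#' @export
plot_mode_comparison <- function(host, target,
                                 thresholds = c(0.01, 0.05, 0.1)) {
  count_at <- function(x, thr) sum(x$qvalue < thr)
  df <- tidyr::expand_grid(mode = c("host", "target"), threshold = thresholds) |>
    mutate(n_significant = map2_int_local(.data$mode, .data$threshold,
                                          host = host, target = target,
                                          f = count_at))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$threshold),
                                   y = .data$n_significant, fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "q-value threshold", y = "significant terms",
                  fill = "mode") +
    ggplot2::theme_minimal()
}

map2_int_local <- function(modes, thrs, host, target, f) {
  map_int(seq_along(modes), function(i) {
    x <- if (modes[i] == "host") host else target
    as.integer(f(x, thrs[i]))
  })
}
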
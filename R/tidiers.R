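# broom-style accessors and ggplot2 autoplot methods for result objects.

#' @export
tidy.rddm_dmr <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "rddm_dmr")
  out
}

#' @export
tidy.rddm_diff <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "rddm_diff")
  out
}

#' @export
tidy.rddm_assoc <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "rddm_assoc")
  out
}

#' @export
tidy.rddm_screen <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "rddm_screen")
  out
}

#' @export
glance.rddm_dmr <- function(x, ...) {
  tibble(context = result_attr(x, "context"),
         comparison = result_attr(x, "comparison"),
         n_tested = result_attr(x, "n_tested"),
         n_dmr = nrow(x),
         n_hyper = sum(x$polarity == "hyper"),
         n_hypo = sum(x$polarity == "hypo"))
}

#' @export
glance.rddm_diff <- function(x, ...) {
  tibble(comparison = result_attr(x, "comparison"),
         n_features = nrow(x),
         n_up = sum(x$direction == "up"),
         n_down = sum(x$direction == "down"),
         n_ns = sum(x$direction == "ns"),
         n_treat = result_attr(x, "n_treat"),
         n_ctrl = result_attr(x, "n_ctrl"))
}

#' Volcano plot of a differential result
#' @param object An `rddm_diff` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rddm_diff <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p, 1e-300)),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b",
                                            down = "#2f6db3",
                                            ns = "grey60")) +
    ggplot2::facet_wrap(~size_class) +
    ggplot2::labs(x = "log2 fold change (log2(CPM+1) scale)",
                  y = "-log10 p",
                  title = result_attr(object, "comparison")) +
    ggplot2::theme_minimal()
}

#' Bar plot of DMR counts by polarity
#' @param object An `rddm_dmr` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rddm_dmr <- function(object, ...) {
  df <- count(as_tibble(object), .data$polarity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$polarity, y = .data$n,
                                   fill = .data$polarity)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(hyper = "#c0392b",
                                          hypo = "#2f6db3")) +
    ggplot2::labs(x = NULL, y = "DMRs",
                  title = paste(result_attr(object, "context"),
                                result_attr(object, "comparison"))) +
    ggplot2::theme_minimal()
}

#' Odds-ratio plot of DMR-DSR association strata
#' @param object An `rddm_assoc` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rddm_assoc <- function(object, ...) {
  df <- mutate(as_tibble(object),
               stratum = paste(.data$direction, "DSR /",
                               .data$polarity, "DMR"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$odds_ratio,
                                   size = .data$neg_log10_p)) +
    ggplot2::geom_point(colour = "#2f6db3") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "odds ratio", size = "-log10 p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Line plot of sRNA length distributions per sample
#' @param dist Output of [srna_length_distribution()].
#' @return A ggplot.
#' @export
plot_length_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$length,
                                     y = .data$proportion,
                                     colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_continuous(breaks = seq(18, 30, 2)) +
    ggplot2::labs(x = "sRNA length (nt)", y = "proportion of reads") +
    ggplot2::theme_minimal()
}

#' Bar plot of pooled methylation level by functional region
#' @param profile Output of [region_profile()].
#' @return A ggplot.
#' @export
plot_region_profile <- function(profile) {
  df <- mutate(profile,
               region = factor(.data$region, levels = unique(.data$region)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$level)) +
    ggplot2::geom_col(fill = "#2f6db3") +
    ggplot2::labs(x = NULL, y = "methylation level (%)") +
    ggplot2::theme_minimal()
}
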
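#' Manhattan plot of per-trait association scans
#'
#' @param gwas a `gwas_result` or GWAS tibble.
#' @param traits traits to facet over (default: all).
#' @param p_line horizontal reference line (default 0.05).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(gwas, traits = NULL, p_line = 0.05) {
  g <- gwas_table(gwas)
  if (!is.null(traits)) g <- filter(g, .data$trait %in% traits)
  g <- mutate(g, chrom = factor(.data$chrom, levels = unique(.data$chrom)))
  ggplot2::ggplot(g, ggplot2::aes(.data$pos / 1e6, -log10(.data$p_value),
                                  colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(p_line), linetype = 2) +
    ggplot2::facet_grid(trait ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.awm <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$trait, .data$snp_id,
                                 fill = .data$effect)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Association weight matrix (standardized effects)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.coassoc_network <- function(object, ...) {
  if (object$empty) abort("cannot plot an empty network")
  lay <- igraph::layout_with_fr(object$graph)
  nodes <- tibble(
    node = igraph::V(object$graph)$name, x = lay[, 1], y = lay[, 2]
  )
  edges <- object$edges |>
    left_join(nodes, by = c(node_a = "node")) |>
    left_join(nodes, by = c(node_b = "node"), suffix = c("", "_b"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_b,
                   yend = .data$y_b, alpha = abs(.data$weight)),
      colour = "grey50", show.legend = FALSE
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 1.5, colour = "steelblue") +
    ggplot2::theme_void() +
    ggplot2::labs(title = "SNP co-association network (PCIT-significant edges)")
}

#' @export
autoplot.mcode_clusters <- function(object, ...) {
  if (nrow(object$summary) == 0) abort("no clusters to plot")
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$nodes, .data$score,
                               size = .data$edges,
                               label = .data$network)) +
    ggplot2::geom_point(alpha = 0.7, colour = "darkred") +
    ggplot2::geom_text(vjust = -1, size = 3) +
    ggplot2::labs(x = "nodes", y = "score (density x nodes)",
                  title = "MCODE clusters") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.enrichment_result <- function(object, n_terms = 15, ...) {
  d <- head(as_tibble(object), n_terms)
  ggplot2::ggplot(d, ggplot2::aes(-log10(.data$p_value),
                                  stats::reorder(.data$term, -.data$p_value),
                                  fill = .data$fold_enrichment)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL,
                  title = "Term enrichment") +
    ggplot2::theme_minimal()
}
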
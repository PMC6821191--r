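#' Plot a consensus metagene profile
#'
#' Bar chart of aggregated crosslink counts per consensus position,
#' shaded by structural region, with the T-loop m5U/m1A coordinates easy
#' to read off.
#'
#' @param object A `ficc_profile` from [project_sites()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ficc_profile
#' @export
autoplot.ficc_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cons_pos, y = .data$count,
                                   fill = .data$region)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(
      x = "tRNA consensus position", y = "crosslink count",
      title = sprintf("Consensus profile (%s, %d genes)",
                      attr(object, "mode"), attr(object, "n_genes"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot an anchored motif PWM
#'
#' Per-position base probabilities of the anchored position-weight
#' matrix as stacked columns (a text-free sequence-logo stand-in).
#'
#' @param object A `ficc_anchor` from [filter_anchor()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ficc_anchor
#' @export
autoplot.ficc_anchor <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$probability,
                                   fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(breaks = unique(df$position)) +
    ggplot2::labs(x = "motif position", y = "base probability") +
    ggplot2::theme_minimal()
}

#' Heatmap of replicate/experiment count correlations
#'
#' @param r Correlation matrix from [correlate_counts()].
#' @return A ggplot object.
#' @export
plot_correlation <- function(r) {
  df <- tibble::as_tibble(r, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r))) +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
                                 high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Crosslink-site track around one gene
#'
#' Column track of per-position crosslink counts over a gene interval,
#' one panel per sample - the single-gene browser-style view.
#'
#' @param sites Site tibble from [extract_crosslinks()].
#' @param gene One row of the gene tibble (or a gene_id plus the gene
#'   tibble via `genes`).
#' @param genes Gene tibble, required when `gene` is an id string.
#' @return A ggplot object.
#' @export
plot_gene_track <- function(sites, gene, genes = NULL) {
  if (is.character(gene)) {
    gene <- genes[genes$gene_id == gene, ]
  }
  df <- dplyr::filter(
    sites, .data$chrom == gene$chrom, .data$strand == gene$strand,
    .data$pos >= gene$start, .data$pos < gene$end
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$pos, .data$count)) +
    ggplot2::geom_col(fill = "purple4") +
    ggplot2::facet_wrap(~sample, ncol = 1) +
    ggplot2::labs(
      x = sprintf("%s:%d-%d (%s)", gene$chrom, gene$start, gene$end,
                  gene$strand),
      y = "unique cDNA truncations", title = gene$gene_id
    ) +
    ggplot2::theme_minimal()
}
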
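#' Position-frequency motif plot of a CDR3 cluster
#'
#' Tile plot of the residue-frequency profile of one cluster, positions on
#' the x axis, residues observed at each position stacked by frequency.
#'
#' @param clusters A `tcr_clusters` tibble.
#' @param cluster_id Which cluster to draw (default: first).
#' @return A ggplot object.
#' @export
plot_cluster_motif <- function(clusters, cluster_id = clusters$cluster_id[1]) {
  row <- clusters[clusters$cluster_id == cluster_id, ]
  if (nrow(row) == 0) abort("unknown cluster_id")
  m <- row$motif[[1]]
  df <- as_tibble(as.table(m), .name_repair = ~ c("residue", "position", "freq")) %>%
    filter(.data$freq > 0) %>%
    mutate(position = as.integer(factor(.data$position, levels = unique(.data$position))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$freq,
                                   fill = .data$residue)) +
    ggplot2::geom_col(color = "grey30", linewidth = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue),
                       position = ggplot2::position_stack(vjust = 0.5), size = 3) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(m))) +
    ggplot2::labs(title = paste0(row$name, " (", row$consensus, ")"),
                  x = "junction position", y = "residue frequency") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Neighbor-enrichment overview plot
#'
#' Repertoire neighbor count against the Bonferroni-adjusted p-value
#' (-log10), significant clones highlighted.
#'
#' @param object A `tcr_enrichment` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot tcr_enrichment
#' @export
autoplot.tcr_enrichment <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(neglog_p = -log10(pmax(.data$p_adj, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k_rep, y = .data$neglog_p,
                                   color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "params")$alpha %||% 0.05),
                        linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "neighbors in repertoire", y = "-log10 adjusted p",
                  color = "enriched") +
    ggplot2::theme_minimal()
}

#' Paired clone-dynamics plot
#'
#' Pre- against post-treatment clone frequency on log axes; clones passing the
#' selection filter are highlighted and the identity line drawn.
#'
#' @param object A `tcr_dynamics` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot tcr_dynamics
#' @export
autoplot.tcr_dynamics <- function(object, ...) {
  filt <- attr(object, "filters")
  floor_f <- 10^floor(log10(min(c(object$freq_pre[object$freq_pre > 0],
                                  object$freq_post[object$freq_post > 0], 1e-4))))
  df <- as_tibble(object) %>%
    mutate(fp = pmax(.data$freq_pre, floor_f), fq = pmax(.data$freq_post, floor_f))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fp, y = .data$fq,
                                   color = .data$selected)) +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "frequency (pre)", y = "frequency (post)",
                  color = sprintf(">=%g%% & fold>=%g",
                                  100 * (filt$min_freq %||% 0.01),
                                  filt$min_fold %||% 2)) +
    ggplot2::theme_minimal()
}

#' Clonal expansion-bin bar plot
#'
#' @param freq_table A [clone_frequencies()] table.
#' @param edges Bin edges forwarded to [expansion_bins()].
#' @return A ggplot object.
#' @export
plot_expansion_bins <- function(freq_table,
                                edges = c(single = 1, small = 5, medium = 20,
                                          large = 100)) {
  df <- freq_table %>%
    mutate(bin = expansion_bins(.data$count, edges = edges)) %>%
    count(.data$sample_id, .data$bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$n,
                                   fill = .data$sample_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "expansion category", y = "clones", fill = "sample") +
    ggplot2::theme_minimal()
}

#' Generation-probability band plot
#'
#' Log10 generation probabilities with the geometric mean (dashed) and the
#' one-SD band (dotted) marked.
#'
#' @param pgen_values Positive generation probabilities.
#' @return A ggplot object.
#' @export
plot_pgen_band <- function(pgen_values) {
  band <- pgen_band(pgen_values)
  df <- tibble(log10_pgen = log10(pgen_values))
  mu <- log10(band$geometric_mean)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_pgen)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_vline(xintercept = mu, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(mu - band$log_sd, mu + band$log_sd),
                        linetype = "dotted") +
    ggplot2::labs(x = "log10 generation probability", y = "density") +
    ggplot2::theme_minimal()
}
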
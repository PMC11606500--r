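#' Clone frequency table of a sample
#'
#' Counts cells per clone key and normalizes by the sample's total number of
#' TCR-bearing cells, so expansion is expressed as repertoire frequency rather
#' than raw category counts.
#'
#' @param repertoire Clonotype/repertoire tibble (`clone_key`, `sample_id`).
#' @param sample_id Optional restriction to one sample.
#' @return A tibble: `clone_key`, `sample_id`, `count`, `frequency`
#'   (frequencies sum to 1 within a sample).
#' @export
clone_frequencies <- function(repertoire, sample_id = NULL) {
  tab <- as_tibble(repertoire)
  if (!is.null(sample_id)) tab <- filter(tab, .data$sample_id %in% !!sample_id)
  if (nrow(tab) == 0) abort("no cells in the requested sample")
  tab %>%
    count(.data$sample_id, .data$clone_key, name = "count") %>%
    group_by(.data$sample_id) %>%
    mutate(frequency = .data$count / sum(.data$count)) %>%
    ungroup() %>%
    select("clone_key", "sample_id", "count", "frequency")
}

#' Treatment-responsive clones between paired samples
#'
#' Implements the paired selection filter: a clone is selected when it
#' comprises at least `min_freq` of the repertoire in either sample and shows
#' at least a `min_fold` difference between the timepoints. For fold-change
#' computation only, a clone absent from one sample receives a pseudo-count
#' (default 1 cell) so the fold is defined; the 1%-of-repertoire filter uses
#' the raw frequencies (absent = 0).
#'
#' @param table_pre,table_post [clone_frequencies()] tables of the paired
#'   samples (distinct `sample_id`s).
#' @param min_freq Frequency filter (default 0.01, i.e. 1%).
#' @param min_fold Fold-change filter (default 2).
#' @param pseudo Pseudo-count for absent clones (default 1).
#' @return A `tcr_dynamics` tibble: `clone_key`, `count_pre`, `count_post`,
#'   `freq_pre`, `freq_post`, `fold_change`, `direction`
#'   (expanded/contracted/stable), `selected`.
#' @export
paired_dynamics <- function(table_pre, table_post, min_freq = 0.01,
                            min_fold = 2, pseudo = 1) {
  id_pre <- unique(table_pre$sample_id)
  id_post <- unique(table_post$sample_id)
  if (length(intersect(id_pre, id_post)) > 0) {
    abort("pre and post tables carry the same sample_id")
  }
  tot_pre <- sum(table_pre$count)
  tot_post <- sum(table_post$count)
  merged <- full_join(
    select(table_pre, "clone_key", count_pre = "count", freq_pre = "frequency"),
    select(table_post, "clone_key", count_post = "count", freq_post = "frequency"),
    by = "clone_key") %>%
    mutate(
      count_pre = tidyr::replace_na(.data$count_pre, 0L),
      count_post = tidyr::replace_na(.data$count_post, 0L),
      freq_pre = tidyr::replace_na(.data$freq_pre, 0),
      freq_post = tidyr::replace_na(.data$freq_post, 0),
      f_pre_eff = if_else(.data$count_pre == 0, pseudo / tot_pre, .data$freq_pre),
      f_post_eff = if_else(.data$count_post == 0, pseudo / tot_post, .data$freq_post),
      fold_change = pmax(.data$f_pre_eff, .data$f_post_eff) /
        pmin(.data$f_pre_eff, .data$f_post_eff),
      direction = dplyr::case_when(
        .data$f_post_eff > .data$f_pre_eff ~ "expanded",
        .data$f_post_eff < .data$f_pre_eff ~ "contracted",
        TRUE ~ "stable"),
      selected = (.data$freq_pre >= min_freq | .data$freq_post >= min_freq) &
        .data$fold_change >= min_fold) %>%
    select(-"f_pre_eff", -"f_post_eff") %>%
    arrange(desc(.data$selected), desc(.data$fold_change), .data$clone_key)
  attr(merged, "filters") <- list(min_freq = min_freq, min_fold = min_fold,
                                  pseudo = pseudo)
  class(merged) <- c("tcr_dynamics", class(merged))
  merged
}

#' Categorical expansion bins of clone sizes
#'
#' Conventional count categories of clonal expansion; the default edges
#' (single = 1, small = 2-5, medium = 6-20, large = 21-100,
#' hyperexpanded > 100) are conventions, recorded in the output metadata, not
#' fixed biology.
#'
#' @param counts Positive integer clone sizes.
#' @param edges Upper bin edges (named).
#' @return Factor of bin labels with the edges in the `"edges"` attribute.
#' @export
expansion_bins <- function(counts,
                           edges = c(single = 1, small = 5, medium = 20, large = 100)) {
  if (any(counts <= 0)) abort("clone counts must be positive")
  breaks <- c(0, unname(edges), Inf)
  labels <- c(names(edges), "hyperexpanded")
  out <- cut(counts, breaks = breaks, labels = labels)
  attr(out, "edges") <- edges
  out
}

#' Rank-sum marker enrichment of a cell group against a background
#'
#' Per gene: counts are library-size normalized to 10,000 and log1p
#' transformed; a two-sided Wilcoxon rank-sum test (normal approximation with
#' tie correction) compares the group to the background, and the log2 fold
#' change of the normalized means (with a small epsilon) is computed. Genes
#' passing `|lfc| >= lfc_min` and `p < p_max` are reported, at most `top_n`
#' ordered by ascending p then decreasing |lfc|.
#'
#' @param gex Cells-by-genes count matrix.
#' @param group_barcodes,background_barcodes Disjoint barcode sets, each with
#'   at least 3 cells (below that there are too few cells for a statistical
#'   comparison).
#' @param lfc_min Log2 fold-change threshold (default 0.25).
#' @param p_max P-value threshold (default 0.05).
#' @param top_n Rows reported (default 30).
#' @return A `marker_table` tibble: `gene`, `log2_fold_change`, `p_value`,
#'   `pct_in_group`, `pct_in_background`. The unfiltered per-gene table is in
#'   the `"all_genes"` attribute.
#' @export
rank_sum_markers <- function(gex, group_barcodes, background_barcodes,
                             lfc_min = 0.25, p_max = 0.05, top_n = 30) {
  if (length(intersect(group_barcodes, background_barcodes)) > 0) {
    abort("group and background barcodes overlap")
  }
  if (length(group_barcodes) < 3 || length(background_barcodes) < 3) {
    abort("fewer than 3 cells in a group: insufficient cells for statistical analysis")
  }
  g <- as.matrix(gex[group_barcodes, , drop = FALSE])
  b <- as.matrix(gex[background_barcodes, , drop = FALSE])
  norm <- function(m) {
    ls <- rowSums(m)
    ls[ls == 0] <- 1
    log1p(m / ls * 1e4)
  }
  gn <- norm(g); bn <- norm(b)
  eps <- 1e-9
  genes <- colnames(gex)
  p <- vapply(seq_along(genes), function(j) {
    x <- gn[, j]; y <- bn[, j]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1)
    suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
  }, numeric(1))
  lfc <- log2((colMeans(gn) + eps) / (colMeans(bn) + eps))
  all_genes <- tibble(
    gene = genes, log2_fold_change = unname(lfc), p_value = unname(p),
    pct_in_group = unname(colMeans(g > 0)),
    pct_in_background = unname(colMeans(b > 0)))
  out <- all_genes %>%
    filter(abs(.data$log2_fold_change) >= lfc_min, .data$p_value < p_max) %>%
    arrange(.data$p_value, desc(abs(.data$log2_fold_change))) %>%
    head(top_n)
  attr(out, "all_genes") <- all_genes
  class(out) <- c("marker_table", class(out))
  out
}
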
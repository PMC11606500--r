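#' Default TCR-sequence annotation rules
#'
#' Ordered rule set (first match wins):
#' \itemize{
#'   \item \strong{MAIT}: AG chain uses TRAV1-2 with TRAJ33, TRAJ20 or TRAJ12
#'     (the semi-invariant MR1-restricted receptor).
#'   \item \strong{gamma_delta}: any TRG or TRD chain present.
#'   \item \strong{CD1bc_candidate}: TRAV13-2 on the AG chain paired with
#'     TRBV4-1 on the BD chain (a candidate call, not a confirmed
#'     restriction).
#'   \item \strong{alpha_beta}: everything else.
#' }
#'
#' @return A tibble of rules (`label`, `priority`, `v_ag`, `j_ag`, `v_bd`,
#'   `j_bd`, `gd`); `j_ag` etc. are list-columns of allowed gene sets (`NULL`
#'   = no constraint), `gd` marks the gamma-delta presence rule.
#' @export
default_tcr_rules <- function() {
  tibble(
    label = c("MAIT", "gamma_delta", "CD1bc_candidate"),
    priority = 1:3,
    v_ag = list("TRAV1-2", NULL, "TRAV13-2"),
    j_ag = list(c("TRAJ33", "TRAJ20", "TRAJ12"), NULL, NULL),
    v_bd = list(NULL, NULL, "TRBV4-1"),
    j_bd = list(NULL, NULL, NULL),
    gd = c(FALSE, TRUE, FALSE))
}

#' Classify cells by TCR gene-usage rules
#'
#' Applies an ordered rule set to each clonotype row; the first rule whose
#' every non-empty requirement is met wins, and cells matching no rule are
#' labeled `"alpha_beta"` (total function). Deterministic: rules are applied
#' in increasing `priority`.
#'
#' @param repertoire Clonotype tibble (columns `v_ag`, `j_ag`, `v_bd`,
#'   `j_bd`, `locus_ag`, `locus_bd`).
#' @param rules Rule tibble ([default_tcr_rules()] layout).
#' @param default_label Label for unmatched cells (default `"alpha_beta"`).
#' @return The repertoire with a `tcr_label` column appended.
#' @export
classify_by_tcr <- function(repertoire, rules = default_tcr_rules(),
                            default_label = "alpha_beta") {
  rules <- rules[order(rules$priority), , drop = FALSE]
  n <- nrow(repertoire)
  label <- rep(NA_character_, n)
  in_set <- function(x, set) {
    if (is.null(set)) rep(TRUE, n) else !is.na(x) & x %in% set
  }
  for (r in seq_len(nrow(rules))) {
    hit <- in_set(repertoire$v_ag, rules$v_ag[[r]]) &
      in_set(repertoire$j_ag, rules$j_ag[[r]]) &
      in_set(repertoire$v_bd, rules$v_bd[[r]]) &
      in_set(repertoire$j_bd, rules$j_bd[[r]])
    if (isTRUE(rules$gd[r])) {
      hit <- (!is.na(repertoire$locus_ag) & repertoire$locus_ag == "TRG") |
        (!is.na(repertoire$locus_bd) & repertoire$locus_bd == "TRD")
    }
    label[is.na(label) & hit] <- rules$label[r]
  }
  label[is.na(label)] <- default_label
  repertoire$tcr_label <- label
  repertoire
}

#' Rank-based signature score of cells
#'
#' UCell-style capped rank statistic: genes are ranked per cell by decreasing
#' count (ties get the average rank, so unexpressed genes share the maximal
#' ranks), ranks are capped at `r_max + 1`, and with `n` signature genes and
#' `R` the sum of their capped ranks the score is
#' `1 - (R - n(n+1)/2) / (n * r_max)`, clipped to `[0, 1]`. Invariant to any
#' monotone transformation of the counts.
#'
#' @param gex Cells-by-genes matrix (or a single named count vector).
#' @param gene_set Character vector of signature genes.
#' @param r_max Rank cap (default 1500).
#' @return Numeric vector of scores, one per cell.
#' @export
signature_score <- function(gex, gene_set, r_max = 1500) {
  if (is.null(dim(gex))) {
    gex <- matrix(gex, nrow = 1, dimnames = list("cell", names(gex)))
  }
  present <- intersect(gene_set, colnames(gex))
  if (length(present) == 0) {
    abort(paste0("no signature gene found in the matrix: ",
                 paste(head(gene_set, 5), collapse = ", ")))
  }
  n <- length(present)
  dense <- as.matrix(gex)
  scores <- apply(dense, 1, function(x) {
    r <- rank(-x, ties.method = "average")
    r <- pmin(r, r_max + 1)
    R <- sum(r[present])
    1 - (R - n * (n + 1) / 2) / (n * r_max)
  })
  pmin(1, pmax(0, scores))
}

#' Build a gating-tree node
#'
#' @param name Node name (becomes the cell label when this is the deepest
#'   node passed).
#' @param positive,negative Lists of gene sets; a cell passes the node iff the
#'   maximum positive-signature score reaches `tau_pos` and every
#'   negative-signature score stays below `tau_neg`.
#' @param children List of child `gating_node`s.
#' @param tau_pos,tau_neg Optional node-level threshold overrides.
#' @return A `gating_node`.
#' @export
gating_node <- function(name, positive = list(), negative = list(),
                        children = list(), tau_pos = NULL, tau_neg = NULL) {
  if (length(positive) > 0 && !is.list(positive)) positive <- list(positive)
  if (length(negative) > 0 && !is.list(negative)) negative <- list(negative)
  structure(list(name = name, positive = positive, negative = negative,
                 children = children, tau_pos = tau_pos, tau_neg = tau_neg),
            class = "gating_node")
}

#' Read a gating tree from a YAML file
#'
#' Each YAML node carries `name`, optional `positive`/`negative` signature
#' lists and `children`. An illustrative tree ships at
#' `system.file("extdata", "gating_tree.yaml", package = "tcrfirst")`.
#'
#' @param path YAML file path.
#' @return A `gating_node`.
#' @export
read_gating_tree <- function(path) {
  build <- function(x, seen = character()) {
    if (x$name %in% seen) abort("gating tree contains a cycle or duplicated node name")
    seen <- c(seen, x$name)
    gating_node(
      name = x$name,
      positive = lapply(x$positive %||% list(), unlist),
      negative = lapply(x$negative %||% list(), unlist),
      children = lapply(x$children %||% list(), build, seen = seen),
      tau_pos = x$tau_pos %||% NULL, tau_neg = x$tau_neg %||% NULL)
  }
  build(yaml::read_yaml(path))
}

#' Semi-supervised marker gating of cells
#'
#' Depth-first descent of a gating tree: a cell passes a node iff its best
#' positive-signature score is at least `tau_pos` and all negative-signature
#' scores are below `tau_neg`; the cell's label is the deepest node passed.
#' When several siblings pass, descent follows the child with the highest
#' positive score (deterministic). Cells failing the root are labeled
#' `"non-T/unknown"`. Cells are processed in batches of `batch_size` with
#' results independent of the batch size.
#'
#' @param gex Cells-by-genes count matrix.
#' @param tree Root [gating_node()].
#' @param tau_pos,tau_neg Default thresholds (0.2 each), overridable per node.
#' @param r_max Rank cap for [signature_score()].
#' @param batch_size Cells per scoring batch (default all).
#' @return A tibble: `barcode`, `gex_label`, plus one `score_*` column per
#'   distinct signature.
#' @export
gate_cells <- function(gex, tree, tau_pos = 0.2, tau_neg = 0.2, r_max = 1500,
                       batch_size = Inf) {
  sigs <- collect_signatures(tree)
  n <- nrow(gex)
  starts <- seq(1, n, by = if (is.finite(batch_size)) batch_size else n)
  res <- lapply(starts, function(s) {
    idx <- s:min(n, s + (if (is.finite(batch_size)) batch_size else n) - 1)
    sub <- gex[idx, , drop = FALSE]
    scores <- vapply(sigs, function(g) signature_score(sub, g, r_max = r_max),
                     numeric(length(idx)))
    if (length(idx) == 1) scores <- matrix(scores, nrow = 1, dimnames = list(NULL, names(sigs)))
    label <- vapply(seq_along(idx), function(ci) {
      descend(tree, scores[ci, ], tau_pos, tau_neg)
    }, "")
    tibble(barcode = rownames(sub), gex_label = label) %>%
      dplyr::bind_cols(as_tibble(scores,
                                 .name_repair = ~ paste0("score_", names(sigs))))
  })
  bind_rows(res)
}

# unique signatures of a tree, keyed by a stable hash of the gene set
collect_signatures <- function(node, acc = list()) {
  for (g in c(node$positive, node$negative)) {
    acc[[sig_key(g)]] <- g
  }
  for (ch in node$children) acc <- collect_signatures(ch, acc)
  acc
}

sig_key <- function(genes) paste(sort(genes), collapse = "+")

node_passes <- function(node, s, tau_pos, tau_neg) {
  tp <- node$tau_pos %||% tau_pos
  tn <- node$tau_neg %||% tau_neg
  pos_ok <- if (length(node$positive) == 0) TRUE else {
    max(vapply(node$positive, function(g) s[[sig_key(g)]], 0)) >= tp
  }
  neg_ok <- if (length(node$negative) == 0) TRUE else {
    max(vapply(node$negative, function(g) s[[sig_key(g)]], 0)) < tn
  }
  pos_ok && neg_ok
}

pos_score <- function(node, s) {
  if (length(node$positive) == 0) return(0)
  max(vapply(node$positive, function(g) s[[sig_key(g)]], 0))
}

descend <- function(node, s, tau_pos, tau_neg) {
  if (!node_passes(node, s, tau_pos, tau_neg)) return("non-T/unknown")
  current <- node
  repeat {
    passing <- keep(current$children, node_passes, s = s,
                    tau_pos = tau_pos, tau_neg = tau_neg)
    if (length(passing) == 0) return(current$name)
    best <- which.max(vapply(passing, pos_score, 0, s = s))
    current <- passing[[best]]
  }
}

#' Join externally produced epitope annotations onto a repertoire
#'
#' Left-joins a clone-level epitope table (e.g. an export of an external
#' epitope-specificity predictor) on `clone_key`, keeping annotations whose
#' prediction score exceeds the threshold; sub-threshold rows are dropped and
#' counted.
#'
#' @param repertoire Clonotype/repertoire tibble with a `clone_key` column.
#' @param annotations A tibble or TSV path with columns `clone_key`,
#'   `epitope`, `score`.
#' @param min_score Score threshold (default 0.2, exclusive).
#' @return The repertoire with `epitope` and `epitope_score` columns; the
#'   number of sub-threshold annotations dropped in the `"dropped_low_score"`
#'   attribute.
#' @export
join_external_epitopes <- function(repertoire, annotations, min_score = 0.2) {
  if (is.character(annotations)) {
    annotations <- readr::read_tsv(annotations, show_col_types = FALSE,
                                   progress = FALSE)
  }
  required <- c("clone_key", "epitope", "score")
  if (!all(required %in% names(annotations))) {
    abort(paste0("epitope table must have columns: ",
                 paste(required, collapse = ", ")),
          class = "tcrfirst_format_error")
  }
  n_low <- sum(annotations$score <= min_score)
  keepers <- annotations %>%
    filter(.data$score > min_score) %>%
    group_by(.data$clone_key) %>%
    slice_max(.data$score, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    select("clone_key", epitope = "epitope", epitope_score = "score")
  out <- left_join(as_tibble(repertoire), keepers, by = "clone_key")
  attr(out, "dropped_low_score") <- n_low
  out
}
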
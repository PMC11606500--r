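#' Split a repertoire into per-chain unique sequence items
#'
#' Deduplicates the resolved chains of a repertoire into one item per unique
#' (locus, v_gene, cdr3_aa) combination, per chain class A (TRA), B (TRB),
#' G (TRG), D (TRD). Each item records a multiplicity (number of cells) and a
#' modal j_gene. Clustering and enrichment run independently per chain, so a
#' gamma chain can never fall into an alpha cluster.
#'
#' @param repertoire Clonotype tibble ([resolve_cell_chains()] /
#'   [build_repertoire()]).
#' @return Named list of item tibbles (`A`, `B`, `G`, `D`), each with columns
#'   `item_id`, `locus`, `v_gene`, `j_gene`, `cdr3_aa`, `multiplicity`.
#' @export
cluster_chain_split <- function(repertoire) {
  long <- bind_rows(
    repertoire %>%
      filter(!is.na(.data$cdr3_ag)) %>%
      select(locus = "locus_ag", v_gene = "v_ag", j_gene = "j_ag", cdr3_aa = "cdr3_ag"),
    repertoire %>%
      filter(!is.na(.data$cdr3_bd)) %>%
      select(locus = "locus_bd", v_gene = "v_bd", j_gene = "j_bd", cdr3_aa = "cdr3_bd"))
  chains <- c(TRA = "A", TRB = "B", TRG = "G", TRD = "D")
  out <- lapply(names(chains), function(loc) {
    items <- long %>%
      filter(.data$locus == loc) %>%
      group_by(.data$locus, .data$v_gene, .data$cdr3_aa) %>%
      summarise(j_gene = modal_value(.data$j_gene),
                multiplicity = dplyr::n(), .groups = "drop") %>%
      arrange(.data$v_gene, .data$cdr3_aa) %>%
      mutate(item_id = row_number()) %>%
      select("item_id", "locus", "v_gene", "j_gene", "cdr3_aa", "multiplicity")
    items
  })
  names(out) <- chains
  out
}

# modal value with lexicographic tie-break, optionally weighted
modal_value <- function(x, w = NULL) {
  if (length(x) == 0) return(NA_character_)
  if (is.null(w)) w <- rep(1, length(x))
  tot <- tapply(w, x, sum)
  names(tot)[order(-tot, names(tot))][1]
}

#' Hamming-distance-1 candidate pairs by wildcard hashing
#'
#' Finds all pairs of items whose CDR3 amino-acid sequences are at Hamming
#' distance at most 1 (equal length by construction) without an all-pairs
#' scan: each length-L sequence emits L wildcard keys (one position masked)
#' plus one exact key; items sharing a key are candidates and candidate pairs
#' are verified. Distinct items carrying an identical CDR3 (different V gene)
#' are at distance 0 and therefore connected.
#'
#' @param items Item tibble from [cluster_chain_split()] (columns `item_id`,
#'   `cdr3_aa`, and optionally `locus`; items must be deduplicated).
#' @param require_v Additionally require equal `v_gene` on an edge (the
#'   stricter clustering variant).
#' @return A `cdr3_graph`: list with `items` and an `edges` tibble
#'   (`from` < `to`, item ids).
#' @export
hamming_pairs <- function(items, require_v = FALSE) {
  n <- nrow(items)
  edges <- tibble(from = integer(), to = integer())
  if (n > 0) {
    seqs <- items$cdr3_aa
    if (any(is.na(seqs) | seqs == "")) abort("items contain empty CDR3 sequences")
    locus <- if ("locus" %in% names(items)) items$locus else rep("", n)
    lens <- nchar(seqs)
    key_list <- lapply(seq_len(n), function(i) {
      s <- seqs[i]; L <- lens[i]
      ks <- vapply(seq_len(L), function(p) {
        sub <- s
        substr(sub, p, p) <- "."
        sub
      }, "")
      paste0(locus[i], ":", L, ":", c(s, ks))
    })
    ids <- rep(seq_len(n), lengths(key_list))
    keys <- unlist(key_list, use.names = FALSE)
    grp <- split(ids, keys)
    grp <- grp[lengths(grp) > 1]
    if (length(grp) > 0) {
      pair_mat <- do.call(cbind, lapply(grp, function(g) {
        g <- sort(unique(g))
        if (length(g) < 2) return(NULL)
        utils::combn(g, 2)
      }))
      if (!is.null(pair_mat) && ncol(pair_mat) > 0) {
        cand <- unique(t(pair_mat))
        hd <- hamming_dist_pairs(seqs[cand[, 1]], seqs[cand[, 2]])
        ok <- hd <= 1
        if (require_v) ok <- ok & items$v_gene[cand[, 1]] == items$v_gene[cand[, 2]]
        edges <- tibble(from = cand[ok, 1], to = cand[ok, 2]) %>%
          arrange(.data$from, .data$to)
      }
    }
  }
  structure(list(items = items, edges = edges), class = "cdr3_graph")
}

# vectorized Hamming distance for equal-length string pairs (Inf otherwise)
hamming_dist_pairs <- function(a, b) {
  out <- rep(Inf, length(a))
  eq <- nchar(a) == nchar(b)
  if (any(eq)) {
    out[eq] <- mapply(function(x, y) {
      sum(charToRaw(x) != charToRaw(y))
    }, a[eq], b[eq], USE.NAMES = FALSE)
  }
  out
}

#' Markov clustering of a similarity graph
#'
#' Canonical MCL on the undirected graph: the adjacency matrix with self-loops
#' is column-normalized, then expansion (matrix power) and inflation
#' (elementwise power followed by column renormalization) alternate, pruning
#' entries below `prune_tol`, until the iterate changes by less than `1e-8` or
#' `max_iter` is reached. Each node is assigned to the attractor row holding
#' the maximum of its column (ties: smallest attractor id). Clusters of size
#' one are reported separately, not as clusters.
#'
#' @param graph A `cdr3_graph` from [hamming_pairs()], or a two-column
#'   edge tibble/matrix plus `n_nodes`.
#' @param inflation Inflation exponent (default 2).
#' @param expansion Expansion power (default 2).
#' @param max_iter Iteration cap (default 100).
#' @param prune_tol Entries below this are dropped each iteration
#'   (default 1e-5).
#' @param n_nodes Number of nodes when `graph` is a raw edge list.
#' @return A tibble (`item_id`, `cluster`) covering non-singleton nodes;
#'   singleton ids in the `"singletons"` attribute.
#' @export
mcl_partition <- function(graph, inflation = 2, expansion = 2, max_iter = 100,
                          prune_tol = 1e-5, n_nodes = NULL) {
  if (inherits(graph, "cdr3_graph")) {
    edges <- graph$edges
    n <- nrow(graph$items)
  } else {
    edges <- as_tibble(as.data.frame(graph))
    names(edges)[1:2] <- c("from", "to")
    if (is.null(n_nodes)) n_nodes <- max(0, edges$from, edges$to)
    n <- n_nodes
  }
  empty <- tibble(item_id = integer(), cluster = integer())
  if (n == 0) {
    attr(empty, "singletons") <- integer()
    return(empty)
  }
  if (nrow(edges) == 0) {
    attr(empty, "singletons") <- seq_len(n)
    return(empty)
  }
  if (any(edges$from == edges$to)) abort("self-edges are not allowed")
  key_f <- paste(edges$from, edges$to)
  key_r <- paste(edges$to, edges$from)
  if (any(key_f %in% key_r)) {
    abort("edge list contains both orientations of a pair; supply each undirected edge once")
  }

  A <- Matrix::sparseMatrix(i = c(edges$from, edges$to, seq_len(n)),
                            j = c(edges$to, edges$from, seq_len(n)),
                            x = 1, dims = c(n, n))
  M <- col_normalize(A)
  for (it in seq_len(max_iter)) {
    Mexp <- M
    if (expansion > 1) for (k in seq_len(expansion - 1)) Mexp <- Mexp %*% M
    Minf <- Mexp
    Minf@x <- Minf@x^inflation
    Minf@x[Minf@x < prune_tol] <- 0
    Minf <- Matrix::drop0(Minf)
    Minf <- col_normalize(Minf)
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < 1e-8) break
  }

  # attractor of column j = argmax row, ties -> smallest row index
  Md <- as.matrix(M)
  att <- apply(Md, 2, which.max)
  cl <- match(att, sort(unique(att)))
  sizes <- table(cl)
  singleton_cl <- as.integer(names(sizes)[sizes == 1])
  singletons <- which(cl %in% singleton_cl)
  keep <- setdiff(seq_len(n), singletons)
  out <- tibble(item_id = keep, cluster = cl[keep]) %>%
    mutate(cluster = match(.data$cluster, unique(.data$cluster))) %>%
    arrange(.data$cluster, .data$item_id)
  attr(out, "singletons") <- singletons
  out
}

col_normalize <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

#' Summarize an MCL partition into named CDR3 clusters
#'
#' Builds per-cluster summaries: name (modal V gene and modal J gene among the
#' members, weighted by multiplicity, lexicographic tie-break), the
#' position-wise residue-frequency motif, and a consensus string in which
#' positions conserved at frequency >= 0.95 are uppercase and variable
#' positions show the majority residue in lowercase.
#'
#' @param partition Output of [mcl_partition()].
#' @param items The item tibble the partition refers to.
#' @return A `tcr_clusters` tibble: `cluster_id`, `chain`, `name`,
#'   `junction_length`, `n_members`, `n_cells`, `consensus`, with the motif
#'   matrices in a `motif` list-column and member tables in `members`.
#' @export
build_clusters <- function(partition, items) {
  chains <- c(TRA = "A", TRB = "B", TRG = "G", TRD = "D")
  rows <- partition %>%
    left_join(items, by = "item_id") %>%
    group_by(.data$cluster)
  out <- rows %>%
    summarise(
      chain = unname(chains[first(.data$locus)]) %||% NA_character_,
      name = paste(modal_value(.data$v_gene, .data$multiplicity),
                   modal_value(.data$j_gene, .data$multiplicity)),
      junction_length = {
        ls <- unique(nchar(.data$cdr3_aa))
        if (length(ls) != 1) abort("cluster members have mixed junction lengths (internal error)")
        ls
      },
      n_members = dplyr::n(),
      n_cells = sum(.data$multiplicity),
      motif = list(motif_matrix(.data$cdr3_aa, .data$multiplicity)),
      members = list(dplyr::pick("item_id", "v_gene", "j_gene", "cdr3_aa",
                                 "multiplicity")),
      .groups = "drop") %>%
    mutate(consensus = map_chr(.data$motif, motif_consensus)) %>%
    rename(cluster_id = "cluster") %>%
    select("cluster_id", "chain", "name", "junction_length", "n_members",
           "n_cells", "consensus", "motif", "members")
  if (any(out$n_members < 2)) abort("singleton passed to build_clusters")
  class(out) <- c("tcr_clusters", class(out))
  out
}

# position-wise residue relative frequencies, multiplicity-weighted;
# columns (positions) each sum to 1
motif_matrix <- function(seqs, w) {
  L <- nchar(seqs[1])
  m <- matrix(0, nrow = length(AA20), ncol = L, dimnames = list(AA20, NULL))
  chars <- strsplit(seqs, "", fixed = TRUE)
  for (i in seq_along(seqs)) {
    idx <- match(chars[[i]], AA20)
    m[cbind(idx, seq_len(L))] <- m[cbind(idx, seq_len(L))] + w[i]
  }
  sweep(m, 2, colSums(m), "/")
}

motif_consensus <- function(m, conserved = 0.95) {
  vapply(seq_len(ncol(m)), function(p) {
    col <- m[, p]
    top <- names(col)[order(-col, names(col))][1]
    if (col[top] >= conserved) top else tolower(top)
  }, "") |> paste(collapse = "")
}

#' Cluster the CDR3 sequences of one chain
#'
#' Convenience wrapper chaining [hamming_pairs()], [mcl_partition()] and
#' [build_clusters()].
#'
#' @inheritParams hamming_pairs
#' @inheritParams mcl_partition
#' @return A `tcr_clusters` tibble; the per-item assignment is attached as the
#'   `"assignment"` attribute and singleton ids as `"singletons"`.
#' @export
cluster_cdr3 <- function(items, inflation = 2, expansion = 2, max_iter = 100,
                         prune_tol = 1e-5, require_v = FALSE) {
  g <- hamming_pairs(items, require_v = require_v)
  part <- mcl_partition(g, inflation = inflation, expansion = expansion,
                        max_iter = max_iter, prune_tol = prune_tol)
  if (nrow(part) == 0) {
    out <- tibble(cluster_id = integer(), chain = character(), name = character(),
                  junction_length = integer(), n_members = integer(),
                  n_cells = integer(), consensus = character(),
                  motif = list(), members = list())
    class(out) <- c("tcr_clusters", class(out))
  } else {
    out <- build_clusters(part, items)
  }
  attr(out, "assignment") <- part
  attr(out, "singletons") <- attr(part, "singletons")
  out
}

#' Flatten clusters to a members table for export
#'
#' @param clusters A `tcr_clusters` tibble.
#' @return One row per member: cluster columns plus member V/J/CDR3 and
#'   multiplicity.
#' @export
cluster_members_table <- function(clusters) {
  clusters %>%
    select("cluster_id", "chain", "name", "junction_length", "consensus", "members") %>%
    tidyr::unnest("members")
}
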
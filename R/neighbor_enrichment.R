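#' Parameters of the weighted CDR3 mismatch distance
#'
#' Defaults follow the tcrdist-family convention under which 12.5 is a
#' meaningful neighbor radius: BLOSUM62 similarity, per-position substitution
#' cost `min(cap, cap - S)` capped at 4, gap cost 4 per length difference, and
#' a CDR3 weight of 3 scaling the total.
#'
#' @param substitution_matrix Symmetric integer similarity table over the
#'   amino-acid alphabet (default [blosum62()]).
#' @param mismatch_cap Substitution cost cap (default 4).
#' @param gap_cost Cost per gapped position (default 4).
#' @param cdr3_weight Multiplier applied to the summed cost (default 3).
#' @param radius Neighbor radius; pairs at distance `<= radius` are neighbors
#'   (default 12.5).
#' @return A `dist_params` list.
#' @export
dist_params <- function(substitution_matrix = blosum62(), mismatch_cap = 4L,
                        gap_cost = 4L, cdr3_weight = 3L, radius = 12.5) {
  if (!isTRUE(all.equal(substitution_matrix, t(substitution_matrix)))) {
    abort("substitution matrix must be symmetric")
  }
  if (radius <= 0) abort("radius must be positive")
  structure(list(substitution_matrix = substitution_matrix,
                 mismatch_cap = as.integer(mismatch_cap),
                 gap_cost = as.integer(gap_cost),
                 cdr3_weight = as.integer(cdr3_weight),
                 radius = radius),
            class = "dist_params")
}

#' Weighted mismatch distance between CDR3 sequences
#'
#' `cdr3_weight * [sum of per-position substitution costs + gap_cost * |len(a)
#' - len(b)|]`, where the shorter sequence is padded with a central gap block
#' (its first `ceiling(m/2)` residues align to the start of the longer, the
#' rest to the end) and the substitution cost is `min(cap, cap - S(x, y))` for
#' `x != y`, 0 otherwise. Symmetric, zero iff the sequences are identical; the
#' triangle inequality is not claimed.
#'
#' @param a,b Character vectors of CDR3 amino-acid sequences (recycled
#'   pairwise).
#' @param params A [dist_params()] object.
#' @return Numeric vector of distances.
#' @export
cdr3_distance <- function(a, b, params = dist_params()) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  cpp_cdr3_dist(a, b, params$substitution_matrix, paste(AA20, collapse = ""),
                params$mismatch_cap, params$gap_cost, params$cdr3_weight)
}

#' Count sequence neighbors of queries within a pool
#'
#' Number of pool entries at distance `<= params$radius` from each query.
#' When the pool is the query set itself (`same_set = TRUE`), each item is
#' excluded from its own count by identity (an identical sequence elsewhere in
#' the pool still counts). Pairs whose length difference alone exceeds the
#' radius are skipped without computing the distance.
#'
#' @param queries Character vector of query CDR3 sequences.
#' @param pool Character vector of pool CDR3 sequences.
#' @param params A [dist_params()] object.
#' @param same_set Pool positions correspond to query positions; exclude the
#'   diagonal.
#' @return Integer vector of neighbor counts.
#' @export
count_neighbors <- function(queries, pool, params = dist_params(), same_set = FALSE) {
  if (length(pool) == 0 || length(queries) == 0) {
    return(integer(length(queries)))
  }
  if (same_set && length(pool) != length(queries)) {
    abort("same_set requires pool and queries of identical length")
  }
  cpp_neighbor_counts(queries, pool, params$substitution_matrix,
                      paste(AA20, collapse = ""), params$mismatch_cap,
                      params$gap_cost, params$cdr3_weight, params$radius,
                      same_set)
}

#' Shuffled-junction background repertoire
#'
#' Builds a background of `fold` times the number of unique input clones by
#' shuffling junctions: two distinct clones A and B with equal CDR3 length L
#' are cut at a uniform position `c` in `[2, L - 2]` and recombined as
#' `A[1..c] + B[(c+1)..L]`, inheriting A's V gene and B's J gene. Candidates
#' identical to any input sequence are discarded. Candidates are generated
#' stratum by stratum so the joint (v_gene, length) distribution of the
#' background matches the input, and, when `pgen_fun` is supplied, resampled
#' so generation-probability decile proportions match as well.
#'
#' @param items Unique clone tibble (columns `v_gene`, `j_gene`, `cdr3_aa`),
#'   e.g. one element of [cluster_chain_split()]. At least 20 unique clones.
#' @param fold Background size as a multiple of the input (default 50).
#' @param seed Mandatory integer seed.
#' @param pgen_fun Optional `function(cdr3_aa)` returning generation
#'   probabilities, used to match pgen deciles (e.g. wrap
#'   [exact_pgen_small()] for synthetic data).
#' @return A `tcr_background` tibble (`v_gene`, `j_gene`, `cdr3_aa`) with a
#'   `"match_report"` attribute holding total-variation divergences between
#'   background and input marginals.
#' @export
shuffle_background <- function(items, fold = 50, seed, pgen_fun = NULL) {
  if (missing(seed)) abort("a seed is required for background construction")
  if (nrow(items) < 20) {
    abort(paste0("too few unique clones (", nrow(items), ") to stratify a ",
                 "background; pool chains or samples before calling"))
  }
  withr::local_seed(as.integer(seed))
  items <- distinct(items, .data$v_gene, .data$cdr3_aa, .keep_all = TRUE)
  items$len <- nchar(items$cdr3_aa)
  n_target <- fold * nrow(items)
  input_set <- unique(items$cdr3_aa)

  # per (v_gene, length) stratum targets by largest remainder
  strat <- items %>% count(.data$v_gene, .data$len) %>%
    mutate(exact = .data$n / sum(.data$n) * n_target,
           base = floor(.data$exact), frac = .data$exact - .data$base)
  short <- n_target - sum(strat$base)
  strat$target <- strat$base +
    as.integer(seq_len(nrow(strat)) %in% order(-strat$frac)[seq_len(short)])

  by_len <- split(items$cdr3_aa, items$len)
  out <- vector("list", nrow(strat))
  for (s in seq_len(nrow(strat))) {
    v <- strat$v_gene[s]; L <- strat$len[s]; want <- strat$target[s]
    if (want == 0) next
    a_pool <- items$cdr3_aa[items$v_gene == v & items$len == L]
    b_pool <- by_len[[as.character(L)]]
    j_pool <- items$j_gene[items$len == L]
    got <- character(0); got_j <- character(0)
    tries <- 0
    while (length(got) < want && tries < 60) {
      tries <- tries + 1
      m <- (want - length(got)) * 2L
      if (length(b_pool) >= 2 && tries <= 30) {
        A <- sample(a_pool, m, replace = TRUE)
        bi <- sample.int(length(b_pool), m, replace = TRUE)
        B <- b_pool[bi]
        bj <- j_pool[bi]
        cut <- sample(2:(L - 2), m, replace = TRUE)
        tail_part <- substr(B, cut + 1, L)
      } else {
        # no same-length partner (or the stratum is exhausted): take the
        # suffix of the needed length from any clone long enough
        A <- sample(a_pool, m, replace = TRUE)
        cut <- sample(2:(L - 2), m, replace = TRUE)
        bi <- sample.int(nrow(items), m, replace = TRUE)
        B <- items$cdr3_aa[bi]
        bj <- items$j_gene[bi]
        keep_len <- nchar(B) >= (L - cut)
        tail_part <- substr(B, nchar(B) - (L - cut) + 1, nchar(B))
        tail_part[!keep_len] <- NA
      }
      cand <- paste0(substr(A, 1, cut), tail_part)
      ok <- !is.na(tail_part) & cand != A & cand != B & !(cand %in% input_set)
      got <- c(got, cand[ok])[seq_len(min(want, length(got) + sum(ok)))]
      got_j <- c(got_j, bj[ok])[seq_along(got)]
    }
    if (length(got) < want && length(got) > 0) {
      # stratum dominated by one sequence family; top up by resampling
      idx <- sample.int(length(got), want, replace = TRUE)
      got <- got[idx]; got_j <- got_j[idx]
    }
    if (length(got) == 0) next
    out[[s]] <- tibble(v_gene = v, j_gene = got_j, cdr3_aa = got)
  }
  bg <- bind_rows(out)

  if (!is.null(pgen_fun)) {
    bg <- match_pgen_deciles(items, bg, pgen_fun)
  }

  report <- list(
    tv_v_gene = tv_distance(table_prop(items$v_gene), table_prop(bg$v_gene)),
    tv_length = tv_distance(table_prop(nchar(items$cdr3_aa)),
                            table_prop(nchar(bg$cdr3_aa))),
    pgen_matched = !is.null(pgen_fun),
    fold = fold, n_input = nrow(items), n_background = nrow(bg))
  if (!is.null(pgen_fun)) {
    report$tv_pgen_decile <- attr(bg, "tv_pgen_decile")
  }
  attr(bg, "match_report") <- report
  class(bg) <- c("tcr_background", class(bg))
  bg
}

table_prop <- function(x) {
  t <- table(x)
  setNames(as.numeric(t) / sum(t), names(t))
}

# total-variation distance between two named proportion vectors
tv_distance <- function(p, q) {
  keys <- union(names(p), names(q))
  p <- ifelse(keys %in% names(p), p[keys], 0)
  q <- ifelse(keys %in% names(q), q[keys], 0)
  0.5 * sum(abs(p - q))
}

# resample the background (with replacement within deciles) so its pgen
# decile proportions track the input's
match_pgen_deciles <- function(items, bg, pgen_fun) {
  pin <- pgen_fun(items$cdr3_aa)
  pbg <- pgen_fun(bg$cdr3_aa)
  pos <- pin > 0
  if (!any(pos)) return(bg)
  br <- unique(stats::quantile(log10(pin[pos]), probs = seq(0, 1, 0.1), names = FALSE))
  cutbin <- function(p) {
    b <- rep(0L, length(p))  # bin 0: unreachable under the model
    b[p > 0] <- findInterval(log10(p[p > 0]), br, rightmost.closed = TRUE,
                             all.inside = TRUE)
    b
  }
  bin_in <- cutbin(pin); bin_bg <- cutbin(pbg)
  target <- table_prop(bin_in)
  n_target <- nrow(bg)
  want <- round(target * n_target)
  idx <- unlist(lapply(names(want), function(b) {
    pool <- which(bin_bg == as.integer(b))
    if (length(pool) == 0) return(integer(0))
    sample(pool, want[[b]], replace = TRUE)
  }))
  if (length(idx) < n_target) {
    idx <- c(idx, sample(seq_len(nrow(bg)), n_target - length(idx), replace = TRUE))
  }
  out <- bg[idx[seq_len(n_target)], , drop = FALSE]
  attr(out, "tv_pgen_decile") <- tv_distance(target, table_prop(cutbin(pgen_fun(out$cdr3_aa))))
  out
}

#' Sequence-neighbor enrichment of each clone
#'
#' For clone i among `N` unique repertoire clones with a background of size
#' `M`: `k` is the number of neighbors (distance `<= radius`) among the other
#' `N - 1` repertoire clones, `K = k +` neighbors in the background, and the
#' enrichment p-value is the hypergeometric tail `P(X >= k)` for `X ~
#' Hypergeometric(N - 1 + M, K, N - 1)`. Bonferroni correction multiplies by
#' the number of clones tested; a clone is significant when the adjusted
#' p-value falls below `alpha`.
#'
#' @param items Unique clone tibble (`v_gene`, `j_gene`, `cdr3_aa`).
#' @param background A [shuffle_background()] result (or compatible tibble).
#' @param params A [dist_params()] object.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return A `tcr_enrichment` tibble: item columns plus `k_rep`, `k_bg`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
enrich_clones <- function(items, background, params = dist_params(), alpha = 0.05) {
  if (is.null(background) || nrow(background) == 0) {
    abort("background is empty; build one with shuffle_background()")
  }
  items <- distinct(items, .data$v_gene, .data$cdr3_aa, .keep_all = TRUE)
  N <- nrow(items)
  M <- nrow(background)
  k_rep <- count_neighbors(items$cdr3_aa, items$cdr3_aa, params, same_set = TRUE)
  k_bg <- count_neighbors(items$cdr3_aa, background$cdr3_aa, params)
  K <- k_rep + k_bg
  p_raw <- phyper(k_rep - 1, K, (N - 1 + M) - K, N - 1, lower.tail = FALSE)
  p_adj <- pmin(1, p_raw * N)
  out <- items %>%
    mutate(k_rep = k_rep, k_bg = k_bg, p_raw = p_raw, p_adj = p_adj,
           significant = .data$p_adj < alpha)
  attr(out, "params") <- list(radius = params$radius, alpha = alpha,
                              n_clones = N, n_background = M)
  class(out) <- c("tcr_enrichment", class(out))
  out
}
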
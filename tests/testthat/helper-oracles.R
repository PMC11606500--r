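# Independent oracles used across the suite. Everything here is written
# against the definitions, not against the package's code paths.

# brute-force Hamming<=1 edge set: full O(n^2) scan (row-against-rest
# mismatch counting, no hashing) within equal-length, equal-locus groups
oracle_hamming_edges <- function(items) {
  n <- nrow(items)
  locus <- if ("locus" %in% names(items)) items$locus else rep("", n)
  grp <- paste(locus, nchar(items$cdr3_aa))
  res <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    m <- length(idx)
    if (m < 2) next
    chars <- do.call(rbind, strsplit(items$cdr3_aa[idx], "", fixed = TRUE))
    for (a in seq_len(m - 1)) {
      rest <- (a + 1):m
      mism <- rowSums(chars[rest, , drop = FALSE] !=
                        matrix(chars[a, ], nrow = length(rest),
                               ncol = ncol(chars), byrow = TRUE))
      hit <- rest[mism <= 1]
      if (length(hit) > 0) {
        res[[length(res) + 1]] <- cbind(idx[a], idx[hit])
      }
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(from = integer(), to = integer()))
  }
  m <- do.call(rbind, res)
  tibble::tibble(from = pmin(m[, 1], m[, 2]), to = pmax(m[, 1], m[, 2])) |>
    dplyr::arrange(from, to)
}

# reference MCL on a dense matrix, written independently with plain loops
oracle_mcl <- function(edges, n, inflation = 2, expansion = 2,
                       max_iter = 100, prune_tol = 1e-5) {
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    A[edges$from[r], edges$to[r]] <- 1
    A[edges$to[r], edges$from[r]] <- 1
  }
  diag(A) <- 1
  normalize <- function(M) sweep(M, 2, pmax(colSums(M), .Machine$double.eps), "/")
  M <- normalize(A)
  for (it in seq_len(max_iter)) {
    Mp <- M
    for (k in seq_len(expansion - 1)) Mp <- Mp %*% M
    Mp <- Mp^inflation
    Mp[Mp < prune_tol] <- 0
    Mp <- normalize(Mp)
    if (max(abs(Mp - M)) < 1e-8) { M <- Mp; break }
    M <- Mp
  }
  att <- apply(M, 2, which.max)
  match(att, sort(unique(att)))
}

# direct R re-implementation of the weighted CDR3 distance definition
oracle_cdr3_distance <- function(a, b, S = tcrfirst::blosum62(),
                                 cap = 4, gap = 4, w = 3) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  m <- nchar(a); n <- nchar(b)
  front <- ceiling(m / 2); back <- m - front
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  cost <- 0
  for (i in seq_len(front)) {
    if (ca[i] != cb[i]) cost <- cost + min(cap, cap - S[ca[i], cb[i]])
  }
  for (i in seq_len(back)) {
    x <- ca[m - i + 1]; y <- cb[n - i + 1]
    if (x != y) cost <- cost + min(cap, cap - S[x, y])
  }
  w * (cost + gap * (n - m))
}

# hypergeometric upper-tail by direct pmf summation
oracle_hyper_tail <- function(k, K, M_pop, n_draw) {
  if (k <= 0) return(1)
  sum(sapply(k:min(K, n_draw), function(x) {
    choose(K, x) * choose(M_pop - K, n_draw - x) / choose(M_pop, n_draw)
  }))
}

# total-variation distance between two samples' empirical distributions
oracle_tv <- function(x, y) {
  keys <- union(unique(x), unique(y))
  px <- sapply(keys, function(k) mean(x == k))
  py <- sapply(keys, function(k) mean(y == k))
  0.5 * sum(abs(px - py))
}

# random CDR3 sequences over the amino-acid alphabet
random_cdr3 <- function(n, len_range = c(10, 16)) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","W","Y","V")
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  vapply(lens, function(L) paste(sample(aa, L, replace = TRUE), collapse = ""), "")
}
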
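# Miniature recombination models and small in-code fixtures.

# one V, one J, no trimming, no insertion: emits exactly one junction
degenerate_model <- function() {
  tcrfirst::recomb_model(
    v_segments = data.frame(name = "TRBV20-1", frequency = 1, prefix = "CASS"),
    j_segments = data.frame(name = "TRBJ2-7", frequency = 1, suffix = "EQYF"),
    insert_length_dist = 1,
    insert_residue_dist = stats::setNames(rep(1 / 20, 20),
      c("A","C","D","E","F","G","H","I","K","L",
        "M","N","P","Q","R","S","T","W","Y","V")),
    trim_dist = 1)
}

# two V, two J, inserts of length 0 or 1, one trim level: small enough to
# enumerate every reachable sequence
miniature_model <- function() {
  tcrfirst::recomb_model(
    v_segments = data.frame(name = c("Vx", "Vy"), frequency = c(0.7, 0.3),
                            prefix = c("CASS", "CASR")),
    j_segments = data.frame(name = c("Jx", "Jy"), frequency = c(0.6, 0.4),
                            suffix = c("EQYF", "QHF")),
    insert_length_dist = c(0.5, 0.5),
    insert_residue_dist = stats::setNames(rep(1 / 20, 20),
      c("A","C","D","E","F","G","H","I","K","L",
        "M","N","P","Q","R","S","T","W","Y","V")),
    trim_dist = c(0.8, 0.2))
}

# every junction reachable by miniature_model(), by direct construction
enumerate_miniature <- function(model = miniature_model()) {
  aa <- names(model$insert_residue_dist)
  out <- character(0)
  for (vi in seq_len(nrow(model$v_segments))) {
    for (tv in 0:(length(model$trim_dist) - 1)) {
      pre <- model$v_segments$prefix[vi]
      if (tv >= nchar(pre)) next
      pre <- substr(pre, 1, nchar(pre) - tv)
      for (ji in seq_len(nrow(model$j_segments))) {
        for (tj in 0:(length(model$trim_dist) - 1)) {
          suf <- model$j_segments$suffix[ji]
          if (tj >= nchar(suf)) next
          suf <- substr(suf, tj + 1, nchar(suf))
          out <- c(out, paste0(pre, suf), paste0(pre, aa, suf))
        }
      }
    }
  }
  unique(out[nchar(out) >= 5])
}

# a small contig tibble covering both chains of a handful of cells
toy_contigs <- function() {
  tibble::tibble(
    barcode = c("BC1-1", "BC1-1", "BC2-1", "BC2-1", "BC2-1", "BC3-1"),
    locus = c("TRA", "TRB", "TRA", "TRA", "TRB", "TRB"),
    v_gene = c("TRAV1-2", "TRBV6-5", "TRAV8-3", "TRAV8-3", "TRBV20-1", "TRBV19"),
    j_gene = c("TRAJ33", "TRBJ1-5", "TRAJ17", "TRAJ17", "TRBJ2-7", "TRBJ2-1"),
    cdr3_aa = c("CAVMDSNYQLIW", "CASRRTGRNQPQHF", "CAVGASKAAGNKLTF",
                "CAVGGSKAAGNKLTF", "CSARDWGEQYF", "CASSIRTNEQFF"),
    cdr3_nt = NA_character_,
    umis = c(4L, 6L, 7L, 2L, 5L, 3L),
    productive = TRUE)
}

# synthetic cells-by-genes matrix with planted per-cell stats for QC tests
qc_fixture <- function(seed = 99, n_cells = 100, n_genes = 300) {
  withr::with_seed(seed, {
    genes <- c(paste0("MT-", 1:10), sprintf("G%04d", seq_len(n_genes - 10)))
    m <- matrix(stats::rpois(n_cells * n_genes, 0.8), nrow = n_cells,
                dimnames = list(sprintf("C%03d-1", seq_len(n_cells)), genes))
    # spike mito counts in a third of the cells
    hot <- sample(n_cells, n_cells %/% 3)
    m[hot, 1:10] <- m[hot, 1:10] + stats::rpois(length(hot) * 10, 20)
    methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  })
}
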
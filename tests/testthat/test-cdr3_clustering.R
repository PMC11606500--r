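test_that("wildcard hashing finds exactly the brute-force Hamming pairs", {
  items <- tibble::tibble(item_id = 1:3, locus = "TRB", v_gene = "TRBV9",
                          j_gene = "TRBJ1-1",
                          cdr3_aa = c("CASSF", "CASSY", "CASTT"),
                          multiplicity = 1L)
  g <- hamming_pairs(items)
  expect_equal(as.data.frame(g$edges), data.frame(from = 1L, to = 2L))

  # unequal lengths can never be Hamming-1
  pair <- tibble::tibble(item_id = 1:2, locus = "TRA", v_gene = "V",
                         j_gene = "J",
                         cdr3_aa = c("CAVGASKAAGNKLTF", "CASRRTGRNQPQHF"),
                         multiplicity = 1L)
  expect_equal(nrow(hamming_pairs(pair)$edges), 0)

  # random instances against the all-pairs oracle
  withr::with_seed(11, {
    for (rep in 1:3) {
      n <- 250
      it <- tibble::tibble(item_id = seq_len(n), locus = "TRB", v_gene = "V",
                           j_gene = "J",
                           cdr3_aa = random_cdr3(n, c(6, 9)),
                           multiplicity = 1L) |>
        dplyr::distinct(cdr3_aa, .keep_all = TRUE)
      it$item_id <- seq_len(nrow(it))
      got <- hamming_pairs(it)$edges
      want <- oracle_hamming_edges(it)
      expect_equal(as.data.frame(got), as.data.frame(want))
    }
  })
})

test_that("identical CDR3s under different V genes are distinct connected nodes", {
  items <- tibble::tibble(item_id = 1:2, locus = "TRB",
                          v_gene = c("TRBV9", "TRBV19"), j_gene = "J",
                          cdr3_aa = "CASSLGETQYF", multiplicity = 1L)
  g <- hamming_pairs(items)
  expect_equal(nrow(g$edges), 1)
  g_strict <- hamming_pairs(items, require_v = TRUE)
  expect_equal(nrow(g_strict$edges), 0)
})

test_that("edges never cross chain classes", {
  items <- tibble::tibble(item_id = 1:2, locus = c("TRA", "TRG"),
                          v_gene = "V", j_gene = "J",
                          cdr3_aa = "CAVMDSNYQLIW", multiplicity = 1L)
  expect_equal(nrow(hamming_pairs(items)$edges), 0)
})

test_that("Markov clustering recovers components and splits bridged cliques", {
  # two disjoint triangles -> exactly the two components
  edges <- tibble::tibble(from = c(1L, 1L, 2L, 4L, 4L, 5L),
                          to = c(2L, 3L, 3L, 5L, 6L, 6L))
  part <- mcl_partition(edges, n_nodes = 6)
  expect_equal(dplyr::n_distinct(part$cluster), 2)
  expect_setequal(part$item_id[part$cluster == part$cluster[1]], 1:3)

  # empty graph -> empty partition
  empty <- mcl_partition(tibble::tibble(from = integer(), to = integer()),
                         n_nodes = 4)
  expect_equal(nrow(empty), 0)
  expect_setequal(attr(empty, "singletons"), 1:4)

  # two 5-cliques joined by one bridge split at the bridge, and the result
  # matches the independently written dense reference MCL
  cl5 <- function(off) {
    idx <- t(utils::combn(5, 2)) + off
    tibble::tibble(from = as.integer(idx[, 1]), to = as.integer(idx[, 2]))
  }
  bridged <- dplyr::bind_rows(cl5(0), cl5(5), tibble::tibble(from = 5L, to = 6L))
  part2 <- mcl_partition(bridged, n_nodes = 10, inflation = 2)
  expect_equal(dplyr::n_distinct(part2$cluster), 2)
  expect_setequal(part2$item_id[part2$cluster == part2$cluster[1]], 1:5)
  ref <- oracle_mcl(bridged, 10, inflation = 2)
  got_lab <- integer(10); got_lab[part2$item_id] <- part2$cluster
  expect_equal(mclust::adjustedRandIndex(got_lab, ref), 1)
})

test_that("MCL rejects duplicated edge orientations and self-edges", {
  expect_error(mcl_partition(tibble::tibble(from = c(1L, 2L), to = c(2L, 1L)),
                             n_nodes = 2), "orientation")
  expect_error(mcl_partition(tibble::tibble(from = 1L, to = 1L), n_nodes = 2),
               "self-edges")
})

test_that("MCL clusters never span graph components", {
  skip_if_not_installed("igraph")
  withr::with_seed(21, {
    for (rep in 1:5) {
      n <- 60
      m <- 50
      edges <- tibble::tibble(from = sample.int(n, m, replace = TRUE),
                              to = sample.int(n, m, replace = TRUE)) |>
        dplyr::filter(from != to) |>
        dplyr::mutate(a = pmin(from, to), b = pmax(from, to)) |>
        dplyr::distinct(a, b) |>
        dplyr::transmute(from = a, to = b)
      part <- mcl_partition(edges, n_nodes = n)
      g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
      g <- igraph::add_vertices(g, n - igraph::vcount(g))
      comp <- igraph::components(g)$membership
      spans <- tapply(comp[part$item_id], part$cluster,
                      function(x) length(unique(x)))
      expect_true(all(spans == 1))
    }
  })
})

test_that("cluster summaries report motif frequencies, consensus and modal names", {
  items <- tibble::tibble(item_id = 1:2, locus = "TRB",
                          v_gene = c("TRBV6-5", "TRBV6-5"),
                          j_gene = c("TRBJ1-1", "TRBJ1-1"),
                          cdr3_aa = c("CASSF", "CASSY"),
                          multiplicity = c(3L, 1L))
  part <- tibble::tibble(item_id = 1:2, cluster = 1L)
  cl <- build_clusters(part, items)
  m <- cl$motif[[1]]
  # hand-computed: position 5 sees F three times, Y once
  expect_equal(unname(m["F", 5]), 0.75)
  expect_equal(unname(m["Y", 5]), 0.25)
  expect_equal(unname(colSums(m)), rep(1, 5), tolerance = 1e-12)
  expect_equal(cl$consensus, "CASSf")
  expect_equal(cl$name, "TRBV6-5 TRBJ1-1")
  expect_equal(cl$n_cells, 4L)

  # modal naming weighted by multiplicity, e.g. an all TRAV1-2/TRAJ33 cluster
  mait <- tibble::tibble(item_id = 1:2, locus = "TRA", v_gene = "TRAV1-2",
                         j_gene = "TRAJ33",
                         cdr3_aa = c("CAVMDSNYQLIW", "CAVMDSNYQLIF"),
                         multiplicity = c(5L, 2L))
  expect_equal(build_clusters(part, mait)$name, "TRAV1-2 TRAJ33")

  expect_error(build_clusters(tibble::tibble(item_id = 1L, cluster = 1L),
                              items[1, ]), "singleton")
})

test_that("chain splitting deduplicates per chain with multiplicities", {
  rep <- tibble::tibble(
    barcode = c("B1", "B2", "B3"), sample_id = "S1",
    locus_ag = c("TRA", "TRA", "TRG"),
    v_ag = c("TRAV1-2", "TRAV1-2", "TRGV4"),
    j_ag = c("TRAJ33", "TRAJ33", "TRGJ2"),
    cdr3_ag = c("CAVMDSNYQLIW", "CAVMDSNYQLIW", "CATWDGPYYKKLF"),
    locus_bd = c("TRB", "TRB", "TRD"),
    v_bd = c("TRBV6-5", "TRBV19", "TRDV1"),
    j_bd = c("TRBJ1-5", "TRBJ2-1", "TRDJ1"),
    cdr3_bd = c("CASRRTGRNQPQHF", "CASSIRTNEQFF", "CALGELGDTPFF"),
    clone_key = "x", dual_lineage = FALSE)
  split <- cluster_chain_split(rep)
  expect_equal(nrow(split$A), 1)            # two cells share one TRA item
  expect_equal(split$A$multiplicity, 2L)
  expect_equal(nrow(split$B), 2)
  expect_equal(nrow(split$G), 1)
  expect_equal(nrow(split$D), 1)
})

test_that("planted cliques are recovered as single clusters", {
  rep <- simulate_repertoire(150, seed = 5, planted_sizes = c(6, 9))
  items <- cluster_chain_split(rep)$B
  cl <- cluster_cdr3(items)
  truth <- attr(rep, "clones") |> dplyr::filter(!is.na(planted_cluster))
  asg <- attr(cl, "assignment")
  joined <- items |>
    dplyr::left_join(asg, by = "item_id") |>
    dplyr::inner_join(truth, by = c(cdr3_aa = "cdr3_bd", v_gene = "v_bd"))
  expect_equal(nrow(joined), 15)
  # every planted member assigned, and members of one planted cluster agree
  expect_false(any(is.na(joined$cluster)))
  agree <- tapply(joined$cluster, joined$planted_cluster,
                  function(x) length(unique(x)))
  expect_true(all(agree == 1))
})
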
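clonotype_row <- function(v_ag = NA, j_ag = NA, v_bd = NA, j_bd = NA,
                          locus_ag = "TRA", locus_bd = "TRB") {
  tibble::tibble(v_ag = v_ag, j_ag = j_ag, v_bd = v_bd, j_bd = j_bd,
                 locus_ag = locus_ag, locus_bd = locus_bd)
}

test_that("TCR rules label MAIT, gamma-delta, CD1b/c candidates and the rest", {
  rows <- dplyr::bind_rows(
    clonotype_row("TRAV1-2", "TRAJ33", "TRBV19", "TRBJ2-1"),
    clonotype_row("TRAV1-2", "TRAJ20", "TRBV19", "TRBJ2-1"),
    clonotype_row("TRAV1-2", "TRAJ45", "TRBV19", "TRBJ2-1"),   # wrong J
    clonotype_row("TRAV13-2", "TRAJ45", "TRBV4-1", "TRBJ2-1"),
    clonotype_row("TRAV8-3", "TRAJ17", "TRBV6-5", "TRBJ1-5"),
    clonotype_row("TRGV4", "TRGJ2", "TRDV1", "TRDJ1",
                  locus_ag = "TRG", locus_bd = "TRD"))
  got <- classify_by_tcr(rows)$tcr_label
  expect_equal(got, c("MAIT", "MAIT", "alpha_beta", "CD1bc_candidate",
                      "alpha_beta", "gamma_delta"))
})

test_that("rule classification is total and stable under reordering disjoint rules", {
  rep <- simulate_repertoire(100, seed = 12)
  lab1 <- classify_by_tcr(rep)$tcr_label
  expect_false(any(is.na(lab1)))
  rules <- default_tcr_rules()
  # MAIT and CD1bc conditions are disjoint (different AG V genes): swapping
  # their priorities must not change any label
  swapped <- rules
  swapped$priority <- c(3L, 2L, 1L)
  lab2 <- classify_by_tcr(rep, rules = swapped)$tcr_label
  expect_equal(lab1, lab2)
})

test_that("TCR-rule MAIT calls have perfect precision and recall by construction", {
  rep <- simulate_repertoire(300, seed = 13)
  # force a known subset into the MAIT arrangement
  idx <- seq(1, nrow(rep), by = 7)
  rep$v_ag[idx] <- "TRAV1-2"
  rep$j_ag[idx] <- sample(c("TRAJ33", "TRAJ20", "TRAJ12"), length(idx),
                          replace = TRUE)
  # make sure no other cell satisfies the rule accidentally
  other <- setdiff(seq_len(nrow(rep)), idx)
  other_mait <- rep$v_ag[other] == "TRAV1-2" &
    rep$j_ag[other] %in% c("TRAJ33", "TRAJ20", "TRAJ12")
  rep$j_ag[other][other_mait] <- "TRAJ45"
  got <- classify_by_tcr(rep)$tcr_label == "MAIT"
  truth <- seq_len(nrow(rep)) %in% idx
  expect_equal(got, truth)  # precision = recall = 1
})

test_that("the rank signature score matches its closed form at the extremes", {
  r_max <- 50
  counts <- setNames(c(100, 90, 80, seq(70, 1, length.out = 57)),
                     c("A1", "A2", "A3", sprintf("F%02d", 1:57)))
  # signature at ranks 1..3
  expect_equal(signature_score(counts, c("A1", "A2", "A3"), r_max = r_max), 1)
  # all-zero signature genes share the maximal average ranks
  counts2 <- setNames(c(seq(60, 1), rep(0, 10)),
                      c(sprintf("F%02d", 1:60), sprintf("Z%02d", 1:10)))
  n <- 5
  got <- signature_score(counts2, sprintf("Z%02d", 1:n), r_max = r_max)
  expect_equal(got, (n - 1) / (2 * r_max), tolerance = 1e-12)
})

test_that("the signature score is rank-based and centered near 0.5 under the null", {
  withr::with_seed(14, {
    n_genes <- 1000
    counts <- setNames(sample(seq_len(n_genes)), sprintf("G%04d", seq_len(n_genes)))
    sig <- sample(names(counts), 10)
    s1 <- signature_score(counts, sig, r_max = n_genes)
    expect_equal(s1, signature_score(sqrt(counts), sig, r_max = n_genes))
    expect_equal(s1, signature_score(counts * 100, sig, r_max = n_genes))

    draws <- replicate(500, {
      x <- setNames(sample(seq_len(n_genes)), names(counts))
      signature_score(x, sig, r_max = n_genes)
    })
    se <- stats::sd(draws) / sqrt(length(draws))
    # exchangeable ranks put the expected score at 1/2 up to the small
    # finite-list offset n/(2N)
    expect_lte(abs(mean(draws) - 0.5), 3 * se + 10 / (2 * n_genes) + 0.005)
  })
  expect_error(signature_score(setNames(1:3, c("A", "B", "C")), "ZZZ"),
               "no signature gene")
})

example_tree <- function() {
  gating_node("T_cell",
    positive = list(c("CD8A", "CD8B"), c("CD4", "IL7R")),
    children = list(
      gating_node("CD8_T", positive = list(c("CD8A", "CD8B"))),
      gating_node("CD4_T", positive = list(c("CD4", "IL7R")))))
}

test_that("gating recovers planted phenotypes and respects gate semantics", {
  sigs <- list(CD8_T = c("CD8A", "CD8B"), CD4_T = c("CD4", "IL7R"))
  ph <- rep(c("CD8_T", "CD4_T"), each = 60)
  gex <- simulate_counts(ph, sigs, n_genes = 300, effect = 8, seed = 15)
  labels <- gate_cells(gex, example_tree(), r_max = 300)
  acc <- mean(labels$gex_label == attr(gex, "truth"))
  expect_gte(acc, 0.95)

  # a cell failing the root gate is non-T regardless of children
  strict <- example_tree()
  strict$tau_pos <- 1.1
  all_non_t <- gate_cells(gex, strict, r_max = 300)
  expect_true(all(all_non_t$gex_label == "non-T/unknown"))

  # tau_pos = 0 passes every positive gate
  lab0 <- gate_cells(gex, example_tree(), tau_pos = 0, r_max = 300)
  expect_false(any(lab0$gex_label %in% c("non-T/unknown", "T_cell")))
})

test_that("negative signatures veto a gate", {
  sigs <- list(CD8_T = c("CD8A", "CD8B", "GZMB", "NKG7"),
               CD4_T = c("CD4", "IL7R", "CD40LG", "CCR4"))
  ph <- rep(c("CD8_T", "CD4_T"), each = 30)
  gex <- simulate_counts(ph, sigs, n_genes = 300, nb_mean = 3, effect = 8,
                         seed = 16)
  tree <- gating_node("T_cell",
    positive = list(sigs$CD8_T, sigs$CD4_T),
    children = list(
      gating_node("CD8_T", positive = list(sigs$CD8_T),
                  negative = list(sigs$CD4_T)),
      gating_node("CD4_T", positive = list(sigs$CD4_T),
                  negative = list(sigs$CD8_T))))
  # in this dense fixture a non-elevated signature scores near 0.5, so the
  # veto threshold sits between the null (~0.5) and elevated (~1) scores
  labels <- gate_cells(gex, tree, tau_neg = 0.85, r_max = 300)
  acc <- mean(labels$gex_label == attr(gex, "truth"))
  expect_gte(acc, 0.95)
  # a veto below every realizable score blocks all cells at the children
  vetoed <- gate_cells(gex, tree, tau_neg = 0.01, r_max = 300)
  expect_true(all(vetoed$gex_label == "T_cell"))
})

test_that("gating results do not depend on the batch size", {
  sigs <- list(CD8_T = c("CD8A", "CD8B"), CD4_T = c("CD4", "IL7R"))
  ph <- rep(c("CD8_T", "CD4_T"), 25)
  gex <- simulate_counts(ph, sigs, n_genes = 200, effect = 8, seed = 17)
  full <- gate_cells(gex, example_tree(), r_max = 200)
  chunked <- gate_cells(gex, example_tree(), r_max = 200, batch_size = 7)
  expect_equal(as.data.frame(full), as.data.frame(chunked))
})

test_that("the shipped YAML gating tree parses into a well-formed tree", {
  path <- system.file("extdata", "gating_tree.yaml", package = "tcrfirst")
  tree <- read_gating_tree(path)
  expect_s3_class(tree, "gating_node")
  expect_equal(tree$name, "T_cell")
  kids <- vapply(tree$children, function(x) x$name, "")
  expect_true(all(c("CD4_T", "CD8_T") %in% kids))
})

test_that("external epitope annotations join above the score threshold only", {
  rep <- simulate_repertoire(50, seed = 18)
  keys <- unique(rep$clone_key)[1:3]
  tab <- tibble::tibble(clone_key = keys,
                        epitope = c("GILGFVFTL", "NLVPMVATV", "GLCTLVAML"),
                        score = c(0.5, 0.1, 0.25))
  out <- join_external_epitopes(rep, tab)
  expect_equal(attr(out, "dropped_low_score"), 1L)
  got <- out |>
    dplyr::distinct(clone_key, epitope) |>
    dplyr::filter(!is.na(epitope))
  expect_setequal(got$clone_key, keys[c(1, 3)])

  # empty table leaves the repertoire unchanged
  empty <- join_external_epitopes(rep, tab[0, ])
  expect_equal(nrow(empty), nrow(rep))
  expect_true(all(is.na(empty$epitope)))

  expect_error(join_external_epitopes(rep, tibble::tibble(foo = 1)),
               class = "tcrfirst_format_error")
})
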
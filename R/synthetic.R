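#' Simulate a paired-chain repertoire with optional planted clusters
#'
#' Draws `n_clones` unique paired clonotypes (an alpha/gamma chain from
#' `model_ag`, a beta/delta chain from `model_bd`), optionally injects planted
#' sequence clusters, expands clones into cells by a geometric clone-size
#' distribution, and distributes cells over samples.
#'
#' A planted cluster is a model-drawn seed CDR3 (on the BD chain) plus
#' `size - 1` variants. With `max_mutations = 1` every variant substitutes a
#' distinct residue at a single cluster-specific interior "hotspot" position,
#' so planted members are pairwise Hamming-1 (a clique in the similarity
#' graph) and mutual sequence neighbors under the weighted CDR3 distance —
#' the convergent, antigen-selected neighborhoods the enrichment statistic is
#' built to detect. With larger `max_mutations`, positions are drawn from a
#' hotspot set of that size.
#'
#' Treatment response: when `samples` has a `condition` column with values
#' `"pre"`/`"post"`, `n_responders` clones double-dip — their sampling weight
#' is multiplied by `response_fold` in `"post"` samples (fold > 1 expands,
#' fold < 1 contracts).
#'
#' @param n_clones Number of background clones.
#' @param seed Mandatory integer seed.
#' @param model_bd,model_ag Recombination models for the two chains.
#' @param planted_sizes Integer vector; one planted cluster per entry
#'   (sizes >= 2).
#' @param max_mutations Hotspot-set size for planted variants (default 1).
#' @param clone_size_prob Geometric success probability; cells per clone
#'   `~ 1 + Geom(prob)` (default 0.5, mean 2 cells).
#' @param samples Tibble with `sample_id`, optional `condition` and
#'   `n_cells`. Default: one sample, geometric expansion.
#' @param n_responders,response_fold Treatment-responsive clones (see above).
#' @return A `tcr_repertoire` tibble (one row per cell) with attributes
#'   `clones` (truth table: `clone_id`, chains, `path_prob_bd`,
#'   `planted_cluster`, `responder`), `samples`, and the models.
#' @export
simulate_repertoire <- function(n_clones, seed,
                                model_bd = toy_trb_model(),
                                model_ag = toy_tra_model(),
                                planted_sizes = integer(),
                                max_mutations = 1,
                                clone_size_prob = 0.5,
                                samples = NULL,
                                n_responders = 0,
                                response_fold = 4) {
  if (missing(seed)) abort("simulate_repertoire() requires a seed")
  stopifnot(all(planted_sizes >= 2))
  withr::local_seed(as.integer(seed))

  draw_unique <- function(model, n, taken = character()) {
    out <- vector("list", n)
    seen <- new.env(parent = emptyenv())
    for (t in taken) assign(t, TRUE, envir = seen)
    i <- 0
    while (i < n) {
      g <- generate_junction(model)
      key <- paste0(g$v_name, "_", g$cdr3_aa)
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      i <- i + 1
      out[[i]] <- g
    }
    out
  }

  bd <- draw_unique(model_bd, n_clones)
  clones <- tibble(
    clone_id = seq_len(n_clones),
    locus_bd = "TRB",
    v_bd = map_chr(bd, "v_name"), j_bd = map_chr(bd, "j_name"),
    cdr3_bd = map_chr(bd, "cdr3_aa"),
    path_prob_bd = map_dbl(bd, "path_probability"),
    planted_cluster = NA_integer_)

  # planted clusters on the BD chain
  if (length(planted_sizes) > 0) {
    taken <- paste0(clones$v_bd, "_", clones$cdr3_bd)
    planted <- vector("list", length(planted_sizes))
    for (ci in seq_along(planted_sizes)) {
      size <- planted_sizes[ci]
      repeat {
        g <- generate_junction(model_bd, min_len = 12)
        if (!(paste0(g$v_name, "_", g$cdr3_aa) %in% taken)) break
      }
      # hotspot positions sit strictly between the germline-templated ends
      # (V prefixes / J suffixes span <= 5-6 residues in the toy models), so
      # a variant cannot collide with a high-frequency germline family
      L <- nchar(g$cdr3_aa)
      pool <- seq(6, L - 6)
      hotspots <- pool[sample.int(length(pool), min(max_mutations, length(pool)))]
      variants <- character(0)
      guard <- 0
      while (length(variants) < size - 1 && guard < 500) {
        guard <- guard + 1
        v <- g$cdr3_aa
        n_pos <- sample.int(length(hotspots), 1)
        pos_set <- hotspots[sample.int(length(hotspots), n_pos)]
        for (pos in pos_set) {
          repl <- sample(setdiff(AA20, substr(v, pos, pos)), 1)
          substr(v, pos, pos) <- repl
        }
        key <- paste0(g$v_name, "_", v)
        if (v != g$cdr3_aa && !(key %in% taken) &&
            !(v %in% variants)) {
          variants <- c(variants, v)
          taken <- c(taken, key)
        }
      }
      if (length(variants) < size - 1) {
        abort("could not construct a planted cluster without collisions")
      }
      taken <- c(taken, paste0(g$v_name, "_", g$cdr3_aa))
      planted[[ci]] <- tibble(
        locus_bd = "TRB", v_bd = g$v_name, j_bd = g$j_name,
        cdr3_bd = c(g$cdr3_aa, variants),
        path_prob_bd = NA_real_, planted_cluster = ci)
    }
    planted <- bind_rows(planted) %>%
      mutate(clone_id = n_clones + row_number())
    clones <- bind_rows(clones, planted)
  }

  ag <- draw_unique(model_ag, nrow(clones))
  clones <- clones %>%
    mutate(locus_ag = "TRA",
           v_ag = map_chr(ag, "v_name"), j_ag = map_chr(ag, "j_name"),
           cdr3_ag = map_chr(ag, "cdr3_aa"),
           clone_key = clone_key(.data$v_ag, .data$j_ag, .data$cdr3_ag,
                                 .data$v_bd, .data$j_bd, .data$cdr3_bd))

  n_total <- nrow(clones)
  clones$responder <- FALSE
  if (n_responders > 0) {
    clones$responder[sample.int(n_total, min(n_responders, n_total))] <- TRUE
  }

  if (is.null(samples)) {
    samples <- tibble(sample_id = "S1", condition = "baseline")
  }
  samples <- as_tibble(samples)
  if (!"condition" %in% names(samples)) samples$condition <- "baseline"

  base_size <- 1L + rgeom(n_total, clone_size_prob)
  cells <- vector("list", nrow(samples))
  for (si in seq_len(nrow(samples))) {
    w <- as.numeric(base_size)
    if (samples$condition[si] == "post") {
      w[clones$responder] <- w[clones$responder] * response_fold
    }
    if ("n_cells" %in% names(samples) && !is.na(samples$n_cells[si])) {
      # fixed sequencing depth: cells drawn multinomially by clone weight
      counts <- stats::rmultinom(1, samples$n_cells[si], w / sum(w))[, 1]
    } else {
      # unconstrained depth: every clone contributes its drawn size, so no
      # clone (in particular no planted member) is lost to sampling
      counts <- as.integer(round(w))
    }
    idx <- rep(seq_len(n_total), counts)
    cells[[si]] <- clones[idx, ] %>%
      mutate(sample_id = samples$sample_id[si])
  }
  rep <- bind_rows(cells) %>%
    mutate(barcode = sprintf("CELL%06d-1", row_number()),
           umis_ag = 1L + rpois(dplyr::n(), 2),
           umis_bd = 1L + rpois(dplyr::n(), 3)) %>%
    select("barcode", "sample_id", "clone_id", "locus_ag", "v_ag", "j_ag",
           "cdr3_ag", "locus_bd", "v_bd", "j_bd", "cdr3_bd", "clone_key",
           "umis_ag", "umis_bd")
  attr(rep, "clones") <- clones
  attr(rep, "samples") <- samples
  attr(rep, "model_bd") <- model_bd
  attr(rep, "model_ag") <- model_ag
  class(rep) <- c("tcr_repertoire", class(rep))
  rep
}

#' Simulate a phenotype-structured expression count matrix
#'
#' Negative-binomial baseline counts; the marker genes of a cell's phenotype
#' have their mean multiplied by `effect`. `effect = 1` makes markers
#' statistically indistinguishable from the rest (the null used by the gating
#' calibration tests).
#'
#' @param phenotypes Character vector of per-cell phenotype labels, optionally
#'   named by barcode.
#' @param signatures Named list mapping each phenotype to its marker gene
#'   set. Overlapping marker sets are allowed (with a warning).
#' @param n_genes Total genes, signature genes included (filler genes are
#'   named `GENE0001`, ...).
#' @param nb_mean Baseline negative-binomial mean (default 2).
#' @param nb_dispersion NB size/dispersion parameter (default 2).
#' @param effect Fold increase applied to a cell's own phenotype markers
#'   (default 8).
#' @param seed Mandatory integer seed.
#' @return A sparse cells-by-genes `dgCMatrix`; phenotype truth labels in the
#'   `"truth"` attribute.
#' @export
simulate_counts <- function(phenotypes, signatures, n_genes = 500,
                            nb_mean = 2, nb_dispersion = 2, effect = 8, seed) {
  if (missing(seed)) abort("simulate_counts() requires a seed")
  withr::local_seed(as.integer(seed))
  stopifnot(all(phenotypes %in% names(signatures) | phenotypes == "other"))
  marker_genes <- unique(unlist(signatures))
  if (length(marker_genes) < length(unlist(signatures))) {
    warn("marker sets overlap across phenotypes")
  }
  n_fill <- max(0, n_genes - length(marker_genes))
  genes <- c(marker_genes, sprintf("GENE%04d", seq_len(n_fill)))
  n_cells <- length(phenotypes)
  barcodes <- names(phenotypes) %||% sprintf("CELL%06d-1", seq_len(n_cells))

  mu <- matrix(nb_mean, nrow = n_cells, ncol = length(genes),
               dimnames = list(barcodes, genes))
  for (ph in names(signatures)) {
    rows <- which(phenotypes == ph)
    if (length(rows) > 0) {
      mu[rows, signatures[[ph]]] <- nb_mean * effect
    }
  }
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = nb_dispersion),
                   nrow = n_cells, dimnames = dimnames(mu))
  out <- as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  attr(out, "truth") <- setNames(unname(phenotypes), barcodes)
  out
}

#' Materialize a synthetic repertoire as on-disk fixtures
#'
#' Writes the exact formats the readers consume: a 10x-style
#' `filtered_contig.csv` (two contig rows per cell) and a Matrix Market
#' triplet directory for the counts, so the whole pipeline is testable with no
#' external download.
#'
#' @param repertoire A [simulate_repertoire()] result.
#' @param gex Optional cells-by-genes matrix over the same barcodes.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_repertoire_fixtures <- function(repertoire, gex = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- bind_rows(
    tibble(barcode = repertoire$barcode, locus = repertoire$locus_ag,
           v_gene = repertoire$v_ag, j_gene = repertoire$j_ag,
           cdr3_aa = repertoire$cdr3_ag, cdr3_nt = NA_character_,
           umis = repertoire$umis_ag, productive = TRUE),
    tibble(barcode = repertoire$barcode, locus = repertoire$locus_bd,
           v_gene = repertoire$v_bd, j_gene = repertoire$j_bd,
           cdr3_aa = repertoire$cdr3_bd, cdr3_nt = NA_character_,
           umis = repertoire$umis_bd, productive = TRUE)) %>%
    arrange(.data$barcode, .data$locus)
  write_contigs_csv(contigs, file.path(dir, "filtered_contig.csv"))
  if (!is.null(gex)) {
    write_gex_triplet(gex, file.path(dir, "gex"))
  }
  invisible(dir)
}
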
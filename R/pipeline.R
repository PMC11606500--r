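#' Run the TCR-first pipeline end to end
#'
#' Orchestrates the stages reading/standardizing the inputs, per-chain CDR3
#' clustering, neighbor enrichment against a shuffled background, TCR-rule
#' annotation, and (for paired samples) clonal dynamics, writing one TSV per
#' stage plus a JSON run manifest (package version, seed, thresholds and
#' per-stage counts — no timestamps, so reruns with the same configuration
#' are byte-identical).
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{contigs}{Path to a `filtered_contig.csv` (or list of paths to
#'       merge).}
#'     \item{gex_dir}{Optional Matrix Market triplet directory; when present,
#'       cells are restricted to both modalities and quality-filtered.}
#'     \item{sample_id}{Sample identifier (default `"S1"`).}
#'     \item{out_dir}{Output directory (required).}
#'     \item{seed}{Integer seed (required).}
#'     \item{chains}{Chain classes to cluster (default `c("A","B","G","D")`).}
#'     \item{min_genes, max_mito_frac}{QC thresholds (defaults 200, 0.1).}
#'     \item{radius, fold, alpha}{Enrichment settings (defaults 12.5, 50,
#'       0.05).}
#'     \item{inflation}{MCL inflation (default 2).}
#'     \item{pre_sample, post_sample}{Optional paired sample ids for
#'       dynamics.}
#'   }
#' @return The manifest list, invisibly; outputs land in `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(sample_id = "S1", chains = c("A", "B", "G", "D"),
                   min_genes = 200, max_mito_frac = 0.1, radius = 12.5,
                   fold = 50, alpha = 0.05, inflation = 2)
  config <- modifyList(defaults, config)
  if (is.null(config$out_dir)) abort("config$out_dir is required")
  if (is.null(config$seed)) abort("config$seed is required")
  if (is.null(config$contigs)) {
    abort("stage io: config$contigs is required", class = "tcrfirst_stage_error")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "tcrfirst",
                   version = as.character(packageVersion("tcrfirst")),
                   seed = config$seed,
                   thresholds = config[c("min_genes", "max_mito_frac", "radius",
                                         "fold", "alpha", "inflation")],
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage ", name, ": ", conditionMessage(e)),
            class = "tcrfirst_stage_error")
    })
  }

  # stage 1: io
  clonotypes <- stage("io", {
    paths <- unlist(config$contigs)
    contigs <- if (length(paths) == 1) parse_contigs(paths[[1]]) else {
      Reduce(merge_chain_sets, lapply(paths, parse_contigs))
    }
    resolve_cell_chains(contigs, sample_id = config$sample_id)
  })
  manifest$stages$io <- list(n_cells = nrow(clonotypes),
                             multiplets = attr(clonotypes, "multiplets"),
                             dual_excluded = attr(clonotypes, "dual_excluded"))
  repertoire <- clonotypes
  if (!is.null(config$gex_dir)) {
    repertoire <- stage("io", {
      gex <- read_gex_triplet(config$gex_dir)
      gex <- qc_filter_cells(gex, config$min_genes, config$max_mito_frac)
      build_repertoire(clonotypes, gex, sample_id = config$sample_id)
    })
    manifest$stages$io$modality_counts <- as.list(attr(repertoire, "modality_counts"))
  }
  write_repertoire_tsv(repertoire, file.path(config$out_dir, "repertoire.tsv"))

  # stage 2: clustering
  items <- stage("clustering", cluster_chain_split(repertoire))
  all_clusters <- list()
  enrichments <- list()
  for (ch in config$chains) {
    it <- items[[ch]]
    if (is.null(it) || nrow(it) == 0) next
    cl <- stage("clustering", cluster_cdr3(it, inflation = config$inflation))
    if (nrow(cl) > 0) {
      all_clusters[[ch]] <- cluster_members_table(cl) %>% mutate(chain = ch)
    }
    manifest$stages$clustering[[ch]] <-
      list(n_items = nrow(it), n_clusters = nrow(cl))
    # stage 3: enrichment (skipped for chains too small to stratify)
    if (nrow(it) >= 20) {
      enr <- stage("enrichment", {
        bg <- shuffle_background(it, fold = config$fold, seed = config$seed)
        enrich_clones(it, bg, dist_params(radius = config$radius),
                      alpha = config$alpha)
      })
      enrichments[[ch]] <- mutate(as_tibble(enr), chain = ch)
      manifest$stages$enrichment[[ch]] <-
        list(n_tested = nrow(enr), n_significant = sum(enr$significant))
    }
  }
  if (length(all_clusters) > 0) {
    readr::write_tsv(bind_rows(all_clusters),
                     file.path(config$out_dir, "clusters.tsv"), progress = FALSE)
  }
  if (length(enrichments) > 0) {
    readr::write_tsv(bind_rows(enrichments),
                     file.path(config$out_dir, "enrichment.tsv"), progress = FALSE)
  }

  # stage 4: annotation
  annotated <- stage("annotation", classify_by_tcr(repertoire))
  readr::write_tsv(count(as_tibble(annotated), .data$tcr_label),
                   file.path(config$out_dir, "tcr_labels.tsv"), progress = FALSE)
  manifest$stages$annotation <-
    as.list(table(annotated$tcr_label))

  # stage 5: dynamics (paired samples only)
  if (!is.null(config$pre_sample) && !is.null(config$post_sample)) {
    dyn <- stage("dynamics", {
      paired_dynamics(clone_frequencies(repertoire, config$pre_sample),
                      clone_frequencies(repertoire, config$post_sample))
    })
    readr::write_tsv(as_tibble(dyn), file.path(config$out_dir, "dynamics.tsv"),
                     progress = FALSE)
    manifest$stages$dynamics <- list(n_clones = nrow(dyn),
                                     n_selected = sum(dyn$selected))
  }

  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}
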
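#' Read a single-cell TCR contig table
#'
#' Parses a 10x Genomics-style `filtered_contig.csv` (or an AIRR rearrangement
#' TSV with the standard column mapping) into a standardized contig tibble.
#' One row corresponds to one sequenced TCR chain of one cell.
#'
#' Rows whose locus is not one of TRA/TRB/TRG/TRD (e.g. `"Multi"`, IG chains)
#' are dropped; the number dropped is reported as a message and stored in the
#' `"dropped_loci"` attribute.
#'
#' @param path Path to the contig file.
#' @param format `"10x"` (CSV with columns `barcode`, `chain`, `v_gene`,
#'   `j_gene`, `cdr3`, optionally `cdr3_nt`, `umis`, `productive`) or
#'   `"airr"` (TSV; `cell_id`/`barcode`, `locus`, `v_call`, `j_call`,
#'   `junction_aa`, `duplicate_count`, `productive`).
#' @return A tibble with columns `barcode`, `locus`, `v_gene`, `j_gene`,
#'   `cdr3_aa`, `cdr3_nt`, `umis`, `productive`.
#' @export
parse_contigs <- function(path, format = c("10x", "airr")) {
  format <- match.arg(format)
  raw <- if (format == "10x") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  cmap <- if (format == "10x") {
    c(barcode = "barcode", locus = "chain", v_gene = "v_gene",
      j_gene = "j_gene", cdr3_aa = "cdr3")
  } else {
    c(barcode = "cell_id", locus = "locus", v_gene = "v_call",
      j_gene = "j_call", cdr3_aa = "junction_aa")
  }
  if (format == "airr" && !"cell_id" %in% names(raw) && "barcode" %in% names(raw)) {
    cmap[["barcode"]] <- "barcode"
  }
  missing <- setdiff(unname(cmap), names(raw))
  if (length(missing) > 0) {
    abort(paste0("contig file is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tcrfirst_format_error")
  }
  if (nrow(raw) == 0) {
    warn("contig file contains a header but no rows")
    out <- tibble(barcode = character(), locus = character(),
                  v_gene = character(), j_gene = character(),
                  cdr3_aa = character(), cdr3_nt = character(),
                  umis = integer(), productive = logical())
    attr(out, "dropped_loci") <- 0L
    return(out)
  }
  umi_col <- if (format == "10x") "umis" else "duplicate_count"
  nt_col <- if (format == "10x") "cdr3_nt" else "junction"
  out <- tibble(
    barcode = as.character(raw[[cmap[["barcode"]]]]),
    locus = as.character(raw[[cmap[["locus"]]]]),
    v_gene = as.character(raw[[cmap[["v_gene"]]]]),
    j_gene = as.character(raw[[cmap[["j_gene"]]]]),
    cdr3_aa = as.character(raw[[cmap[["cdr3_aa"]]]]),
    cdr3_nt = if (nt_col %in% names(raw)) as.character(raw[[nt_col]]) else NA_character_,
    umis = if (umi_col %in% names(raw)) as.integer(raw[[umi_col]]) else 1L,
    productive = parse_truthy(raw[["productive"]] %||% TRUE)
  )
  keep <- out$locus %in% c("TRA", "TRB", "TRG", "TRD")
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf("dropped %d contig(s) with locus outside TRA/TRB/TRG/TRD", n_drop))
  }
  out <- out[keep, , drop = FALSE]
  attr(out, "dropped_loci") <- n_drop
  out
}

parse_truthy <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "yes", "productive", "1")
}

#' Merge separately delivered alpha-beta and gamma-delta contig tables
#'
#' Some kits deliver the alpha-beta and gamma-delta receptors of one run as two
#' contig files; this concatenates them and flags barcodes that carry contigs
#' from both lineages (`dual_lineage`), leaving the collision rule to
#' [resolve_cell_chains()].
#'
#' @param ab,gd Contig tibbles as returned by [parse_contigs()].
#' @return The combined contig tibble with a logical `dual_lineage` column.
#' @export
merge_chain_sets <- function(ab, gd) {
  merged <- bind_rows(ab, gd)
  if (nrow(merged) == 0) {
    merged$dual_lineage <- logical(0)
    return(merged)
  }
  lineage <- if_else(merged$locus %in% c("TRA", "TRB"), "ab", "gd")
  dual_bc <- unique(merged$barcode[lineage == "ab"])
  dual_bc <- intersect(dual_bc, unique(merged$barcode[lineage == "gd"]))
  merged$dual_lineage <- merged$barcode %in% dual_bc
  merged
}

#' Resolve per-cell chains into clonotypes
#'
#' Keeps only productive contigs, selects within each chain group (AG = TRA or
#' TRG, BD = TRB or TRD) the contig with the highest UMI count (ties broken by
#' the lexicographically smallest CDR3), and builds one clonotype row per cell.
#' Cells with more than two distinct productive contigs in a single chain group
#' are flagged as multiplets and excluded; cells carrying both alpha-beta and
#' gamma-delta receptors are excluded by default as ambiguous.
#'
#' @param records Contig tibble ([parse_contigs()] / [merge_chain_sets()]).
#' @param sample_id Sample identifier attached to every clonotype.
#' @param keep_dual Keep dual-lineage (alpha-beta + gamma-delta) cells, flagged
#'   in the `dual_lineage` column, instead of excluding them.
#' @return A clonotype tibble, one row per cell: `barcode`, `sample_id`,
#'   `locus_ag`, `v_ag`, `j_ag`, `cdr3_ag`, `locus_bd`, `v_bd`, `j_bd`,
#'   `cdr3_bd`, `clone_key`, `dual_lineage`. Exclusion counts are stored in the
#'   `"multiplets"` and `"dual_excluded"` attributes.
#' @export
resolve_cell_chains <- function(records, sample_id = "S1", keep_dual = FALSE) {
  prod <- records %>%
    filter(.data$productive, !is.na(.data$cdr3_aa), .data$cdr3_aa != "") %>%
    distinct(.data$barcode, .data$locus, .data$v_gene, .data$j_gene,
             .data$cdr3_aa, .keep_all = TRUE) %>%
    mutate(group = if_else(.data$locus %in% c("TRA", "TRG"), "AG", "BD"),
           lineage = if_else(.data$locus %in% c("TRA", "TRB"), "ab", "gd"))

  if (nrow(prod) == 0) {
    out <- empty_clonotypes()
    attr(out, "multiplets") <- 0L
    attr(out, "dual_excluded") <- 0L
    return(out)
  }

  grp_n <- prod %>% count(.data$barcode, .data$group)
  multiplet_bc <- unique(grp_n$barcode[grp_n$n > 2])
  dual_tab <- prod %>% distinct(.data$barcode, .data$lineage) %>% count(.data$barcode)
  dual_bc <- dual_tab$barcode[dual_tab$n > 1]
  drop_dual <- if (keep_dual) character(0) else dual_bc

  best <- prod %>%
    filter(!.data$barcode %in% multiplet_bc, !.data$barcode %in% drop_dual) %>%
    group_by(.data$barcode, .data$group) %>%
    arrange(desc(.data$umis), .data$cdr3_aa, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup()

  if (nrow(best) == 0) {
    out <- empty_clonotypes()
  } else {
    wide <- best %>%
      select("barcode", "group", "locus", "v_gene", "j_gene", "cdr3_aa") %>%
      tidyr::pivot_wider(names_from = "group",
                         values_from = c("locus", "v_gene", "j_gene", "cdr3_aa"),
                         names_glue = "{.value}_{tolower(group)}")
    for (col in c("locus_ag", "v_gene_ag", "j_gene_ag", "cdr3_aa_ag",
                  "locus_bd", "v_gene_bd", "j_gene_bd", "cdr3_aa_bd")) {
      if (!col %in% names(wide)) wide[[col]] <- NA_character_
    }
    out <- wide %>%
      rename(v_ag = "v_gene_ag", j_ag = "j_gene_ag", cdr3_ag = "cdr3_aa_ag",
             v_bd = "v_gene_bd", j_bd = "j_gene_bd", cdr3_bd = "cdr3_aa_bd") %>%
      mutate(sample_id = sample_id,
             clone_key = clone_key(.data$v_ag, .data$j_ag, .data$cdr3_ag,
                                   .data$v_bd, .data$j_bd, .data$cdr3_bd),
             dual_lineage = .data$barcode %in% dual_bc) %>%
      select("barcode", "sample_id", "locus_ag", "v_ag", "j_ag", "cdr3_ag",
             "locus_bd", "v_bd", "j_bd", "cdr3_bd", "clone_key", "dual_lineage") %>%
      arrange(.data$barcode)
  }
  attr(out, "multiplets") <- length(multiplet_bc)
  attr(out, "dual_excluded") <- length(drop_dual)
  out
}

empty_clonotypes <- function() {
  tibble(barcode = character(), sample_id = character(),
         locus_ag = character(), v_ag = character(), j_ag = character(),
         cdr3_ag = character(), locus_bd = character(), v_bd = character(),
         j_bd = character(), cdr3_bd = character(), clone_key = character(),
         dual_lineage = logical())
}

#' Canonical clone key
#'
#' Deterministic string identity of a paired receptor:
#' `"Vag.Jag_CDR3ag|Vbd.Jbd_CDR3bd"`, with a missing chain rendered as an
#' empty field.
#'
#' @param v_ag,j_ag,cdr3_ag,v_bd,j_bd,cdr3_bd Chain components (vectors).
#' @return Character vector of clone keys.
#' @export
clone_key <- function(v_ag, j_ag, cdr3_ag, v_bd, j_bd, cdr3_bd) {
  ag <- if_else(is.na(cdr3_ag), "", paste0(v_ag, ".", j_ag, "_", cdr3_ag))
  bd <- if_else(is.na(cdr3_bd), "", paste0(v_bd, ".", j_bd, "_", cdr3_bd))
  paste0(ag, "|", bd)
}

#' Restrict clonotypes to cells present in a count matrix
#'
#' Implements the both-modalities rule: the repertoire keeps exactly the
#' clonotypes whose barcode also appears in the expression matrix. Reports how
#' many cells carry TCR only, expression only, or both (attribute
#' `"modality_counts"`).
#'
#' @param clonotypes Clonotype tibble from [resolve_cell_chains()].
#' @param gex Cells-by-genes sparse count matrix ([read_gex_triplet()]).
#' @param sample_id Optional sample id overriding the clonotype table's.
#' @param strip_suffix Strip a trailing `-<digits>` barcode suffix on both
#'   sides before intersecting (10x suffix dialects differ between files).
#' @return A `tcr_repertoire` tibble (clonotype rows restricted to shared
#'   barcodes) with the matrix attached as the `"gex"` attribute.
#' @export
build_repertoire <- function(clonotypes, gex, sample_id = NULL, strip_suffix = FALSE) {
  stopifnot(inherits(gex, "Matrix") || is.matrix(gex))
  gex_bc <- rownames(gex)
  if (anyDuplicated(gex_bc)) abort("expression matrix barcodes are not unique")
  tcr_bc <- clonotypes$barcode
  norm <- function(x) if (strip_suffix) sub("-[0-9]+$", "", x) else x
  shared <- intersect(norm(tcr_bc), norm(gex_bc))
  if (length(shared) == 0) {
    abort(paste0("no barcode overlap between TCR and expression data; ",
                 "check for a '-1'-style suffix mismatch ",
                 "(see the strip_suffix argument)"))
  }
  keep <- norm(tcr_bc) %in% shared
  rep <- clonotypes[keep, , drop = FALSE]
  if (!is.null(sample_id)) rep$sample_id <- sample_id
  gex_keep <- norm(gex_bc) %in% norm(rep$barcode)
  attr(rep, "gex") <- gex[gex_keep, , drop = FALSE]
  attr(rep, "modality_counts") <- c(
    tcr_only = sum(!keep),
    gex_only = sum(!gex_keep),
    both = sum(keep)
  )
  class(rep) <- c("tcr_repertoire", class(rep))
  rep
}

#' Read a Matrix Market expression triplet directory
#'
#' Reads `matrix.mtx`, `barcodes.tsv` and `features.tsv` (gzipped variants
#' accepted) and returns a cells-by-genes sparse count matrix. Orientation is
#' auto-detected from the barcode and feature list lengths; the 10x convention
#' (genes x cells) is assumed when ambiguous.
#'
#' @param dir Directory containing the three files.
#' @return A `dgCMatrix` with barcodes as rownames and gene symbols as
#'   colnames.
#' @export
read_gex_triplet <- function(dir) {
  find1 <- function(stems) {
    for (s in stems) {
      for (ext in c("", ".gz")) {
        p <- file.path(dir, paste0(s, ext))
        if (file.exists(p)) return(p)
      }
    }
    abort(paste0("no ", stems[1], "[.gz] found in ", dir),
          class = "tcrfirst_format_error")
  }
  mtx_path <- find1("matrix.mtx")
  bc_path <- find1("barcodes.tsv")
  ft_path <- find1(c("features.tsv", "genes.tsv"))

  m <- tryCatch(
    Matrix::readMM(if (grepl("\\.gz$", mtx_path)) gzfile(mtx_path) else mtx_path),
    error = function(e) abort(paste0("malformed Matrix Market file: ",
                                     conditionMessage(e)),
                              class = "tcrfirst_format_error"))
  barcodes <- readLines(bc_path)
  ft_lines <- readLines(ft_path)
  ft_fields <- strsplit(ft_lines, "\t", fixed = TRUE)
  # 10x features.tsv: id <tab> symbol <tab> type; plain lists: symbol only
  features <- vapply(ft_fields, function(f) if (length(f) >= 2) f[2] else f[1], "")

  nb <- length(barcodes); nf <- length(features)
  if (nrow(m) == nf && ncol(m) == nb) {
    m <- Matrix::t(m)
  } else if (!(nrow(m) == nb && ncol(m) == nf)) {
    abort(sprintf(
      "matrix dimensions %d x %d match neither barcodes (%d) x features (%d) nor its transpose",
      nrow(m), ncol(m), nb, nf), class = "tcrfirst_format_error")
  }
  m <- as(as(m, "CsparseMatrix"), "dMatrix")
  dimnames(m) <- list(barcodes, features)
  m
}

#' Write an expression matrix as a Matrix Market triplet directory
#'
#' Inverse of [read_gex_triplet()]; writes in the 10x orientation
#' (genes x cells). Used to materialize synthetic fixtures.
#'
#' @param gex Cells-by-genes matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gex_triplet <- function(gex, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(Matrix::t(gex), "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(gex), file.path(dir, "barcodes.tsv"))
  writeLines(paste(colnames(gex), colnames(gex), "Gene Expression", sep = "\t"),
             file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Quality-filter cells of an expression matrix
#'
#' Retains cells with at least `min_genes` detected genes and a mitochondrial
#' fraction (genes with the `MT-` symbol prefix) of at most `max_mito_frac`.
#'
#' @param gex Cells-by-genes sparse count matrix.
#' @param min_genes Minimum number of genes with nonzero counts (default 200).
#' @param max_mito_frac Maximum mitochondrial count fraction (default 0.1).
#' @return The filtered matrix; per-cell statistics of the removed and kept
#'   cells in the `"qc_stats"` attribute.
#' @export
qc_filter_cells <- function(gex, min_genes = 200, max_mito_frac = 0.1) {
  detected <- Matrix::rowSums(gex > 0)
  totals <- Matrix::rowSums(gex)
  mito_cols <- startsWith(colnames(gex), "MT-")
  mito <- if (any(mito_cols)) Matrix::rowSums(gex[, mito_cols, drop = FALSE]) else 0
  mito_frac <- ifelse(totals > 0, mito / totals, 0)
  keep <- detected >= min_genes & mito_frac <= max_mito_frac
  if (!any(keep)) {
    abort("quality filter removed every cell; thresholds are too strict")
  }
  out <- gex[keep, , drop = FALSE]
  attr(out, "qc_stats") <- tibble(
    barcode = rownames(gex), detected = as.integer(detected),
    mito_frac = as.numeric(mito_frac), kept = keep)
  out
}

#' Write the canonical one-row-per-cell repertoire table
#'
#' @param repertoire Clonotype/repertoire tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_repertoire_tsv <- function(repertoire, path) {
  readr::write_tsv(as_tibble(repertoire), path, progress = FALSE)
  invisible(path)
}

#' Write a contig tibble in the 10x filtered_contig.csv layout
#'
#' @param contigs Contig tibble ([parse_contigs()] layout).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contigs_csv <- function(contigs, path) {
  out <- tibble(
    barcode = contigs$barcode, chain = contigs$locus,
    v_gene = contigs$v_gene, j_gene = contigs$j_gene,
    cdr3 = contigs$cdr3_aa, cdr3_nt = contigs$cdr3_nt %||% NA_character_,
    umis = contigs$umis, productive = ifelse(contigs$productive, "True", "False"))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
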
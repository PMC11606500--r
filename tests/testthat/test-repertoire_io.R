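test_that("contig CSV round-trips and off-locus rows are dropped with a count", {
  contigs <- toy_contigs()
  extra <- dplyr::bind_rows(
    contigs,
    tibble::tibble(barcode = "BC9-1", locus = "Multi", v_gene = "TRBV9",
                   j_gene = "TRBJ1-1", cdr3_aa = "CASSXX", cdr3_nt = NA,
                   umis = 1L, productive = TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_contigs_csv(extra, path)
  suppressMessages(got <- parse_contigs(path))
  expect_equal(nrow(got), nrow(contigs))
  expect_equal(attr(got, "dropped_loci"), 1L)
  expect_equal(got$cdr3_aa, contigs$cdr3_aa)
  expect_true(all(got$productive))
  expect_equal(got$umis, contigs$umis)
})

test_that("contig parsing enforces required columns and tolerates empty files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("barcode,chain,v_gene,cdr3", path)  # j_gene missing
  expect_error(parse_contigs(path), "j_gene", class = "tcrfirst_format_error")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("barcode,chain,v_gene,j_gene,cdr3,umis,productive", path2)
  expect_warning(got <- parse_contigs(path2), "no rows")
  expect_equal(nrow(got), 0)
})

test_that("AIRR rearrangement TSVs map onto the standard contig columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    cell_id = "BC1-1", locus = "TRB", v_call = "TRBV6-5", j_call = "TRBJ1-5",
    junction_aa = "CASRRTGRNQPQHF", duplicate_count = 9, productive = "T"),
    path)
  got <- parse_contigs(path, format = "airr")
  expect_equal(got$v_gene, "TRBV6-5")
  expect_equal(got$umis, 9L)
  expect_true(got$productive)
})

test_that("merging alpha-beta and gamma-delta files flags shared barcodes", {
  ab <- toy_contigs()
  gd <- tibble::tibble(
    barcode = c("BC1-1", "BC7-1"), locus = c("TRG", "TRD"),
    v_gene = c("TRGV4", "TRDV1"), j_gene = c("TRGJ2", "TRDJ1"),
    cdr3_aa = c("CATWDGPYYKKLF", "CALGELGDTPFF"), cdr3_nt = NA_character_,
    umis = c(2L, 3L), productive = TRUE)
  merged <- merge_chain_sets(ab, gd)
  expect_equal(nrow(merged), nrow(ab) + nrow(gd))
  expect_setequal(merged$barcode[merged$dual_lineage], "BC1-1")

  only <- merge_chain_sets(ab, ab[0, ])
  expect_equal(only$barcode, ab$barcode)
  expect_false(any(only$dual_lineage))
})

test_that("chain resolution keeps the top-UMI contig per group and drops multiplets", {
  contigs <- toy_contigs()
  res <- resolve_cell_chains(contigs)
  # BC2 had two TRA contigs (umis 7 vs 2): the 7-UMI one wins
  bc2 <- res[res$barcode == "BC2-1", ]
  expect_equal(bc2$cdr3_ag, "CAVGASKAAGNKLTF")
  # BC3 has only a BD chain
  bc3 <- res[res$barcode == "BC3-1", ]
  expect_true(is.na(bc3$cdr3_ag))
  expect_equal(bc3$cdr3_bd, "CASSIRTNEQFF")
  expect_equal(attr(res, "multiplets"), 0L)

  # UMI tie broken by lexicographically smallest CDR3
  tie <- contigs
  tie$umis[tie$barcode == "BC2-1" & tie$locus == "TRA"] <- 5L
  res_tie <- resolve_cell_chains(tie)
  expect_equal(res_tie$cdr3_ag[res_tie$barcode == "BC2-1"], "CAVGASKAAGNKLTF")

  # three productive contigs in one group: multiplet, excluded
  tri <- dplyr::bind_rows(contigs, tibble::tibble(
    barcode = "BC2-1", locus = "TRA", v_gene = "TRAV19", j_gene = "TRAJ40",
    cdr3_aa = "CALSETSGTYKYIF", cdr3_nt = NA, umis = 9L, productive = TRUE))
  res_tri <- resolve_cell_chains(tri)
  expect_false("BC2-1" %in% res_tri$barcode)
  expect_equal(attr(res_tri, "multiplets"), 1L)
})

test_that("chain resolution is idempotent and order-independent", {
  contigs <- toy_contigs()
  res1 <- resolve_cell_chains(contigs)
  res2 <- resolve_cell_chains(contigs[sample(nrow(contigs)), ])
  expect_equal(as.data.frame(res1), as.data.frame(res2))
})

test_that("dual-lineage cells are excluded by default and kept on request", {
  both <- merge_chain_sets(toy_contigs(), tibble::tibble(
    barcode = "BC1-1", locus = "TRG", v_gene = "TRGV4", j_gene = "TRGJ2",
    cdr3_aa = "CATWDGPYYKKLF", cdr3_nt = NA_character_, umis = 8L,
    productive = TRUE))
  dropped <- resolve_cell_chains(both)
  expect_false("BC1-1" %in% dropped$barcode)
  expect_equal(attr(dropped, "dual_excluded"), 1L)
  kept <- resolve_cell_chains(both, keep_dual = TRUE)
  expect_true("BC1-1" %in% kept$barcode)
  expect_true(kept$dual_lineage[kept$barcode == "BC1-1"])
})

test_that("repertoire restriction is exactly the barcode intersection", {
  clonotypes <- resolve_cell_chains(toy_contigs())
  gex <- qc_fixture(n_cells = 10)
  rownames(gex)[1:2] <- c("BC1-1", "BC2-1")
  rep <- build_repertoire(clonotypes, gex)
  expect_setequal(rep$barcode, c("BC1-1", "BC2-1"))
  counts <- attr(rep, "modality_counts")
  expect_equal(unname(counts["both"]), 2)
  expect_equal(unname(counts["tcr_only"]), 1)
  expect_equal(unname(counts["gex_only"]), 8)
  expect_equal(rownames(attr(rep, "gex")), c("BC1-1", "BC2-1"))
})

test_that("suffix-dialect barcodes intersect only with stripping enabled", {
  clonotypes <- resolve_cell_chains(toy_contigs())
  gex <- qc_fixture(n_cells = 4)
  rownames(gex) <- c("BC1", "BC2", "BC3", "BC4")  # no '-1' suffix
  expect_error(build_repertoire(clonotypes, gex), "suffix")
  rep <- build_repertoire(clonotypes, gex, strip_suffix = TRUE)
  # manual normalization oracle
  manual <- intersect(sub("-[0-9]+$", "", clonotypes$barcode),
                      sub("-[0-9]+$", "", rownames(gex)))
  expect_setequal(sub("-[0-9]+$", "", rep$barcode), manual)
})

test_that("Matrix Market triplets round-trip, auto-orient, and reject truncation", {
  gex <- qc_fixture(n_cells = 7, n_genes = 30)
  dir <- withr::local_tempdir()
  write_gex_triplet(gex, dir)
  back <- read_gex_triplet(dir)
  expect_equal(as.matrix(back), as.matrix(gex))

  # already cells-x-genes on disk: orientation detected from lengths
  dir2 <- withr::local_tempdir()
  Matrix::writeMM(gex, file.path(dir2, "matrix.mtx"))
  writeLines(rownames(gex), file.path(dir2, "barcodes.tsv"))
  writeLines(colnames(gex), file.path(dir2, "features.tsv"))
  expect_equal(as.matrix(read_gex_triplet(dir2)), as.matrix(gex))

  # truncated matrix file (header and size line lost)
  dir3 <- withr::local_tempdir()
  write_gex_triplet(gex, dir3)
  lines <- readLines(file.path(dir3, "matrix.mtx"))
  writeLines(lines[1], file.path(dir3, "matrix.mtx"))
  expect_error(read_gex_triplet(dir3), class = "tcrfirst_format_error")

  # truncated barcode list: dimensions no longer agree
  dir4 <- withr::local_tempdir()
  write_gex_triplet(gex, dir4)
  writeLines(rownames(gex)[-1], file.path(dir4, "barcodes.tsv"))
  expect_error(read_gex_triplet(dir4), class = "tcrfirst_format_error")
})

test_that("gzipped triplet files are accepted", {
  gex <- qc_fixture(n_cells = 5, n_genes = 20)
  dir <- withr::local_tempdir()
  write_gex_triplet(gex, dir)
  for (f in c("matrix.mtx", "barcodes.tsv", "features.tsv")) {
    p <- file.path(dir, f)
    R.utils_gzip <- function(src) {
      con <- gzfile(paste0(src, ".gz"), "wb")
      writeLines(readLines(src), con)
      close(con)
      unlink(src)
    }
    R.utils_gzip(p)
  }
  expect_equal(as.matrix(read_gex_triplet(dir)), as.matrix(gex))
})

test_that("cell quality filter matches a brute-force per-cell recomputation", {
  gex <- qc_fixture()
  kept <- qc_filter_cells(gex, min_genes = 150, max_mito_frac = 0.1)
  dense <- as.matrix(gex)
  manual_keep <- vapply(seq_len(nrow(dense)), function(i) {
    row <- dense[i, ]
    detected <- sum(row > 0)
    mito <- sum(row[startsWith(colnames(dense), "MT-")])
    detected >= 150 && (mito / sum(row)) <= 0.1
  }, logical(1))
  expect_setequal(rownames(kept), rownames(dense)[manual_keep])
  expect_gt(nrow(kept), 0)
  expect_lt(nrow(kept), nrow(dense))
  expect_error(qc_filter_cells(gex, min_genes = 10000), "too strict")
})
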
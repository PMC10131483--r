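#' Write a synthetic bundle to a directory of plain-text files
#'
#' Emits every pipeline input in its standard on-disk form: gene catalogs
#' as one id per line, pairwise hits as 12-column BLAST tabular (outfmt 6)
#' TSV without header, domain hits and expression matrices as headered
#' TSV, the cell-cluster and lineage/precursor maps as TSV, the ground
#' truth as JSON, plus a `manifest.json` listing each file with its data
#' row count.
#'
#' @param bundle An `effector_bundle` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#'
#' @return The manifest as a tibble (`file`, `rows`), invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", dir))
  }
  p <- function(f) file.path(dir, f)
  manifest <- list()
  put <- function(file, rows) manifest[[length(manifest) + 1]] <<-
    tibble::tibble(file = file, rows = as.integer(rows))

  writeLines(bundle$catalog_a$gene_id, p("catalog_a.txt"))
  put("catalog_a.txt", nrow(bundle$catalog_a))
  writeLines(bundle$catalog_b$gene_id, p("catalog_b.txt"))
  put("catalog_b.txt", nrow(bundle$catalog_b))

  readr::write_tsv(bundle$domain_hits, p("domain_hits.tsv"))
  put("domain_hits.tsv", nrow(bundle$domain_hits))

  readr::write_tsv(as_outfmt6(bundle$hits_ab), p("hits_ab.tsv"),
                   col_names = FALSE)
  put("hits_ab.tsv", nrow(bundle$hits_ab))
  readr::write_tsv(as_outfmt6(bundle$hits_ba), p("hits_ba.tsv"),
                   col_names = FALSE)
  put("hits_ba.tsv", nrow(bundle$hits_ba))

  readr::write_tsv(bundle$cluster_avg_eg, p("cluster_avg_eg.tsv"))
  put("cluster_avg_eg.tsv", nrow(bundle$cluster_avg_eg))
  readr::write_tsv(bundle$cluster_avg_eb, p("cluster_avg_eb.tsv"))
  put("cluster_avg_eb.tsv", nrow(bundle$cluster_avg_eb))
  readr::write_tsv(bundle$cells_eb, p("cells_eb.tsv"))
  put("cells_eb.tsv", nrow(bundle$cells_eb))
  readr::write_tsv(bundle$cell_clusters_eb, p("cell_clusters_eb.tsv"))
  put("cell_clusters_eb.tsv", nrow(bundle$cell_clusters_eb))

  readr::write_tsv(bundle$lineage_map, p("lineage_map.tsv"))
  put("lineage_map.tsv", nrow(bundle$lineage_map))
  readr::write_tsv(bundle$precursor_map, p("precursor_map.tsv"))
  put("precursor_map.tsv", nrow(bundle$precursor_map))

  for (r in seq_along(bundle$temporal_replicates)) {
    f <- sprintf("temporal_rep%d.tsv", r)
    readr::write_tsv(bundle$temporal_replicates[[r]], p(f))
    put(f, nrow(bundle$temporal_replicates[[r]]))
  }

  truth_json <- bundle$truth
  jsonlite::write_json(truth_json, p("truth.json"), auto_unbox = FALSE,
                       digits = NA, na = "null", pretty = FALSE)
  put("truth.json", nrow(bundle$truth))

  cfg <- unclass(bundle$config)
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  put("config.json", 1L)

  manifest <- dplyr::bind_rows(manifest)
  jsonlite::write_json(manifest, p("manifest.json"), digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

outfmt6_cols <- function() {
  c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore")
}

# dress a (query_id, subject_id, bitscore, e_value) table up as the
# 12-column BLAST tabular layout; alignment geometry columns get fixed
# placeholder values
as_outfmt6 <- function(hits) {
  tibble::tibble(qseqid = hits$query_id, sseqid = hits$subject_id,
                 pident = 85, length = 300L, mismatch = 45L, gapopen = 3L,
                 qstart = 1L, qend = 300L, sstart = 1L, send = 300L,
                 evalue = hits$e_value, bitscore = hits$bitscore)
}

#' Read a BLAST tabular (outfmt 6) pairwise hit table
#'
#' @param path TSV file, 12 unnamed columns in the standard order, or a
#'   headered 4-column table `query_id`, `subject_id`, `bitscore`,
#'   `e_value`.
#'
#' @return Tibble with columns `query_id`, `subject_id`, `bitscore`,
#'   `e_value`.
#' @export
read_pairwise_hits <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) {
    return(tibble::tibble(query_id = character(), subject_id = character(),
                          bitscore = numeric(), e_value = numeric()))
  }
  if (grepl("^query_id\t", first)) {
    return(readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols()))
  }
  raw <- readr::read_tsv(path, col_names = outfmt6_cols(),
                         show_col_types = FALSE)
  tibble::tibble(query_id = raw$qseqid, subject_id = raw$sseqid,
                 bitscore = raw$bitscore, e_value = raw$evalue)
}

#' Read a domain hit table
#'
#' @param path Input file.
#' @param dialect `"tsv"` for a headered table with columns `gene_id`,
#'   `domain_accession`, `e_value`, `score`; `"hmmer_tblout"` for the
#'   whitespace-delimited per-sequence table produced by a profile search
#'   (`--tblout`), from which the target name, query accession, full-
#'   sequence e-value and score are taken.
#'
#' @return Tibble with columns `gene_id`, `domain_accession`, `e_value`,
#'   `score`.
#' @export
read_domain_hits <- function(path, dialect = c("tsv", "hmmer_tblout")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    return(readr::read_tsv(path, show_col_types = FALSE))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(gene_id = character(),
                          domain_accession = character(),
                          e_value = numeric(), score = numeric()))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  tibble::tibble(
    gene_id = vapply(fields, `[`, "", 1),
    domain_accession = vapply(fields, `[`, "", 4),
    e_value = as.numeric(vapply(fields, `[`, "", 5)),
    score = as.numeric(vapply(fields, `[`, "", 6))
  )
}

#' Read a gene catalog
#'
#' @param path One gene id per line, or a FASTA file (ids taken from the
#'   first token of each header line).
#'
#' @return Tibble with a `gene_id` column.
#' @export
read_gene_catalog <- function(path) {
  lines <- readLines(path)
  if (any(startsWith(lines, ">"))) {
    ids <- sub("^>", "", lines[startsWith(lines, ">")])
    ids <- vapply(strsplit(ids, "[[:space:]]+"), `[`, "", 1)
  } else {
    ids <- lines[nzchar(lines)]
  }
  tibble::tibble(gene_id = ids)
}

#' Read a genes-by-columns expression matrix TSV
#'
#' @param path Headered TSV whose first column is `gene_id`.
#'
#' @return Tibble, `gene_id` first, numeric value columns.
#' @export
read_expression_matrix <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = readr::col_character(),
                           .default = readr::col_double()))
  check_expr_tbl(out)
  out
}

#' Read a cluster-to-lineage map
#'
#' @param path TSV with columns `cluster_id`, `lineage`, or a YAML file
#'   mapping cluster ids to lineage names.
#'
#' @return Tibble with columns `cluster_id` (integer), `lineage`.
#' @export
read_lineage_map <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    m <- yaml::read_yaml(path)
    out <- tibble::tibble(cluster_id = as.integer(names(m)),
                          lineage = unname(unlist(m)))
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             cluster_id = readr::col_integer(),
                             lineage = readr::col_character()))
  }
  check_lineage_map(out)
}

#' Read a written bundle back into memory
#'
#' Inverse of [write_bundle()]: reconstructs the in-memory bundle from a
#' directory, exactly for ids/integers and to write-precision for reals.
#'
#' @param dir Directory written by [write_bundle()].
#'
#' @return An `effector_bundle` (without the `config` element's class).
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  if (!file.exists(p("manifest.json"))) {
    abort(paste0("no manifest.json under ", dir))
  }
  reps <- sort(list.files(dir, pattern = "^temporal_rep[0-9]+\\.tsv$"))
  truth <- tibble::as_tibble(jsonlite::fromJSON(p("truth.json")))
  truth$lineage_set <- purrr::map(truth$lineage_set, as.character)
  truth$true_onset_hpf <- as.numeric(truth$true_onset_hpf)
  structure(list(
    config = jsonlite::fromJSON(p("config.json")),
    catalog_a = read_gene_catalog(p("catalog_a.txt")),
    catalog_b = read_gene_catalog(p("catalog_b.txt")),
    domain_hits = read_domain_hits(p("domain_hits.tsv")),
    hits_ab = read_pairwise_hits(p("hits_ab.tsv")),
    hits_ba = read_pairwise_hits(p("hits_ba.tsv")),
    cluster_avg_eg = read_expression_matrix(p("cluster_avg_eg.tsv")),
    cluster_avg_eb = read_expression_matrix(p("cluster_avg_eb.tsv")),
    cells_eb = read_expression_matrix(p("cells_eb.tsv")),
    cell_clusters_eb = readr::read_tsv(p("cell_clusters_eb.tsv"),
                                       show_col_types = FALSE),
    lineage_map = read_lineage_map(p("lineage_map.tsv")),
    precursor_map = readr::read_tsv(p("precursor_map.tsv"),
                                    show_col_types = FALSE),
    temporal_replicates = purrr::map(reps,
                                     ~ read_expression_matrix(p(.x))),
    truth = truth
  ), class = "effector_bundle")
}
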
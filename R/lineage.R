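#' Default cluster-to-lineage assignment at the early gastrula stage
#'
#' Fifteen cell clusters (0-14) mapped onto the seven embryonic lineages:
#' apical ectoderm (cluster 11), nonapical ectoderm (1-3, 8, 9), Veg1
#' ectoderm (0, 5, 6), Veg1/2 endoderm (4, 7), nonskeletogenic mesoderm
#' (10, 14), skeletogenic cells (12) and germline (13). Veg1 and Veg2
#' endoderm are treated as a single lineage because the clusters cannot
#' be separated at this stage.
#'
#' @return A tibble with columns `cluster_id` (integer) and `lineage`.
#' @export
default_lineage_map <- function() {
  tibble::tibble(
    cluster_id = c(11L, 1L, 2L, 3L, 8L, 9L, 0L, 5L, 6L, 4L, 7L, 10L, 14L,
                   12L, 13L),
    lineage = c("apical_ectoderm",
                rep("nonapical_ectoderm", 5),
                rep("veg1_ectoderm", 3),
                rep("veg12_endoderm", 2),
                rep("NSM", 2),
                "skeletogenic", "germline")
  )
}

check_lineage_map <- function(lmap) {
  lmap <- tibble::as_tibble(lmap)
  if (!all(c("cluster_id", "lineage") %in% names(lmap))) {
    abort("lineage map needs columns cluster_id and lineage")
  }
  bad <- setdiff(unique(lmap$lineage), lineage_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown lineage(s) in map: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(lmap$cluster_id)) {
    abort("each cluster may map to at most one lineage")
  }
  lmap
}

#' Average a cell-level expression matrix by cluster
#'
#' @param cells Genes-by-cells expression tibble: `gene_id` first, one
#'   numeric column per cell.
#' @param assignments Tibble with columns `cell_id`, `cluster_id` covering
#'   every cell column of `cells`; every cluster must contain at least one
#'   cell.
#'
#' @return A genes-by-clusters tibble of arithmetic means: `gene_id` first,
#'   one column per cluster id (sorted), named by the cluster id.
#' @export
average_by_cluster <- function(cells, assignments) {
  check_expr_tbl(cells, "cell matrix")
  assignments <- tibble::as_tibble(assignments)
  cell_cols <- setdiff(names(cells), "gene_id")
  missing <- setdiff(cell_cols, assignments$cell_id)
  if (length(missing) > 0) {
    abort(paste0("cells without a cluster assignment: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  declared <- unique(assignments$cluster_id)
  assignments <- assignments[assignments$cell_id %in% cell_cols, ]
  empty <- setdiff(declared, unique(assignments$cluster_id))
  if (length(empty) > 0) {
    abort(paste0("cluster(s) with no cells in the matrix: ",
                 paste(empty, collapse = ", ")))
  }
  long <- cells %>%
    tidyr::pivot_longer(-"gene_id", names_to = "cell_id",
                        values_to = "value") %>%
    dplyr::inner_join(assignments, by = "cell_id") %>%
    dplyr::group_by(.data$gene_id, .data$cluster_id) %>%
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  out <- long %>%
    dplyr::mutate(cluster_id = as.character(.data$cluster_id)) %>%
    tidyr::pivot_wider(names_from = "cluster_id", values_from = "value")
  cl <- setdiff(names(out), "gene_id")
  out <- out[, c("gene_id", cl[order(suppressWarnings(as.numeric(cl)), cl)])]
  # restore catalog order
  out[match(cells$gene_id, out$gene_id), ]
}

#' Per-lineage representative clusters and their averages
#'
#' For each gene and lineage, the representative cluster is the member
#' cluster with the highest average expression (ties broken by lowest
#' cluster id).
#'
#' @param cluster_avg Genes-by-clusters average-expression tibble
#'   (`gene_id` first, columns named by cluster id).
#' @param lineage_map Tibble with columns `cluster_id`, `lineage`; clusters
#'   absent from the map are ignored (excluded clusters).
#'
#' @return Long tibble: `gene_id`, `lineage`, `representative_cluster`,
#'   `average`.
#' @export
lineage_representatives <- function(cluster_avg,
                                    lineage_map = default_lineage_map()) {
  check_expr_tbl(cluster_avg, "cluster-average matrix")
  lmap <- check_lineage_map(lineage_map)
  long <- cluster_avg %>%
    tidyr::pivot_longer(-"gene_id", names_to = "cluster_id",
                        values_to = "average") %>%
    dplyr::mutate(cluster_id = as.integer(.data$cluster_id)) %>%
    dplyr::inner_join(lmap, by = "cluster_id")
  long %>%
    dplyr::arrange(dplyr::desc(.data$average), .data$cluster_id) %>%
    dplyr::distinct(.data$gene_id, .data$lineage, .keep_all = TRUE) %>%
    dplyr::arrange(.data$gene_id, .data$lineage) %>%
    dplyr::transmute(.data$gene_id, .data$lineage,
                     representative_cluster = .data$cluster_id,
                     .data$average)
}

#' Call the set of lineages in which each gene is expressed
#'
#' A gene is expressed in a lineage when its representative cluster's
#' average expression is strictly above `threshold` (default 0.3). Genes
#' expressed in no lineage are `undetected`, in all seven `ubiquitous`,
#' otherwise `restricted` (1-6 lineages): the tissue-specific candidates.
#'
#' @inheritParams lineage_representatives
#' @param threshold Expression cutoff (strict), nonnegative.
#'
#' @return A tibble, one row per gene in input order: `gene_id`,
#'   `n_lineages`, `category`, `lineage_set` (list-column of character
#'   vectors in canonical lineage order).
#' @export
#'
#' @examples
#' m <- tibble::tibble(gene_id = "g1", `12` = 0.9, `13` = 0.1)
#' lm <- tibble::tibble(cluster_id = c(12L, 13L),
#'                      lineage = c("skeletogenic", "germline"))
#' call_lineages(m, lm)
call_lineages <- function(cluster_avg, lineage_map = default_lineage_map(),
                          threshold = 0.3) {
  if (!is.numeric(threshold) || threshold < 0) {
    abort("threshold must be nonnegative")
  }
  reps <- lineage_representatives(cluster_avg, lineage_map)
  calls <- reps %>%
    dplyr::mutate(expressed = .data$average > threshold,
                  lineage = factor(.data$lineage, levels = lineage_levels())) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      n_lineages = sum(.data$expressed),
      lineage_set = list(as.character(sort(.data$lineage[.data$expressed]))),
      .groups = "drop"
    ) %>%
    dplyr::mutate(category = dplyr::case_when(
      .data$n_lineages == 0 ~ "undetected",
      .data$n_lineages == 7 ~ "ubiquitous",
      TRUE ~ "restricted"
    )) %>%
    dplyr::select("gene_id", "n_lineages", "category", "lineage_set")
  calls[match(cluster_avg$gene_id, calls$gene_id), ]
}

#' Per-cluster distribution summary of gene-wise average expression
#'
#' Median and third quartile of the average expression of all genes in
#' each cluster, using the linear-interpolation quantile convention
#' (R type 7).
#'
#' @inheritParams lineage_representatives
#'
#' @return Tibble with columns `cluster_id`, `median`, `q3`.
#' @export
summarize_distribution <- function(cluster_avg) {
  check_expr_tbl(cluster_avg, "cluster-average matrix")
  if (nrow(cluster_avg) == 0) abort("at least one gene is required")
  cluster_avg %>%
    tidyr::pivot_longer(-"gene_id", names_to = "cluster_id",
                        values_to = "average") %>%
    dplyr::group_by(.data$cluster_id) %>%
    dplyr::summarise(
      median = stats::median(.data$average),
      q3 = unname(stats::quantile(.data$average, 0.75, type = 7)),
      .groups = "drop"
    )
}
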
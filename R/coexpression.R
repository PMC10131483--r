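#' Count coexpression of a gene pair within one cell cluster
#'
#' A cell expresses a gene when its normalized value is strictly above
#' `expressed_min` (default 0: any nonzero expression). The coexpression
#' fraction is the share of the cluster's cells expressing both genes.
#'
#' @param cells Genes-by-cells expression tibble (`gene_id` first).
#' @param assignments Tibble with columns `cell_id`, `cluster_id`.
#' @param gene_a,gene_b Gene ids; `gene_a == gene_b` degenerates to a
#'   single-gene expressing count.
#' @param cluster Cluster id to count in; must contain at least one cell.
#' @param expressed_min Expression cutoff (strict).
#'
#' @return One-row tibble: `gene_a`, `gene_b`, `precursor_cluster`,
#'   `n_cells`, `n_expressing_a`, `n_expressing_b`, `n_coexpressing`,
#'   `fraction_coexpressing`.
#' @export
coexpression_in_cluster <- function(cells, assignments, gene_a, gene_b,
                                    cluster, expressed_min = 0) {
  check_expr_tbl(cells, "cell matrix")
  assignments <- tibble::as_tibble(assignments)
  for (g in unique(c(gene_a, gene_b))) {
    if (!g %in% cells$gene_id) abort(paste0("unknown gene: ", g))
  }
  in_cluster <- assignments$cell_id[assignments$cluster_id == cluster]
  in_cluster <- intersect(in_cluster, setdiff(names(cells), "gene_id"))
  if (length(in_cluster) == 0) {
    abort(paste0("cluster ", cluster, " has no cells in the matrix"))
  }
  va <- as.numeric(cells[cells$gene_id == gene_a, in_cluster])
  vb <- as.numeric(cells[cells$gene_id == gene_b, in_cluster])
  ea <- va > expressed_min
  eb <- vb > expressed_min
  tibble::tibble(
    gene_a = gene_a, gene_b = gene_b, precursor_cluster = cluster,
    n_cells = length(in_cluster),
    n_expressing_a = sum(ea), n_expressing_b = sum(eb),
    n_coexpressing = sum(ea & eb),
    fraction_coexpressing = sum(ea & eb) / length(in_cluster)
  )
}

#' Default lineage-pair to precursor-cluster map
#'
#' At the early blastula stage the Veg2 blastomeres are the shared
#' precursor of the Veg1/2 endoderm and the nonskeletogenic mesoderm,
#' and the Veg1 blastomeres the shared precursor of the Veg1 ectoderm
#' and the Veg1/2 endoderm. Cluster ids must match the early-stage cell
#' matrix in use; these defaults match the synthetic bundle
#' ([simulate_dataset()]).
#'
#' @return Tibble with columns `lineage_a`, `lineage_b`,
#'   `precursor_cluster`.
#' @export
default_precursor_map <- function() {
  tibble::tibble(
    lineage_a = c("veg12_endoderm", "veg1_ectoderm"),
    lineage_b = c("NSM", "veg12_endoderm"),
    precursor_cluster = c("Veg2", "Veg1")
  )
}

#' Screen coexpression of single-lineage effector pairs in precursors
#'
#' Enumerates every pair of single-lineage genes whose two (different)
#' lineages share a precursor cluster at the earlier stage, and counts
#' their coexpression there. Pairs are ordered `gene_a < gene_b` by id;
#' the result is sorted by descending coexpression fraction (ties by
#' gene ids for determinism).
#'
#' @inheritParams coexpression_in_cluster
#' @param lineage_calls Tibble from [call_lineages()] at the later stage;
#'   only rows with `n_lineages == 1` participate.
#' @param precursor_map Tibble with columns `lineage_a`, `lineage_b`,
#'   `precursor_cluster` (one row per lineage pair and precursor cluster).
#'
#' @return Tibble of [coexpression_in_cluster()] rows, one per (pair,
#'   precursor cluster).
#' @export
screen_precursor_coexpression <- function(cells, assignments, lineage_calls,
                                          precursor_map = default_precursor_map(),
                                          expressed_min = 0) {
  single <- lineage_calls %>%
    dplyr::filter(.data$n_lineages == 1) %>%
    dplyr::mutate(lineage = purrr::map_chr(.data$lineage_set, 1)) %>%
    dplyr::select("gene_id", "lineage")
  out <- purrr::pmap_dfr(precursor_map, function(lineage_a, lineage_b,
                                                 precursor_cluster, ...) {
    ga <- single$gene_id[single$lineage == lineage_a]
    gb <- single$gene_id[single$lineage == lineage_b]
    if (length(ga) == 0 || length(gb) == 0) return(NULL)
    pairs <- tidyr::expand_grid(a = ga, b = gb) %>%
      dplyr::filter(.data$a != .data$b) %>%
      dplyr::mutate(gene_a = pmin(.data$a, .data$b),
                    gene_b = pmax(.data$a, .data$b)) %>%
      dplyr::distinct(.data$gene_a, .data$gene_b)
    purrr::map2_dfr(pairs$gene_a, pairs$gene_b, function(a, b) {
      coexpression_in_cluster(cells, assignments, a, b, precursor_cluster,
                              expressed_min = expressed_min)
    })
  })
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(
      gene_a = character(), gene_b = character(),
      precursor_cluster = character(), n_cells = integer(),
      n_expressing_a = integer(), n_expressing_b = integer(),
      n_coexpressing = integer(), fraction_coexpressing = numeric()
    ))
  }
  dplyr::arrange(out, dplyr::desc(.data$fraction_coexpressing),
                 .data$gene_a, .data$gene_b)
}
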
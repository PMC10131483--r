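# Randomized fixture builders used by the oracle-equivalence and
# property-style tests. Bitscores are drawn from a coarse set so ties
# occur often enough to exercise the tie-break rules.

random_hit_tables <- function(n_a = 6, n_b = 6, p_hit = 0.5) {
  ids_a <- sprintf("a%02d", seq_len(n_a))
  ids_b <- sprintf("b%02d", seq_len(n_b))
  grid <- expand.grid(query_id = ids_a, subject_id = ids_b,
                      stringsAsFactors = FALSE)
  make <- function(g) {
    g <- g[runif(nrow(g)) < p_hit, ]
    tibble::tibble(
      query_id = g$query_id,
      subject_id = g$subject_id,
      bitscore = sample(c(100, 150, 200, 250), nrow(g), replace = TRUE),
      e_value = sample(c(1e-50, 1e-30, 1e-10), nrow(g), replace = TRUE)
    )
  }
  rev_grid <- data.frame(query_id = grid$subject_id,
                         subject_id = grid$query_id,
                         stringsAsFactors = FALSE)
  list(ab = make(grid), ba = make(rev_grid))
}

random_cluster_matrix <- function(n_genes = 30, lmap = default_lineage_map()) {
  vals <- matrix(runif(n_genes * nrow(lmap), 0, 0.6), nrow = n_genes)
  out <- tibble::as_tibble(vals, .name_repair = ~ as.character(lmap$cluster_id))
  dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%03d", seq_len(n_genes))),
                   out)
}

random_fpkm_matrix <- function(n_genes = 100, hours = time_grid()) {
  # mix of scales so all origin classes and undetected genes appear
  vals <- matrix(rexp(n_genes * length(hours), rate = 1 / 3),
                 nrow = n_genes)
  low <- runif(n_genes) < 0.3
  vals[low, ] <- vals[low, ] * 0.3
  out <- tibble::as_tibble(vals, .name_repair = ~ paste0("h", hours))
  dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%03d", seq_len(n_genes))),
                   out)
}

random_cell_matrix <- function(n_genes = 8, n_cells = 20, n_clusters = 2) {
  vals <- matrix(rexp(n_genes * n_cells) * rbinom(n_genes * n_cells, 1, 0.5),
                 nrow = n_genes)
  cell_ids <- sprintf("c%03d", seq_len(n_cells))
  out <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%02d", seq_len(n_genes))),
    tibble::as_tibble(vals, .name_repair = ~ cell_ids)
  )
  assignments <- tibble::tibble(
    cell_id = cell_ids,
    cluster_id = sample(sprintf("cl%d", seq_len(n_clusters)), n_cells,
                        replace = TRUE)
  )
  list(cells = out, assignments = assignments)
}

small_config <- function(n_genes = 120, noise_sd = 0.2, seed = 1, ...) {
  simulation_config(n_genes = n_genes, noise_sd = noise_sd, seed = seed,
                    cells_per_cluster = 10, ...)
}

new_tempdir <- function() {
  d <- tempfile("bundle")
  dir.create(d)
  d
}
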
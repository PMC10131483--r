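four_cell_fixture <- function() {
  cells <- tibble::tibble(
    gene_id = c("gA", "gB", "gZ"),
    c1 = c(1, 0, 0), c2 = c(1, 1, 0), c3 = c(0, 1, 0), c4 = c(0, 0, 0)
  )
  asg <- tibble::tibble(cell_id = paste0("c", 1:4), cluster_id = "Veg2")
  list(cells = cells, asg = asg)
}

test_that("coexpression counts cells expressing both genes", {
  fx <- four_cell_fixture()
  res <- coexpression_in_cluster(fx$cells, fx$asg, "gA", "gB", "Veg2")
  expect_equal(res$n_cells, 4)
  expect_equal(res$n_expressing_a, 2)
  expect_equal(res$n_expressing_b, 2)
  expect_equal(res$n_coexpressing, 1)
  expect_equal(res$fraction_coexpressing, 0.25)

  none <- coexpression_in_cluster(fx$cells, fx$asg, "gA", "gZ", "Veg2")
  expect_equal(none$n_coexpressing, 0)

  same <- coexpression_in_cluster(fx$cells, fx$asg, "gA", "gA", "Veg2")
  expect_equal(same$n_coexpressing, same$n_expressing_a)

  expect_error(coexpression_in_cluster(fx$cells, fx$asg, "gA", "nope", "Veg2"),
               "unknown gene")
  expect_error(coexpression_in_cluster(fx$cells, fx$asg, "gA", "gB", "nope"),
               "no cells")
})

test_that("swapping the pair swaps the expressing counts and keeps the fraction", {
  set.seed(13)
  fx <- random_cell_matrix(n_genes = 6, n_cells = 25)
  cl <- fx$assignments$cluster_id[1]
  ab <- coexpression_in_cluster(fx$cells, fx$assignments, "g01", "g02", cl)
  ba <- coexpression_in_cluster(fx$cells, fx$assignments, "g02", "g01", cl)
  expect_equal(ab$n_expressing_a, ba$n_expressing_b)
  expect_equal(ab$n_expressing_b, ba$n_expressing_a)
  expect_equal(ab$n_coexpressing, ba$n_coexpressing)
  expect_equal(ab$fraction_coexpressing, ba$fraction_coexpressing)
})

test_that("the coexpression fraction is nonincreasing in the expression cutoff", {
  set.seed(14)
  fx <- random_cell_matrix(n_genes = 4, n_cells = 30)
  cl <- fx$assignments$cluster_id[1]
  fr <- sapply(c(0, 0.5, 1, 2), function(mn) {
    coexpression_in_cluster(fx$cells, fx$assignments, "g01", "g02", cl,
                            expressed_min = mn)$fraction_coexpressing
  })
  expect_true(all(diff(fr) <= 0))
})

test_that("coexpression counting matches the cell-loop oracle", {
  for (s in 1:5) {
    set.seed(s)
    fx <- random_cell_matrix(n_genes = 8, n_cells = 20)
    genes <- fx$cells$gene_id
    cl <- fx$assignments$cluster_id[1]
    for (a in genes[1:4]) for (b in genes[5:8]) {
      got <- coexpression_in_cluster(fx$cells, fx$assignments, a, b, cl)
      want <- oracle_coexpression(fx$cells, fx$assignments, a, b, cl)
      expect_equal(got$n_cells, want$n_cells)
      expect_equal(got$n_coexpressing, want$n_ab)
      expect_equal(got$fraction_coexpressing, want$fraction)
      expect_true(got$n_coexpressing <=
                    min(got$n_expressing_a, got$n_expressing_b))
    }
  }
})

test_that("precursor screening enumerates shared-precursor pairs, sorted by fraction", {
  # two endoderm genes, one NSM gene, one apical gene (no shared precursor
  # with endoderm in the default map beyond Veg2/Veg1 pairs)
  calls <- tibble::tibble(
    gene_id = c("gEndo1", "gEndo2", "gNSM", "gApical", "gMulti"),
    n_lineages = c(1L, 1L, 1L, 1L, 3L),
    category = c(rep("restricted", 5)),
    lineage_set = list("veg12_endoderm", "veg12_endoderm", "NSM",
                       "apical_ectoderm",
                       c("NSM", "germline", "skeletogenic"))
  )
  cells <- tibble::tibble(
    gene_id = calls$gene_id,
    v1 = c(1, 1, 1, 0, 1), v2 = c(1, 0, 1, 0, 1),
    v3 = c(0, 1, 0, 1, 0), v4 = c(0, 0, 0, 1, 0)
  )
  asg <- tibble::tibble(cell_id = paste0("v", 1:4), cluster_id = "Veg2")
  res <- screen_precursor_coexpression(cells, asg, calls)
  # pairs: gEndo1-gNSM and gEndo2-gNSM (endoderm x NSM in Veg2); gMulti is
  # not single-lineage and never participates
  expect_equal(nrow(res), 2)
  expect_false("gMulti" %in% c(res$gene_a, res$gene_b))
  expect_false("gApical" %in% c(res$gene_a, res$gene_b))
  expect_true(all(res$gene_a < res$gene_b))
  expect_true(all(diff(res$fraction_coexpressing) <= 0))
  got <- res[res$gene_a == "gEndo1", ]
  expect_equal(got$n_coexpressing, 2)
  expect_equal(got$fraction_coexpressing, 0.5)

  empty <- screen_precursor_coexpression(cells, asg,
                                         calls[calls$n_lineages > 1, ])
  expect_equal(nrow(empty), 0)
})

test_that("planted precursor coexpression is recovered exactly at zero noise", {
  b <- simulate_dataset(small_config(n_genes = 150, noise_sd = 0, seed = 9))
  calls <- call_lineages(b$cluster_avg_eg, b$lineage_map)
  res <- screen_precursor_coexpression(b$cells_eb, b$cell_clusters_eb,
                                       calls, b$precursor_map)
  if (nrow(res) > 0) {
    expect_true(all(res$fraction_coexpressing ==
                      b$config$coexpression_fraction))
  }
  expect_gt(nrow(res), 0)
})
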
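test_that("invalid configurations are rejected", {
  expect_error(simulation_config(fraction_housekeeping = 0.5,
                                 fraction_restricted = 0.5,
                                 fraction_undetected = 0.5),
               "sum to 1")
  expect_error(simulation_config(class_weights_temporal = c(
    maternal_only = 0.5, zygotic_clear = 0.5, maternal_dip_rise = 0.2,
    ambiguous_t0 = 0, never_expressed = 0)), "sum to 1")
  expect_error(simulation_config(n_genes = 3), "at least")
  expect_error(simulation_config(fraction_ortholog = 0.9,
                                 fraction_decoy = 0.2), "at most 1")
  expect_error(simulation_config(onset_grid = c(6, 0, 8)), "increasing")
})

test_that("the bundle is a pure function of the configuration", {
  cfg <- small_config(n_genes = 80, seed = 17)
  b1 <- simulate_dataset(cfg)
  b2 <- simulate_dataset(cfg)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$hits_ab, b2$hits_ab)
  expect_identical(b1$cluster_avg_eg, b2$cluster_avg_eg)
  expect_identical(b1$temporal_replicates, b2$temporal_replicates)
  b3 <- simulate_dataset(small_config(n_genes = 80, seed = 18))
  expect_false(identical(b1$cluster_avg_eg, b3$cluster_avg_eg))
})

test_that("zero noise puts every cluster average exactly at its class mean", {
  cfg <- small_config(n_genes = 60, noise_sd = 0, seed = 2)
  b <- simulate_dataset(cfg)
  lmap <- b$lineage_map
  for (i in seq_len(nrow(b$truth))) {
    expressed <- lmap$lineage %in% b$truth$lineage_set[[i]]
    want <- ifelse(expressed, cfg$expressed_mean, cfg$background_mean)
    got <- as.numeric(b$cluster_avg_eg[i, as.character(lmap$cluster_id)])
    expect_equal(got, want)
  }
  # replicates are identical without noise
  expect_identical(b$temporal_replicates[[1]], b$temporal_replicates[[2]])
})

test_that("planted trajectory classes obey their defining constraints", {
  cfg <- small_config(n_genes = 200, noise_sd = 0, seed = 4)
  b <- simulate_dataset(cfg)
  avg <- average_replicates(b$temporal_replicates)
  f <- as.matrix(avg[, -1])
  hours <- time_grid()
  tr <- b$truth
  # onset hour only for classes with embryonic transcription
  expect_true(all(is.na(tr$true_onset_hpf) ==
                    (tr$temporal_class %in% c("maternal_only",
                                              "never_expressed"))))
  expect_true(all(tr$true_onset_hpf[!is.na(tr$true_onset_hpf)] > 0))
  for (i in seq_len(nrow(tr))) {
    cls <- tr$temporal_class[i]
    if (cls == "zygotic_clear") {
      expect_lt(f[i, 1], 1)
      first <- hours[which(f[i, ] > 3)[1]]
      expect_equal(first, tr$true_onset_hpf[i])
    } else if (cls == "maternal_dip_rise") {
      expect_gt(f[i, 1], 3)
      win <- f[i, hours %in% c(6, 8, 10)]
      expect_lt(min(win), f[i, 1])
    } else if (cls == "maternal_only") {
      expect_gt(f[i, 1], 3)
    } else if (cls == "never_expressed") {
      expect_true(all(f[i, ] < 3))
    } else if (cls == "ambiguous_t0") {
      expect_true(f[i, 1] >= 1 && f[i, 1] <= 3)
    }
  }
})

test_that("ortholog pairs are mutual top hits and decoys are one-directional", {
  b <- simulate_dataset(small_config(n_genes = 200, seed = 5))
  rbh <- reciprocal_best_hits(b$hits_ab, b$hits_ba)
  truth_pairs <- b$truth[b$truth$ortholog_status == "ortholog", ]
  expect_setequal(rbh$species_a_id, truth_pairs$gene_id)
  expect_equal(
    rbh$species_b_id[match(truth_pairs$gene_id, rbh$species_a_id)],
    truth_pairs$ortholog_partner
  )
  decoys <- b$truth$gene_id[b$truth$ortholog_status == "decoy"]
  expect_gt(length(decoys), 0)
  # decoys have a forward top hit but never a reciprocal pair
  expect_true(all(decoys %in% b$hits_ab$query_id))
  expect_false(any(decoys %in% rbh$species_a_id))
})

test_that("realized temporal-class counts are consistent with the configured weights", {
  counts <- c(maternal_only = 0, zygotic_clear = 0, maternal_dip_rise = 0,
              ambiguous_t0 = 0, never_expressed = 0)
  n_per <- 150
  seeds <- 1:20
  for (s in seeds) {
    b <- simulate_dataset(small_config(n_genes = n_per, seed = s))
    tab <- table(b$truth$temporal_class)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  w <- simulation_config()$class_weights_temporal[names(counts)]
  p <- stats::chisq.test(counts, p = w)$p.value
  expect_gt(p, 0.001)
})
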
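#' Configuration for the synthetic screening dataset
#'
#' Defines the study conditions the generator emulates: catalog size, the
#' share of regulatory genes, the split of the catalog into housekeeping /
#' lineage-restricted / undetected genes, how many lineages restricted
#' genes occupy, the mix of temporal transcript classes, expression scales
#' and multiplicative noise. Defaults mirror the proportions observed in
#' the sea urchin screen this package implements (e.g. ~3% regulatory
#' genes, 56/16/28% undetected/housekeeping/restricted, a maternal-heavy
#' temporal mix) with a lognormal noise sd of 0.2 on cluster averages and
#' FPKM replicates.
#'
#' @param n_genes Number of species-A genes (at least 5).
#' @param fraction_regulatory Probability a gene carries a regulatory
#'   (TF/signaling) domain.
#' @param fraction_housekeeping,fraction_restricted,fraction_undetected
#'   Lineage-category proportions; must sum to 1.
#' @param lineage_count_weights Weights for 1-6 occupied lineages among
#'   restricted genes (normalized internally).
#' @param class_weights_temporal Named proportions for the temporal
#'   classes `maternal_only`, `zygotic_clear`, `maternal_dip_rise`,
#'   `ambiguous_t0`, `never_expressed`; must sum to 1.
#' @param expressed_mean,background_mean Cluster-average scales for
#'   expressed vs non-expressed lineages (expressed above, background
#'   below the 0.3 calling threshold).
#' @param noise_sd Lognormal sd (sdlog) applied multiplicatively to
#'   cluster averages and to each FPKM replicate value; 0 gives exact
#'   class means.
#' @param fpkm_high,fpkm_low Plateau FPKM for expressed genes and baseline
#'   FPKM for silent genes/timepoints.
#' @param onset_grid Sampling hours; must be strictly increasing, start
#'   at 0 and jump to 6.
#' @param fraction_ortholog Probability a gene gets a reciprocal
#'   cross-species partner.
#' @param fraction_decoy Probability a gene is a decoy: a one-directional
#'   top hit at 90% of a true pair's bitscore, excluded by the reciprocal
#'   criterion. `fraction_ortholog + fraction_decoy` must not exceed 1.
#' @param cells_per_cluster Cells per early-stage cluster in the
#'   cell-level matrix.
#' @param coexpression_fraction Fraction of precursor-cluster cells in
#'   which a precursor-expressed gene is on (deterministic leading block,
#'   so any planted pair coexpresses in exactly this fraction).
#' @param n_replicates Temporal replicates (averaged downstream).
#' @param seed Integer seed; the whole bundle is a pure function of the
#'   configuration.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 2000,
                              fraction_regulatory = 0.03,
                              fraction_housekeeping = 0.16,
                              fraction_restricted = 0.28,
                              fraction_undetected = 0.56,
                              lineage_count_weights = c(1058, 507, 494, 329, 348, 327),
                              class_weights_temporal = c(maternal_only = 0.55,
                                                         zygotic_clear = 0.17,
                                                         maternal_dip_rise = 0.05,
                                                         ambiguous_t0 = 0.13,
                                                         never_expressed = 0.10),
                              expressed_mean = 1,
                              background_mean = 0.05,
                              noise_sd = 0.2,
                              fpkm_high = 10,
                              fpkm_low = 0.2,
                              onset_grid = time_grid(),
                              fraction_ortholog = 0.9,
                              fraction_decoy = 0.05,
                              cells_per_cluster = 40,
                              coexpression_fraction = 0.6,
                              n_replicates = 3,
                              seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              fraction_regulatory = fraction_regulatory,
              fraction_housekeeping = fraction_housekeeping,
              fraction_restricted = fraction_restricted,
              fraction_undetected = fraction_undetected,
              lineage_count_weights = lineage_count_weights,
              class_weights_temporal = class_weights_temporal,
              expressed_mean = expressed_mean,
              background_mean = background_mean,
              noise_sd = noise_sd,
              fpkm_high = fpkm_high, fpkm_low = fpkm_low,
              onset_grid = onset_grid,
              fraction_ortholog = fraction_ortholog,
              fraction_decoy = fraction_decoy,
              cells_per_cluster = as.integer(cells_per_cluster),
              coexpression_fraction = coexpression_fraction,
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

temporal_classes <- function() {
  c("maternal_only", "zygotic_clear", "maternal_dip_rise", "ambiguous_t0",
    "never_expressed")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < length(temporal_classes())) {
    abort("n_genes must be at least the number of planted temporal classes (5)")
  }
  lin_frac <- cfg$fraction_housekeeping + cfg$fraction_restricted +
    cfg$fraction_undetected
  if (abs(lin_frac - 1) > 1e-9) {
    abort("fraction_housekeeping + fraction_restricted + fraction_undetected must sum to 1")
  }
  if (abs(sum(cfg$class_weights_temporal) - 1) > 1e-9) {
    abort("class_weights_temporal must sum to 1")
  }
  if (!identical(sort(names(cfg$class_weights_temporal)),
                 sort(temporal_classes()))) {
    abort("class_weights_temporal must be named with the five temporal classes")
  }
  if (length(cfg$lineage_count_weights) != 6 ||
      any(cfg$lineage_count_weights < 0) ||
      sum(cfg$lineage_count_weights) <= 0) {
    abort("lineage_count_weights must be 6 nonnegative weights with positive sum")
  }
  if (cfg$fraction_regulatory < 0 || cfg$fraction_regulatory > 1) {
    abort("fraction_regulatory must lie in [0, 1]")
  }
  if (cfg$fraction_ortholog + cfg$fraction_decoy > 1 + 1e-9 ||
      cfg$fraction_ortholog < 0 || cfg$fraction_decoy < 0) {
    abort("fraction_ortholog and fraction_decoy must be nonnegative and sum to at most 1")
  }
  stopifnot(cfg$expressed_mean > 0, cfg$background_mean >= 0,
            cfg$noise_sd >= 0, cfg$fpkm_high > 0, cfg$fpkm_low >= 0,
            cfg$cells_per_cluster >= 1, cfg$n_replicates >= 1,
            cfg$coexpression_fraction >= 0, cfg$coexpression_fraction <= 1)
  grid <- cfg$onset_grid
  if (is.unsorted(grid, strictly = TRUE) || grid[1] != 0 || length(grid) < 3) {
    abort("onset_grid must be strictly increasing and start at 0")
  }
  invisible(cfg)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# maternal decay scale (> maternal threshold at t0) and decay rate for the
# maternal-only and dip-rise trajectory shapes
.maternal_t0 <- 6
.maternal_decay_rate <- 0.2
.maternal_slow_decay_rate <- 0.05
.ambiguous_t0_level <- 2

# deterministic class-mean trajectory on the grid (no noise)
class_trajectory <- function(class, onset, grid, cfg) {
  low <- rep(cfg$fpkm_low, length(grid))
  switch(class,
    never_expressed = low,
    maternal_only = cfg$fpkm_high * exp(-.maternal_slow_decay_rate * grid),
    zygotic_clear = ifelse(grid >= onset, cfg$fpkm_high, cfg$fpkm_low),
    ambiguous_t0 = {
      v <- ifelse(grid >= onset, cfg$fpkm_high, cfg$fpkm_low)
      v[grid == 0] <- .ambiguous_t0_level
      v
    },
    maternal_dip_rise = .maternal_t0 * exp(-.maternal_decay_rate * grid) +
      ifelse(grid >= onset, cfg$fpkm_high, 0),
    abort(paste0("unknown temporal class: ", class))
  )
}

lognoise <- function(n, sd) {
  if (sd == 0) rep(1, n) else exp(stats::rnorm(n, mean = 0, sd = sd))
}

#' Simulate a full synthetic screening bundle with known ground truth
#'
#' Generates every input the screening cascade consumes — two gene
#' catalogs, a domain-hit table, two directed pairwise hit tables,
#' cluster-averaged single-cell expression at the early blastula and
#' early gastrula stages, a cell-level early-stage matrix with cluster
#' assignments, and replicate-level temporal FPKM matrices — together
#' with the per-gene truth (regulatory status, ortholog partner, lineage
#' set, temporal class, true onset hour). With `noise_sd = 0` every
#' downstream stage recovers the truth exactly; for a fixed configuration
#' the bundle is byte-reproducible.
#'
#' @param config A [simulation_config()] object.
#'
#' @return An object of class `effector_bundle`: a list with elements
#'   `config`, `catalog_a`, `catalog_b`, `domain_hits`, `hits_ab`,
#'   `hits_ba`, `cluster_avg_eg`, `cluster_avg_eb`, `cells_eb`,
#'   `cell_clusters_eb`, `lineage_map`, `precursor_map`,
#'   `temporal_replicates` (list) and `truth`.
#' @export
#'
#' @examples
#' bundle <- simulate_dataset(simulation_config(n_genes = 50, seed = 7))
#' bundle$truth
simulate_dataset <- function(config = simulation_config()) {
  validate_sim_config(config)
  with_seed(config$seed, build_bundle(config))
}

build_bundle <- function(cfg) {
  n <- cfg$n_genes
  grid <- cfg$onset_grid
  ids_a <- sprintf("HpSim%05d", seq_len(n))
  ids_b <- sprintf("SpSim%05d", seq_len(n))

  # --- per-gene truth ------------------------------------------------
  is_regulatory <- stats::runif(n) < cfg$fraction_regulatory
  orth_draw <- stats::runif(n)
  ortholog_status <- ifelse(orth_draw < cfg$fraction_ortholog, "ortholog",
                     ifelse(orth_draw < cfg$fraction_ortholog + cfg$fraction_decoy,
                            "decoy", "none"))
  lineage_category <- sample(c("housekeeping", "restricted", "undetected"),
                             n, replace = TRUE,
                             prob = c(cfg$fraction_housekeeping,
                                      cfg$fraction_restricted,
                                      cfg$fraction_undetected))
  lineage_set <- purrr::map(seq_len(n), function(i) {
    switch(lineage_category[i],
           housekeeping = lineage_levels(),
           undetected = character(0),
           restricted = {
             k <- sample.int(6, 1, prob = cfg$lineage_count_weights)
             lineage_levels()[sort(sample.int(7, k))]
           })
  })
  temporal_class <- sample(temporal_classes(), n, replace = TRUE,
                           prob = unname(cfg$class_weights_temporal[temporal_classes()]))
  zyg_hours <- grid[grid >= 6]
  dip_hours <- grid[grid >= 8]  # a dip needs at least one earlier embryonic point
  true_onset <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    true_onset[i] <- switch(temporal_class[i],
      zygotic_clear = sample(zyg_hours, 1),
      ambiguous_t0 = sample(zyg_hours, 1),
      maternal_dip_rise = sample(dip_hours, 1),
      NA_real_)
  }

  truth <- tibble::tibble(
    gene_id = ids_a,
    ortholog_partner = ifelse(ortholog_status == "ortholog", ids_b, NA_character_),
    ortholog_status = ortholog_status,
    is_regulatory = is_regulatory,
    lineage_category = lineage_category,
    n_lineages = lengths(lineage_set),
    lineage_set = lineage_set,
    temporal_class = temporal_class,
    true_onset_hpf = true_onset
  )

  # --- domain hits ---------------------------------------------------
  doms <- regulatory_domain_list()
  all_reg_acc <- c(doms$tf_accessions, doms$signaling_accessions)
  decoy_acc <- sprintf("PF999%02d", 1:10)  # off-list domains
  hit_rows <- purrr::map_dfr(seq_len(n), function(i) {
    rows <- NULL
    if (is_regulatory[i]) {
      rows <- tibble::tibble(gene_id = ids_a[i],
                             domain_accession = sample(all_reg_acc, 1),
                             e_value = 10^stats::runif(1, -50, -10),
                             score = stats::runif(1, 50, 300))
    } else {
      u <- stats::runif(1)
      if (u < 0.10) {            # off-list structural domain
        rows <- tibble::tibble(gene_id = ids_a[i],
                               domain_accession = sample(decoy_acc, 1),
                               e_value = 10^stats::runif(1, -50, -10),
                               score = stats::runif(1, 50, 300))
      } else if (u < 0.15) {     # regulatory domain, insignificant e-value
        rows <- tibble::tibble(gene_id = ids_a[i],
                               domain_accession = sample(all_reg_acc, 1),
                               e_value = 10^stats::runif(1, -4, -1),
                               score = stats::runif(1, 5, 15))
      }
    }
    rows
  })

  # --- pairwise hit tables ------------------------------------------
  pair_bits <- stats::runif(n, 200, 800)
  orth_idx <- which(ortholog_status == "ortholog")
  decoy_idx <- which(ortholog_status == "decoy")
  hits_ab <- tibble::tibble(query_id = ids_a[orth_idx],
                            subject_id = ids_b[orth_idx],
                            bitscore = round(pair_bits[orth_idx], 1),
                            e_value = 10^(-pair_bits[orth_idx] / 10))
  hits_ba <- tibble::tibble(query_id = ids_b[orth_idx],
                            subject_id = ids_a[orth_idx],
                            bitscore = round(pair_bits[orth_idx] * 0.98, 1),
                            e_value = 10^(-pair_bits[orth_idx] * 0.98 / 10))
  if (length(decoy_idx) > 0 && length(orth_idx) > 0) {
    # decoys: forward top hit onto a true pair's subject at 90% bitscore;
    # the subject's own best hit remains its true partner
    target <- sample(orth_idx, length(decoy_idx), replace = TRUE)
    hits_ab <- dplyr::bind_rows(hits_ab, tibble::tibble(
      query_id = ids_a[decoy_idx],
      subject_id = ids_b[target],
      bitscore = round(pair_bits[target] * 0.9, 1),
      e_value = 10^(-pair_bits[target] * 0.9 / 10)))
    hits_ba <- dplyr::bind_rows(hits_ba, tibble::tibble(
      query_id = ids_b[target],
      subject_id = ids_a[decoy_idx],
      bitscore = round(pair_bits[target] * 0.8, 1),
      e_value = 10^(-pair_bits[target] * 0.8 / 10)))
  }

  # --- cluster-average matrices -------------------------------------
  lmap <- default_lineage_map()
  cluster_avg_eg <- cluster_average_matrix(truth, lmap, cfg)

  # --- early-stage cell-level matrix and its cluster averages -------
  pmap <- default_precursor_map()
  eb <- cell_level_matrix(truth, pmap, cfg)

  # --- temporal replicate matrices ----------------------------------
  base <- t(vapply(seq_len(n), function(i) {
    class_trajectory(temporal_class[i], true_onset[i], grid, cfg)
  }, numeric(length(grid))))
  reps <- purrr::map(seq_len(cfg$n_replicates), function(r) {
    noisy <- base * matrix(lognoise(length(base), cfg$noise_sd), nrow = n)
    out <- tibble::as_tibble(noisy, .name_repair = ~ hour_cols(grid))
    dplyr::bind_cols(tibble::tibble(gene_id = ids_a), out)
  })

  structure(list(config = cfg,
                 catalog_a = tibble::tibble(gene_id = ids_a),
                 catalog_b = tibble::tibble(gene_id = ids_b),
                 domain_hits = hit_rows,
                 hits_ab = hits_ab, hits_ba = hits_ba,
                 cluster_avg_eg = cluster_avg_eg,
                 cluster_avg_eb = eb$cluster_avg,
                 cells_eb = eb$cells,
                 cell_clusters_eb = eb$clusters,
                 lineage_map = lmap,
                 precursor_map = default_precursor_map(),
                 temporal_replicates = reps,
                 truth = truth),
            class = "effector_bundle")
}

cluster_average_matrix <- function(truth, lmap, cfg) {
  clusters <- lmap$cluster_id
  means <- vapply(seq_len(nrow(truth)), function(i) {
    expressed <- lmap$lineage %in% truth$lineage_set[[i]]
    ifelse(expressed, cfg$expressed_mean, cfg$background_mean)
  }, numeric(length(clusters)))
  vals <- t(means) * matrix(lognoise(length(means), cfg$noise_sd),
                            nrow = nrow(truth))
  out <- tibble::as_tibble(vals, .name_repair = ~ as.character(clusters))
  dplyr::bind_cols(truth["gene_id"], out)
}

# Early-stage cells: two precursor clusters (Veg2, Veg1) plus a catch-all
# cluster so averages are defined for every cell. A gene is "on" in a
# precursor cluster when its lineage set touches that cluster's pair of
# descendant lineages; on-genes occupy the leading block of
# coexpression_fraction * cells_per_cluster cells.
cell_level_matrix <- function(truth, pmap, cfg) {
  ncell <- cfg$cells_per_cluster
  cluster_ids <- c(unique(pmap$precursor_cluster), "Other")
  cells <- purrr::map(cluster_ids, function(cl) {
    sprintf("cell_%s_%03d", cl, seq_len(ncell))
  })
  names(cells) <- cluster_ids
  assignments <- tibble::tibble(cell_id = unlist(cells, use.names = FALSE),
                                cluster_id = rep(cluster_ids, each = ncell))
  n_on <- max(1L, ceiling(cfg$coexpression_fraction * ncell))
  mat <- matrix(0, nrow = nrow(truth), ncol = nrow(assignments),
                dimnames = list(NULL, assignments$cell_id))
  for (cl in cluster_ids) {
    if (cl == "Other") {
      descendants <- lineage_levels()
    } else {
      rows <- pmap[pmap$precursor_cluster == cl, ]
      descendants <- unique(c(rows$lineage_a, rows$lineage_b))
    }
    on_gene <- vapply(truth$lineage_set,
                      function(s) any(descendants %in% s), logical(1))
    cols <- cells[[cl]][seq_len(n_on)]
    if (any(on_gene)) {
      vals <- cfg$expressed_mean *
        lognoise(sum(on_gene) * n_on, cfg$noise_sd)
      mat[on_gene, cols] <- matrix(vals, ncol = n_on)
    }
  }
  cells_tbl <- dplyr::bind_cols(
    truth["gene_id"],
    tibble::as_tibble(mat, .name_repair = "minimal")
  )
  cluster_avg <- average_by_cluster(cells_tbl, assignments)
  list(cells = cells_tbl, clusters = assignments, cluster_avg = cluster_avg)
}

#' @export
print.effector_bundle <- function(x, ...) {
  cat("<effector_bundle>\n")
  cat("  genes:", nrow(x$catalog_a), " seed:", x$config$seed,
      " noise_sd:", x$config$noise_sd, "\n")
  cat("  temporal classes:",
      paste(names(table(x$truth$temporal_class)),
            table(x$truth$temporal_class), collapse = ", "), "\n")
  invisible(x)
}
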
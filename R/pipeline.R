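#' Run the full effector-gene screening cascade
#'
#' Executes the screening stages in order on a bundle of inputs:
#' (1) remove regulatory genes by Pfam domain content, (2) keep genes
#' with a reciprocal-best-hit ortholog in the reference species,
#' (3) keep genes whose early-gastrula expression is restricted to 1-6
#' of the seven lineages, (4) keep clearly zygotic genes and determine
#' their expression onset (maternal genes with a dip-rise inferred onset
#' are reported separately, not kept), (5) apply a user-supplied
#' post-hoc exclusion list (regulatory genes recognized at the manual
#' annotation stage). Every removal is accounted for in the funnel
#' report and conservation (`n_in = n_out + n_removed`, chained) is
#' asserted at each stage.
#'
#' @param bundle An `effector_bundle` ([simulate_dataset()] /
#'   [read_bundle()]) or any list with elements `catalog_a`, `catalog_b`,
#'   `domain_hits`, `hits_ab`, `hits_ba`, `cluster_avg_eg`, `lineage_map`
#'   and `temporal_replicates` (list of replicate FPKM tibbles).
#' @param domains [regulatory_domain_list()] used for the domain filter.
#' @param evalue_max Domain-hit significance cutoff.
#' @param lineage_threshold Cluster-average expression cutoff (strict)
#'   for lineage calling.
#' @param expr_threshold FPKM detection/onset cutoff (strict).
#' @param maternal_threshold 0-hpf FPKM above which a transcript is
#'   maternal.
#' @param zygotic_t0_max 0-hpf FPKM below which a gene is clearly
#'   zygotic.
#' @param early_window Hours scanned by the dip-rise rule.
#' @param exclusion_ids Gene ids excluded post hoc (annotation stage).
#'
#' @return An object of class `effector_pipeline`: list with `records`
#'   (per-gene joined table over the whole catalog), `funnel` (stage
#'   accounting), `lineage_calls`, `onset_calls`, `ortholog_map` and
#'   `params`.
#' @export
run_pipeline <- function(bundle,
                         domains = regulatory_domain_list(),
                         evalue_max = 1e-5,
                         lineage_threshold = 0.3,
                         expr_threshold = 3,
                         maternal_threshold = 3,
                         zygotic_t0_max = 1,
                         early_window = c(6, 8, 10),
                         exclusion_ids = character()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  regs <- stage("domain_filter",
                classify_regulatory(bundle$catalog_a, bundle$domain_hits,
                                    domains, evalue_max))
  orth <- stage("reciprocal_best_hits",
                reciprocal_best_hits(bundle$hits_ab, bundle$hits_ba))
  lin <- stage("lineage_restriction",
               call_lineages(bundle$cluster_avg_eg, bundle$lineage_map,
                             threshold = lineage_threshold))
  fpkm <- stage("average_replicates",
                average_replicates(bundle$temporal_replicates))
  ons <- stage("onset_calling",
               call_onset(fpkm, expr_threshold = expr_threshold,
                          maternal_threshold = maternal_threshold,
                          zygotic_t0_max = zygotic_t0_max,
                          early_window = early_window))

  records <- regs %>%
    dplyr::left_join(orth, by = c(gene_id = "species_a_id")) %>%
    dplyr::rename(ortholog_id = "species_b_id") %>%
    dplyr::left_join(lin, by = "gene_id") %>%
    dplyr::left_join(ons, by = "gene_id") %>%
    dplyr::mutate(post_hoc_excluded = .data$gene_id %in% exclusion_ids)

  keep0 <- records$gene_id
  keep1 <- records$gene_id[!records$regulatory]
  r1 <- records[records$gene_id %in% keep1, ]
  keep2 <- r1$gene_id[!is.na(r1$ortholog_id)]
  r2 <- records[records$gene_id %in% keep2, ]
  keep3a <- r2$gene_id[!is.na(r2$category) & r2$category != "undetected"]
  r3a <- records[records$gene_id %in% keep3a, ]
  keep3 <- r3a$gene_id[r3a$category == "restricted"]
  r3 <- records[records$gene_id %in% keep3, ]
  keep4a <- r3$gene_id[r3$detected %in% TRUE]
  r4a <- records[records$gene_id %in% keep4a, ]
  keep4b <- r4a$gene_id[r4a$origin != "maternal"]
  r4b <- records[records$gene_id %in% keep4b, ]
  keep4 <- r4b$gene_id[r4b$origin == "zygotic_clear"]
  r4 <- records[records$gene_id %in% keep4, ]
  keep5 <- r4$gene_id[!r4$post_hoc_excluded]

  funnel <- tibble::tibble(
    stage = c("domain_filter", "rbh_restriction", "lineage_detected",
              "lineage_restricted", "timecourse_detected",
              "zygotic_origin", "unambiguous_t0", "posthoc_exclusion"),
    removed_as = c("regulatory", "no_reciprocal_ortholog",
                   "undetected_in_clusters", "ubiquitous",
                   "undetected_on_timecourse", "maternal_origin",
                   "ambiguous_t0", "posthoc_regulatory"),
    n_in = c(length(keep0), length(keep1), length(keep2), length(keep3a),
             length(keep3), length(keep4a), length(keep4b), length(keep4)),
    n_out = c(length(keep1), length(keep2), length(keep3a), length(keep3),
              length(keep4a), length(keep4b), length(keep4), length(keep5))
  ) %>%
    dplyr::mutate(n_removed = .data$n_in - .data$n_out)
  check_funnel(funnel)

  records <- records %>%
    dplyr::mutate(effector = .data$gene_id %in% keep5)

  structure(list(records = records, funnel = funnel,
                 lineage_calls = lin, onset_calls = ons,
                 ortholog_map = orth,
                 params = list(evalue_max = evalue_max,
                               lineage_threshold = lineage_threshold,
                               expr_threshold = expr_threshold,
                               maternal_threshold = maternal_threshold,
                               zygotic_t0_max = zygotic_t0_max,
                               early_window = early_window,
                               n_exclusions = length(exclusion_ids))),
            class = "effector_pipeline")
}

check_funnel <- function(funnel) {
  stopifnot(all(funnel$n_in - funnel$n_removed == funnel$n_out))
  if (nrow(funnel) > 1) {
    stopifnot(all(funnel$n_out[-nrow(funnel)] == funnel$n_in[-1]))
  }
  invisible(funnel)
}

#' Cross-tabulate zygotic onset against lineage occupancy
#'
#' Counts onset-resolved effector records by onset hour and either the
#' number of occupied lineages or (for single-lineage genes) the lineage
#' itself.
#'
#' @param records Record table from [run_pipeline()] (its `records`
#'   element or the whole object).
#' @param by `"n_lineages"` for all effectors, `"lineage"` for the
#'   single-lineage subset.
#'
#' @return Tidy tibble of counts: `onset_hpf`, grouping column, `n`.
#' @export
onset_histogram <- function(records, by = c("n_lineages", "lineage")) {
  by <- match.arg(by)
  if (inherits(records, "effector_pipeline")) records <- records$records
  eff <- records %>%
    dplyr::filter(.data$effector %in% TRUE, !is.na(.data$onset_hpf))
  if (by == "n_lineages") {
    out <- eff %>%
      dplyr::count(.data$onset_hpf, .data$n_lineages, name = "n")
  } else {
    out <- eff %>%
      dplyr::filter(.data$n_lineages == 1) %>%
      dplyr::mutate(lineage = purrr::map_chr(.data$lineage_set, 1)) %>%
      dplyr::count(.data$onset_hpf, .data$lineage, name = "n")
  }
  out
}

#' @export
print.effector_pipeline <- function(x, ...) {
  cat("<effector_pipeline>\n")
  print(x$funnel)
  cat("effector genes:", sum(x$records$effector), "of",
      nrow(x$records), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-gene record table of a pipeline run
#'
#' @param x An `effector_pipeline`.
#' @param ... Unused.
#' @return The per-gene record tibble (one row per catalog gene).
#' @export
tidy.effector_pipeline <- function(x, ...) {
  x$records
}

#' One-row summary of a pipeline run
#'
#' Reports the catalog size, stage survivors and, because the reciprocal
#' ortholog count and the candidate-intersect-ortholog count answer
#' different questions, both numbers.
#'
#' @param x An `effector_pipeline`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.effector_pipeline <- function(x, ...) {
  f <- x$funnel
  n_out <- function(s) f$n_out[f$stage == s]
  tibble::tibble(
    n_genes = f$n_in[1],
    n_regulatory = f$n_removed[f$stage == "domain_filter"],
    n_rbh_pairs = nrow(x$ortholog_map),
    n_candidates_with_ortholog = n_out("rbh_restriction"),
    n_restricted = n_out("lineage_restricted"),
    n_zygotic_clear = n_out("unambiguous_t0"),
    n_effectors = n_out("posthoc_exclusion")
  )
}
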
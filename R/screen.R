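#' Pfam domains used to flag regulatory genes
#'
#' The default domain lists used to separate regulatory genes
#' (transcription factors and cell-signaling molecules) from the
#' candidate effector pool. Accessions are stored unversioned
#' ("PF01388", not "PF01388.17"); matching against hit tables strips
#' version suffixes on both sides.
#'
#' @param tf_accessions Character vector of Pfam accessions marking
#'   transcription-factor domains.
#' @param signaling_accessions Character vector of Pfam accessions marking
#'   cell-signaling domains. Must be disjoint from `tf_accessions`.
#'
#' @return An object of class `regulatory_domains`: a list with elements
#'   `tf_accessions` and `signaling_accessions`.
#' @export
#'
#' @examples
#' doms <- regulatory_domain_list()
#' length(doms$tf_accessions)
regulatory_domain_list <- function(tf_accessions = default_tf_accessions(),
                                   signaling_accessions = default_signaling_accessions()) {
  tf <- strip_pfam_version(unique(tf_accessions))
  sig <- strip_pfam_version(unique(signaling_accessions))
  overlap <- intersect(tf, sig)
  if (length(overlap) > 0) {
    abort(paste0("tf and signaling accession sets must be disjoint; shared: ",
                 paste(overlap, collapse = ", ")))
  }
  structure(list(tf_accessions = tf, signaling_accessions = sig),
            class = "regulatory_domains")
}

#' @rdname regulatory_domain_list
#' @export
default_tf_accessions <- function() {
  c("PF01388", "PF02178", "PF01586", "PF02376", "PF00751", "PF00178",
    "PF00250", "PF00320", "PF03615", "PF00010", "PF00505", "PF07527",
    "PF00046", "PF00104", "PF03826", "PF00870", "PF07710", "PF00292",
    "PF00157", "PF05044", "PF00554", "PF00853", "PF02023", "PF06621",
    "PF00319", "PF00907", "PF12598", "PF03299", "PF03529", "PF00170",
    "PF07716", "PF00096", "PF01530", "PF00105")
}

#' @rdname regulatory_domain_list
#' @export
default_signaling_accessions <- function() {
  c("PF04709", "PF05337", "PF02262", "PF02761", "PF02762", "PF01584",
    "PF00778", "PF02377", "PF00167", "PF03623", "PF00631", "PF01109",
    "PF01627", "PF07400", "PF03039", "PF00715", "PF02059", "PF00727",
    "PF02025", "PF01415", "PF00015", "PF03000", "PF06554", "PF00341",
    "PF04692", "PF06404", "PF01091", "PF05196", "PF08916", "PF00615",
    "PF03528", "PF01017", "PF02864", "PF02865", "PF00019", "PF00688",
    "PF09034", "PF00110")
}

strip_pfam_version <- function(x) sub("\\.[0-9]+$", "", x)

#' Partition a gene catalog into regulatory and candidate-effector genes
#'
#' A gene is called regulatory when it carries at least one significant
#' hit (e-value at or below `evalue_max`) to a transcription-factor or
#' signaling Pfam domain. All other catalog genes are candidate effectors.
#'
#' @param catalog Data frame with a `gene_id` column (one row per gene),
#'   or a character vector of gene ids.
#' @param hits Domain hit table: data frame with columns `gene_id`,
#'   `domain_accession`, `e_value` (and optionally `score`).
#' @param domains A [regulatory_domain_list()] object.
#' @param evalue_max Significance cutoff on the hit e-value (inclusive).
#'
#' @return A tibble with one row per catalog gene, in catalog order:
#'   `gene_id`, `regulatory` (logical), `reason` (`"tf"`, `"signaling"`,
#'   `"both"` or `"none"`).
#' @export
#'
#' @examples
#' cat <- tibble::tibble(gene_id = c("g1", "g2"))
#' hits <- tibble::tibble(gene_id = "g1", domain_accession = "PF00046",
#'                        e_value = 1e-12)
#' classify_regulatory(cat, hits)
classify_regulatory <- function(catalog, hits,
                                domains = regulatory_domain_list(),
                                evalue_max = 1e-5) {
  if (!is.numeric(evalue_max) || evalue_max <= 0) {
    abort("evalue_max must be a positive number")
  }
  ids <- catalog_ids(catalog)
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) > 0) {
    unknown <- setdiff(unique(hits$gene_id), ids)
    if (length(unknown) > 0) {
      abort(paste0("domain hits reference genes absent from the catalog: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  sig <- hits %>%
    dplyr::filter(.data$e_value <= evalue_max) %>%
    dplyr::mutate(acc = strip_pfam_version(.data$domain_accession)) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      tf = any(.data$acc %in% domains$tf_accessions),
      signaling = any(.data$acc %in% domains$signaling_accessions),
      .groups = "drop"
    )
  tibble::tibble(gene_id = ids) %>%
    dplyr::left_join(sig, by = "gene_id") %>%
    dplyr::mutate(
      tf = dplyr::coalesce(.data$tf, FALSE),
      signaling = dplyr::coalesce(.data$signaling, FALSE),
      regulatory = .data$tf | .data$signaling,
      reason = dplyr::case_when(
        .data$tf & .data$signaling ~ "both",
        .data$tf ~ "tf",
        .data$signaling ~ "signaling",
        TRUE ~ "none"
      )
    ) %>%
    dplyr::select("gene_id", "regulatory", "reason")
}

catalog_ids <- function(catalog) {
  ids <- if (is.data.frame(catalog)) catalog$gene_id else as.character(catalog)
  if (is.null(ids)) abort("catalog must have a gene_id column")
  if (anyDuplicated(ids)) abort("catalog gene ids must be unique")
  ids
}

# reduce a pairwise hit table to one best subject per query:
# max bitscore, ties -> min e-value, then lexicographically smallest subject
best_hit_per_query <- function(hits) {
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0) {
    return(tibble::tibble(query_id = character(), subject_id = character()))
  }
  hits %>%
    # multiple HSP rows for one (query, subject): keep the strongest
    dplyr::arrange(dplyr::desc(.data$bitscore), .data$e_value) %>%
    dplyr::distinct(.data$query_id, .data$subject_id, .keep_all = TRUE) %>%
    # then the best subject per query, with the deterministic tie order
    dplyr::arrange(dplyr::desc(.data$bitscore), .data$e_value,
                   .data$subject_id) %>%
    dplyr::distinct(.data$query_id, .keep_all = TRUE) %>%
    dplyr::select("query_id", "subject_id")
}

#' Ortholog pairing by reciprocal best hits
#'
#' Pair (a, b) is an ortholog call when b is a's top-scoring subject in
#' the a-to-b hit table and a is b's top-scoring subject in the b-to-a
#' table. The best hit is the maximum-bitscore row; ties are broken by
#' minimum e-value, then by lexicographically smallest subject id, so the
#' result is invariant under row permutation of the inputs.
#'
#' @param hits_ab,hits_ba Pairwise hit tables (data frames with columns
#'   `query_id`, `subject_id`, `bitscore`, `e_value`), queries of species A
#'   against species B and vice versa.
#'
#' @return A tibble with columns `species_a_id`, `species_b_id`; each id
#'   occurs in at most one pair.
#' @export
#'
#' @examples
#' ab <- tibble::tibble(query_id = "a1", subject_id = "b1",
#'                      bitscore = 100, e_value = 1e-30)
#' ba <- tibble::tibble(query_id = "b1", subject_id = "a1",
#'                      bitscore = 98, e_value = 1e-28)
#' reciprocal_best_hits(ab, ba)
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  top_ab <- best_hit_per_query(hits_ab)
  top_ba <- best_hit_per_query(hits_ba)
  dplyr::inner_join(
    top_ab,
    top_ba,
    by = c(query_id = "subject_id", subject_id = "query_id")
  ) %>%
    dplyr::transmute(species_a_id = .data$query_id,
                     species_b_id = .data$subject_id) %>%
    dplyr::arrange(.data$species_a_id)
}

#' Keep only candidates that have a cross-species ortholog
#'
#' @param candidate_ids Character vector of candidate gene ids (species A).
#' @param ortholog_map Tibble from [reciprocal_best_hits()].
#'
#' @return The subset of `candidate_ids` present in the map's species-A
#'   column, in input order.
#' @export
restrict_to_orthologs <- function(candidate_ids, ortholog_map) {
  candidate_ids[candidate_ids %in% ortholog_map$species_a_id]
}
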
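# Independent brute-force reimplementations of the screening rules,
# written as plain loops so they share no code path with the package.

oracle_classify_regulatory <- function(ids, hits, tf, sig, evalue_max) {
  out <- data.frame(gene_id = ids, regulatory = FALSE, reason = "none",
                    stringsAsFactors = FALSE)
  strip <- function(x) sub("\\.[0-9]+$", "", x)
  for (i in seq_along(ids)) {
    h <- hits[hits$gene_id == ids[i] & hits$e_value <= evalue_max, ]
    has_tf <- FALSE
    has_sig <- FALSE
    for (j in seq_len(nrow(h))) {
      acc <- strip(h$domain_accession[j])
      if (acc %in% strip(tf)) has_tf <- TRUE
      if (acc %in% strip(sig)) has_sig <- TRUE
    }
    out$regulatory[i] <- has_tf || has_sig
    out$reason[i] <- if (has_tf && has_sig) "both" else if (has_tf) "tf" else
      if (has_sig) "signaling" else "none"
  }
  out
}

# best subject of one query under (bitscore desc, e-value asc, subject asc)
oracle_best_subject <- function(tbl, q) {
  rows <- tbl[tbl$query_id == q, ]
  if (nrow(rows) == 0) return(NA_character_)
  # collapse repeated (query, subject) rows to their strongest HSP
  subj <- unique(rows$subject_id)
  bs <- ev <- numeric(length(subj))
  for (k in seq_along(subj)) {
    r <- rows[rows$subject_id == subj[k], ]
    r <- r[order(-r$bitscore, r$e_value), ]
    bs[k] <- r$bitscore[1]
    ev[k] <- r$e_value[1]
  }
  o <- order(-bs, ev, subj)
  subj[o[1]]
}

oracle_rbh <- function(ab, ba) {
  pairs <- list()
  for (a in sort(unique(ab$query_id))) {
    b <- oracle_best_subject(ab, a)
    if (!is.na(b) && identical(oracle_best_subject(ba, b), a)) {
      pairs[[length(pairs) + 1]] <- c(a, b)
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(species_a_id = character(),
                      species_b_id = character()))
  }
  m <- do.call(rbind, pairs)
  data.frame(species_a_id = m[, 1], species_b_id = m[, 2],
             stringsAsFactors = FALSE)
}

oracle_call_lineages <- function(mat, lmap, threshold) {
  lineages <- unique(lmap$lineage)
  clusters <- as.integer(setdiff(names(mat), "gene_id"))
  res <- vector("list", nrow(mat))
  for (i in seq_len(nrow(mat))) {
    expressed <- character(0)
    for (lin in lineages) {
      members <- lmap$cluster_id[lmap$lineage == lin]
      members <- members[members %in% clusters]
      if (length(members) == 0) next
      vals <- sapply(members, function(cl) mat[[as.character(cl)]][i])
      best <- members[order(-vals, members)][1]
      rep_avg <- mat[[as.character(best)]][i]
      if (rep_avg > threshold) expressed <- c(expressed, lin)
    }
    canonical <- intersect(effectoronset::lineage_levels(), expressed)
    res[[i]] <- list(gene_id = mat$gene_id[i],
                     n_lineages = length(canonical),
                     lineage_set = canonical)
  }
  res
}

oracle_call_onset <- function(fpkm_row, hours, expr_threshold = 3,
                              maternal_threshold = 3, zygotic_t0_max = 1,
                              early_window = c(6, 8, 10)) {
  f0 <- fpkm_row[hours == 0][1]
  if (!any(fpkm_row > expr_threshold)) {
    return(list(origin = "undetected", onset = NA_real_,
                inferred = NA_real_))
  }
  if (f0 > maternal_threshold) {
    wh <- hours[hours %in% early_window]
    wv <- fpkm_row[hours %in% early_window]
    fmin <- min(wv)
    tmin <- wh[which(wv == fmin)[1]]
    inferred <- NA_real_
    if (fmin < f0) {
      for (j in seq_along(hours)) {
        if (hours[j] > tmin && fpkm_row[j] > fmin &&
            fpkm_row[j] > expr_threshold) {
          inferred <- hours[j]
          break
        }
      }
    }
    return(list(origin = "maternal", onset = NA_real_, inferred = inferred))
  }
  if (f0 < zygotic_t0_max) {
    for (j in seq_along(hours)) {
      if (hours[j] >= 6 && fpkm_row[j] > expr_threshold) {
        return(list(origin = "zygotic_clear", onset = hours[j],
                    inferred = NA_real_))
      }
    }
  }
  list(origin = "ambiguous_t0", onset = NA_real_, inferred = NA_real_)
}

oracle_coexpression <- function(cells, assignments, gene_a, gene_b, cluster,
                                expressed_min = 0) {
  cell_ids <- assignments$cell_id[assignments$cluster_id == cluster]
  cell_ids <- cell_ids[cell_ids %in% names(cells)]
  va <- as.numeric(cells[cells$gene_id == gene_a, cell_ids])
  vb <- as.numeric(cells[cells$gene_id == gene_b, cell_ids])
  n_a <- n_b <- n_ab <- 0
  for (k in seq_along(cell_ids)) {
    ea <- va[k] > expressed_min
    eb <- vb[k] > expressed_min
    n_a <- n_a + ea
    n_b <- n_b + eb
    n_ab <- n_ab + (ea && eb)
  }
  list(n_cells = length(cell_ids), n_a = n_a, n_b = n_b, n_ab = n_ab,
       fraction = n_ab / length(cell_ids))
}
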
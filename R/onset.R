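#' Average replicate-level temporal FPKM matrices
#'
#' Element-wise arithmetic mean of replicate matrices sharing the same
#' genes (same order) and time grid.
#'
#' @param replicates List of genes-by-timepoints tibbles (`gene_id` first,
#'   hour columns `h0`, `h6`, ..., `h30`).
#'
#' @return A single tibble of the same shape holding the means.
#' @export
average_replicates <- function(replicates) {
  if (!is.list(replicates) || length(replicates) == 0) {
    abort("replicates must be a non-empty list of matrices")
  }
  ref <- tibble::as_tibble(replicates[[1]])
  check_expr_tbl(ref, "temporal matrix")
  for (r in replicates[-1]) {
    r <- tibble::as_tibble(r)
    if (!identical(names(r), names(ref)) ||
        !identical(r$gene_id, ref$gene_id)) {
      abort("replicates must share identical gene sets, order and time grid")
    }
  }
  vals <- purrr::map(replicates,
                     ~ as.matrix(tibble::as_tibble(.x)[, -1, drop = FALSE]))
  avg <- Reduce(`+`, vals) / length(vals)
  dplyr::bind_cols(ref["gene_id"], tibble::as_tibble(avg))
}

#' Infer zygotic onset of a maternal transcript from a dip-then-rise
#'
#' For a gene whose transcript is maternally deposited (FPKM above
#' `maternal_threshold` at 0 hpf), embryonic transcription can still be
#' inferred when the maternal transcript first decays and the trajectory
#' then re-rises. Let `t_min` be the timepoint of minimum FPKM within the
#' early window (ties broken by the earliest hour). The rule fires when
#' FPKM(t_min) is strictly below FPKM(0) and some later timepoint exceeds
#' both FPKM(t_min) and `expr_threshold`; the inferred onset is the
#' earliest such timepoint.
#'
#' @param fpkm Numeric vector: one gene's replicate-averaged FPKM values.
#' @param hours Numeric vector of the sampling hours, same length as
#'   `fpkm`, containing 0 and the early window.
#' @param early_window Hours scanned for the maternal minimum.
#' @param expr_threshold Expression cutoff the rise must exceed (strict).
#' @param maternal_threshold 0-hpf level above which a transcript counts
#'   as maternal; calling this on a non-maternal trajectory is an error.
#'
#' @return The inferred onset hour, or `NA` when the rule does not fire.
#' @export
#'
#' @examples
#' h <- time_grid()
#' f <- c(3.23, 2.5, 1.86, 4.93, rep(5, 10))
#' infer_dip_rise_onset(f, h)
infer_dip_rise_onset <- function(fpkm, hours = time_grid(),
                                 early_window = c(6, 8, 10),
                                 expr_threshold = 3,
                                 maternal_threshold = 3) {
  if (length(fpkm) != length(hours)) {
    abort("fpkm and hours must have the same length")
  }
  if (!0 %in% hours) abort("hours must contain the 0 hpf timepoint")
  f0 <- fpkm[hours == 0][1]
  if (!(f0 > maternal_threshold)) {
    abort("dip-rise inference applies only to maternal genes (FPKM(0) above the maternal threshold)")
  }
  win <- which(hours %in% early_window)
  if (length(win) == 0) abort("early_window not on the sampling grid")
  t_min <- hours[win][which.min(fpkm[win])]
  f_min <- min(fpkm[win])
  if (!(f_min < f0)) return(NA_real_)
  later <- which(hours > t_min & fpkm > f_min & fpkm > expr_threshold)
  if (length(later) == 0) return(NA_real_)
  hours[min(later)]
}

#' Classify transcript origin and zygotic expression onset
#'
#' On the replicate-averaged genes-by-timepoints FPKM matrix, a gene is
#' `detected` when any value on the grid is strictly above
#' `expr_threshold`. Detected genes are classified by their 0-hpf value:
#' above `maternal_threshold` the transcript is maternal; strictly below
#' `zygotic_t0_max` the gene is clearly zygotic, with onset at the first
#' timepoint whose FPKM strictly exceeds `expr_threshold`; values in
#' between are ambiguous at 0 hpf and receive no onset. For maternal
#' genes a zygotic onset can only be inferred from the dip-then-rise
#' pattern ([infer_dip_rise_onset()]); it is reported in the separate
#' `inferred_onset_hpf` column.
#'
#' @param fpkm Genes-by-timepoints tibble (`gene_id` first, hour columns
#'   `h0`, `h6`, ..., replicate-averaged).
#' @param expr_threshold Detection/onset FPKM cutoff (strict).
#' @param maternal_threshold 0-hpf FPKM above which the transcript is
#'   maternal (strict).
#' @param zygotic_t0_max 0-hpf FPKM below which a gene is clearly zygotic
#'   (strict); must not exceed `expr_threshold`.
#' @param infer_dip_rise Whether to attempt dip-rise onset inference for
#'   maternal genes.
#' @param early_window Hours scanned for the maternal minimum.
#'
#' @return A tibble, one row per gene in input order: `gene_id`,
#'   `detected`, `origin` (`maternal`, `zygotic_clear`, `ambiguous_t0`,
#'   `undetected`), `onset_hpf` (first-crossing onset, zygotic-clear genes
#'   only), `inferred_onset_hpf` (dip-rise onset, maternal genes only) and
#'   `method` (`first_crossing`, `dip_rise`, `undefined`).
#' @export
call_onset <- function(fpkm, expr_threshold = 3, maternal_threshold = 3,
                       zygotic_t0_max = 1, infer_dip_rise = TRUE,
                       early_window = c(6, 8, 10)) {
  check_expr_tbl(fpkm, "temporal matrix")
  stopifnot(expr_threshold >= 0, maternal_threshold >= 0, zygotic_t0_max >= 0)
  if (zygotic_t0_max > expr_threshold) {
    abort("zygotic_t0_max must not exceed expr_threshold")
  }
  hours <- cols_to_hours(setdiff(names(fpkm), "gene_id"))
  if (any(is.na(hours)) || is.unsorted(hours) || !0 %in% hours) {
    abort("temporal columns must be h<hour>, sorted, and include h0")
  }
  mat <- as.matrix(fpkm[, -1, drop = FALSE])
  purrr::map_dfr(seq_len(nrow(mat)), function(i) {
    f <- mat[i, ]
    detected <- any(f > expr_threshold)
    f0 <- f[hours == 0][1]
    origin <- if (!detected) "undetected"
      else if (f0 > maternal_threshold) "maternal"
      else if (f0 < zygotic_t0_max) "zygotic_clear"
      else "ambiguous_t0"
    onset <- NA_real_
    inferred <- NA_real_
    method <- "undefined"
    if (origin == "zygotic_clear") {
      cross <- which(f > expr_threshold & hours >= 6)
      # detected with FPKM(0) < t0-max <= threshold: a crossing at t >= 6 exists
      onset <- hours[min(cross)]
      method <- "first_crossing"
    } else if (origin == "maternal" && infer_dip_rise) {
      inferred <- infer_dip_rise_onset(f, hours, early_window = early_window,
                                       expr_threshold = expr_threshold,
                                       maternal_threshold = maternal_threshold)
      if (!is.na(inferred)) method <- "dip_rise"
    }
    tibble::tibble(gene_id = fpkm$gene_id[i], detected = detected,
                   origin = origin, onset_hpf = onset,
                   inferred_onset_hpf = inferred, method = method)
  })
}
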
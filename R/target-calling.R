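#' Call direct targets from joint expression and binding evidence
#'
#' A gene is called a potential direct target when (i) its Expression Score
#' is at least `es_min`, (ii) a TSS-proximal binding peak was found in at
#' least `chip_min` ChIP datasets, and (iii) both the up-regulation calls and
#' the binding calls come from at least `min_studies` distinct studies. The
#' study rule makes the "observed in data sets from at least two different
#' studies" guarantee explicit rather than relying on it falling out of the
#' dataset thresholds. Typical settings: `chip_min = 3` for a mouse-style
#' panel of 9 p53 ChIP datasets, `chip_min = 5` for a human-style panel
#' of 28.
#'
#' @param expr_scores data.frame from [compute_expression_scores()].
#' @param binding_scores data.frame from [assign_peaks_to_tss()] for the p53
#'   window (genes absent from it count as unbound).
#' @param es_min Minimum Expression Score (default 5).
#' @param chip_min Minimum number of ChIP datasets with a TSS-proximal peak.
#' @param min_studies Minimum distinct studies for each evidence type
#'   (default 2).
#' @return data.frame with one row per scored gene: `gene_id`, `score`,
#'   `n_datasets_bound`, per-criterion logicals (`pass_expression`,
#'   `pass_binding`, `pass_expression_studies`, `pass_binding_studies`) and
#'   `is_direct_target`.
#' @export
call_direct_targets <- function(expr_scores, binding_scores,
                                es_min = 5L, chip_min = 3L, min_studies = 2L) {
  m <- match(expr_scores$gene_id, binding_scores$gene_id)
  nb <- ifelse(is.na(m), 0L, binding_scores$n_datasets_bound[m])
  nbs <- ifelse(is.na(m), 0L, binding_scores$n_studies_bound[m])
  out <- data.frame(
    gene_id = expr_scores$gene_id,
    score = expr_scores$score,
    n_datasets_bound = nb,
    pass_expression = expr_scores$score >= es_min,
    pass_binding = nb >= chip_min,
    pass_expression_studies = expr_scores$n_up_studies >= min_studies,
    pass_binding_studies = nbs >= min_studies,
    stringsAsFactors = FALSE
  )
  out$is_direct_target <- out$pass_expression & out$pass_binding &
    out$pass_expression_studies & out$pass_binding_studies
  out
}

#' Call candidate DREAM-repressed genes
#'
#' Genes strongly down-regulated when p53 is active and bound by E2F4/DREAM
#' near the TSS (1 kb window) are candidates for indirect repression through
#' the p53-p21-DREAM axis. Thresholds mirror the direct-target call
#' symmetrically.
#'
#' @param expr_scores data.frame from [compute_expression_scores()].
#' @param e2f4_binding_scores data.frame from [assign_peaks_to_tss()] for
#'   the E2F4/DREAM window.
#' @param es_max Maximum (most positive) Expression Score (default -5).
#' @param chip_min Minimum number of E2F4/DREAM ChIP datasets (default 3).
#' @param min_studies Minimum distinct studies for each evidence type
#'   (default 2).
#' @return data.frame like [call_direct_targets()], with
#'   `is_dream_candidate` as the final call.
#' @export
call_dream_candidates <- function(expr_scores, e2f4_binding_scores,
                                  es_max = -5L, chip_min = 3L,
                                  min_studies = 2L) {
  m <- match(expr_scores$gene_id, e2f4_binding_scores$gene_id)
  nb <- ifelse(is.na(m), 0L, e2f4_binding_scores$n_datasets_bound[m])
  nbs <- ifelse(is.na(m), 0L, e2f4_binding_scores$n_studies_bound[m])
  out <- data.frame(
    gene_id = expr_scores$gene_id,
    score = expr_scores$score,
    n_datasets_bound = nb,
    pass_expression = expr_scores$score <= es_max,
    pass_binding = nb >= chip_min,
    pass_expression_studies = expr_scores$n_down_studies >= min_studies,
    pass_binding_studies = nbs >= min_studies,
    stringsAsFactors = FALSE
  )
  out$is_dream_candidate <- out$pass_expression & out$pass_binding &
    out$pass_expression_studies & out$pass_binding_studies
  out
}
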
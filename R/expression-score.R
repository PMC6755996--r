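#' Call differential regulation for one gene in one dataset
#'
#' A gene is called up-regulated when `log2fc >= lfc_min` and
#' `adj_p <= p_max`, down-regulated when `log2fc <= -lfc_min` and
#' `adj_p <= p_max`, and not significant (`"ns"`) otherwise. Both thresholds
#' are inclusive.
#'
#' @param log2fc Numeric vector of log2 fold changes (active regulator vs
#'   control).
#' @param adj_p Numeric vector of multiple-testing-adjusted p-values in
#'   `[0, 1]`.
#' @param lfc_min Minimum absolute log2 fold change (default 0.5).
#' @param p_max Maximum adjusted p-value (default 0.05).
#' @return Character vector in `{"up", "down", "ns"}`.
#' @examples
#' call_regulation(c(0.5, -0.6, 0.8), c(0.05, 0.01, 0.2))
#' @export
call_regulation <- function(log2fc, adj_p, lfc_min = 0.5, p_max = 0.05) {
  if (any(!is.finite(log2fc))) stop("non-finite log2fc")
  if (any(!is.finite(adj_p)) || any(adj_p < 0 | adj_p > 1)) {
    stop("adj_p must be finite and in [0, 1]")
  }
  sig <- adj_p <= p_max
  ifelse(sig & log2fc >= lfc_min, "up",
         ifelse(sig & log2fc <= -lfc_min, "down", "ns"))
}

# Per-row verdicts with optional per-dataset threshold overrides. Internal.
dataset_verdicts <- function(calls, dataset_config = NULL,
                             lfc_min = 0.5, p_max = 0.05) {
  lfc_thr <- rep(lfc_min, nrow(calls))
  p_thr <- rep(p_max, nrow(calls))
  if (!is.null(dataset_config)) {
    m <- match(calls$dataset_id, dataset_config$dataset_id)
    if (anyNA(m)) {
      stop("datasets missing from dataset_config: ",
           paste(unique(calls$dataset_id[is.na(m)]), collapse = ", "))
    }
    if (!is.null(dataset_config$lfc_min)) {
      ov <- dataset_config$lfc_min[m]
      lfc_thr <- ifelse(is.na(ov), lfc_thr, ov)
    }
    if (!is.null(dataset_config$p_max)) {
      ov <- dataset_config$p_max[m]
      p_thr <- ifelse(is.na(ov), p_thr, ov)
    }
  }
  sig <- calls$adj_p <= p_thr
  ifelse(sig & calls$log2fc >= lfc_thr, "up",
         ifelse(sig & calls$log2fc <= -lfc_thr, "down", "ns"))
}

# Map dataset ids to study ids; without a config each dataset is its own
# study. Internal.
dataset_studies <- function(dataset_ids, dataset_config = NULL) {
  if (is.null(dataset_config) || is.null(dataset_config$study_id)) {
    return(as.character(dataset_ids))
  }
  m <- match(dataset_ids, dataset_config$dataset_id)
  out <- dataset_config$study_id[m]
  out[is.na(m)] <- as.character(dataset_ids)[is.na(m)]
  out
}

#' Compute per-gene Expression Scores across many datasets
#'
#' The Expression Score of a gene is the number of datasets that call it
#' significantly up-regulated minus the number that call it down-regulated
#' when the regulator is active. A gene is "present" in a dataset when it
#' appears as a row in that dataset's table, whatever the verdict; genes
#' present in fewer than `min_present` datasets are excluded.
#'
#' @param calls Long data.frame with columns `gene_id`, `dataset_id`,
#'   `log2fc`, `adj_p` — one row per gene per dataset in which it was
#'   measured (see [read_de_tables()]).
#' @param dataset_config Optional data.frame with columns `dataset_id`,
#'   `study_id` and per-dataset threshold overrides `lfc_min` / `p_max`
#'   (NA entries fall back to the defaults). Some studies use deviating
#'   thresholds; this is where they are declared.
#' @param min_present Minimum number of datasets a gene must be measured in
#'   (default 3).
#' @param lfc_min,p_max Default thresholds passed to the per-row verdict
#'   (see [call_regulation()]).
#' @return data.frame with one row per retained gene: `gene_id`, `n_up`,
#'   `n_down`, `n_ns`, `n_present`, `score`, `n_up_studies`,
#'   `n_down_studies` (distinct studies supporting each direction), sorted
#'   by `gene_id`.
#' @export
compute_expression_scores <- function(calls, dataset_config = NULL,
                                      min_present = 3L,
                                      lfc_min = 0.5, p_max = 0.05) {
  need <- c("gene_id", "dataset_id", "log2fc", "adj_p")
  if (!all(need %in% names(calls))) {
    stop("calls must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(calls$gene_id, calls$dataset_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (gene_id, dataset_id) rows in calls")
  }
  verdict <- dataset_verdicts(calls, dataset_config, lfc_min, p_max)
  g <- factor(calls$gene_id)
  n_present <- as.integer(tabulate(g, nbins = nlevels(g)))
  n_up <- as.integer(rowsum((verdict == "up") + 0L, g, reorder = TRUE))
  n_down <- as.integer(rowsum((verdict == "down") + 0L, g, reorder = TRUE))
  study <- dataset_studies(calls$dataset_id, dataset_config)
  study_count <- function(dir) {
    sel <- verdict == dir
    if (!any(sel)) return(integer(nlevels(g)))
    u <- unique(data.frame(g = as.integer(g)[sel], s = study[sel]))
    as.integer(tabulate(u$g, nbins = nlevels(g)))
  }
  out <- data.frame(
    gene_id = levels(g),
    n_up = n_up,
    n_down = n_down,
    n_ns = n_present - n_up - n_down,
    n_present = n_present,
    score = n_up - n_down,
    n_up_studies = study_count("up"),
    n_down_studies = study_count("down"),
    stringsAsFactors = FALSE
  )
  out <- out[out$n_present >= min_present, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histogram of Expression Score groups
#'
#' Tabulates genes per observed integer score. With `merge_min_size > 0`,
#' score groups smaller than that are folded into the adjacent observed
#' group nearer zero (cascading if the combined group is still too small);
#' group 0 never merges. Merging is a presentation aid for sparse extreme
#' groups and preserves the total gene count.
#'
#' @param scores data.frame from [compute_expression_scores()] or an integer
#'   vector of scores.
#' @param merge_min_size Minimum group size below which a group is merged
#'   inward (default 0 = no merging).
#' @return data.frame with columns `score`, `n_genes`, sorted by score.
#' @export
score_group_histogram <- function(scores, merge_min_size = 0L) {
  s <- if (is.data.frame(scores)) scores$score else scores
  tab <- table(s)
  df <- data.frame(score = as.integer(names(tab)), n_genes = as.integer(tab))
  df <- df[order(df$score), , drop = FALSE]
  if (merge_min_size > 0L) {
    repeat {
      small <- which(df$n_genes < merge_min_size & df$score != 0L)
      if (!length(small)) break
      i <- small[1L]
      # index of the adjacent observed group nearer zero
      j <- if (df$score[i] < 0L) i + 1L else i - 1L
      if (j < 1L || j > nrow(df)) break
      df$n_genes[j] <- df$n_genes[j] + df$n_genes[i]
      df <- df[-i, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  df
}

#' Leave-one-out concordance of expression datasets
#'
#' Each dataset is held out in turn and tested against the summed Expression
#' Score of the remaining datasets: among genes whose remaining score equals
#' `s`, what fraction does the held-out dataset call regulated in the same
#' direction? Concordance rising with the remaining score indicates that the
#' score behaves as a confidence measure.
#'
#' @inheritParams compute_expression_scores
#' @return data.frame with columns `dataset_id`, `direction` (`"up"` for
#'   positive remaining-score bins, `"down"` for negative), `remaining_score`,
#'   `n_genes`, `n_recovered`, `recovery`.
#' @export
leave_one_out_concordance <- function(calls, dataset_config = NULL,
                                      lfc_min = 0.5, p_max = 0.05) {
  datasets <- unique(calls$dataset_id)
  if (length(datasets) < 3L) stop("need at least 3 datasets")
  verdict <- dataset_verdicts(calls, dataset_config, lfc_min, p_max)
  res <- list()
  for (d in datasets) {
    held <- calls$dataset_id == d
    held_v <- setNames(verdict[held], calls$gene_id[held])
    rest <- calls[!held, , drop = FALSE]
    rest_v <- verdict[!held]
    g <- factor(rest$gene_id)
    score <- as.integer(rowsum((rest_v == "up") - (rest_v == "down"), g))
    names(score) <- levels(g)
    common <- intersect(names(held_v), names(score))
    sc <- score[common]
    hv <- held_v[common]
    for (s in sort(unique(sc[sc != 0L]))) {
      dir <- if (s > 0L) "up" else "down"
      in_bin <- sc == s
      res[[length(res) + 1L]] <- data.frame(
        dataset_id = d, direction = dir, remaining_score = s,
        n_genes = sum(in_bin), n_recovered = sum(hv[in_bin] == dir),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  out$recovery <- out$n_recovered / out$n_genes
  rownames(out) <- NULL
  out
}
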
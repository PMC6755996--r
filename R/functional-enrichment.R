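#' Over-representation test of a gene set against term annotations
#'
#' Classic hypergeometric over-representation analysis: for each term with
#' `K` members in the universe, the probability of observing at least the
#' actual overlap `k` between the term and a query of size `n` drawn from a
#' universe of size `N` is the upper-tail hypergeometric probability
#' `P(X >= k)`. P-values are adjusted across all tested terms with the
#' Benjamini-Hochberg step-up procedure. The universe should be the set of
#' genes the upstream analysis could have scored (e.g. all genes with an
#' Expression Score), not the whole annotation.
#'
#' @param query_genes Character vector of genes of interest; must be a
#'   subset of `universe`.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]); members outside the universe are ignored.
#' @param universe Character vector of all eligible genes.
#' @return data.frame with one row per term: `term_id`, `overlap` (k),
#'   `term_size` (K, within universe), `query_size` (n), `universe_size`
#'   (N), `p_value`, `fdr`; sorted by `fdr` then `p_value`.
#' @export
enrich_terms <- function(query_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% universe)) {
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query_genes, universe), 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(query_genes)
  K <- vapply(gene_sets, function(m) length(intersect(m, universe)), integer(1))
  k <- vapply(gene_sets, function(m) length(intersect(m, query_genes)),
              integer(1))
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(
    term_id = names(gene_sets),
    overlap = k, term_size = K, query_size = n, universe_size = N,
    p_value = p,
    fdr = p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$fdr, out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
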
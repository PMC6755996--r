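#' Pair one-to-one orthologs that are scored in both species
#'
#' Keeps only orthology rows of homology type `"one2one"` for which both
#' genes received an Expression Score, and attaches both species' scores and
#' per-direction dataset counts.
#'
#' @param orthology data.frame with columns `gene_A`, `gene_B`,
#'   `homology_type` (see [read_orthology()]).
#' @param scores_A,scores_B data.frames from [compute_expression_scores()]
#'   for species A and B.
#' @return data.frame with one row per retained pair: `gene_A`, `gene_B`,
#'   `score_A`, `score_B`, `n_up_A`, `n_down_A`, `n_up_B`, `n_down_B`,
#'   `n_up_studies_A`, `n_down_studies_A`, `n_up_studies_B`,
#'   `n_down_studies_B`.
#' @export
build_ortholog_pairs <- function(orthology, scores_A, scores_B) {
  oo <- orthology[orthology$homology_type == "one2one", , drop = FALSE]
  if (anyDuplicated(oo$gene_A) || anyDuplicated(oo$gene_B)) {
    stop("a gene appears in more than one one2one orthology row")
  }
  ma <- match(oo$gene_A, scores_A$gene_id)
  mb <- match(oo$gene_B, scores_B$gene_id)
  keep <- !is.na(ma) & !is.na(mb)
  oo <- oo[keep, , drop = FALSE]
  ma <- ma[keep]; mb <- mb[keep]
  out <- data.frame(
    gene_A = oo$gene_A, gene_B = oo$gene_B,
    score_A = scores_A$score[ma], score_B = scores_B$score[mb],
    n_up_A = scores_A$n_up[ma], n_down_A = scores_A$n_down[ma],
    n_up_B = scores_B$n_up[mb], n_down_B = scores_B$n_down[mb],
    n_up_studies_A = scores_A$n_up_studies[ma],
    n_down_studies_A = scores_A$n_down_studies[ma],
    n_up_studies_B = scores_B$n_up_studies[mb],
    n_down_studies_B = scores_B$n_down_studies[mb],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Spearman correlation of Expression Scores between species
#'
#' Correlates the two species' scores over the pairs in which the reference
#' species shows regulation in the requested direction (score > 0 for up,
#' score < 0 for down). Because the subset depends on which species anchors
#' it, the correlation is conventionally reported for both reference
#' orientations per direction.
#'
#' @param pairs data.frame from [build_ortholog_pairs()].
#' @param direction `"up"` or `"down"`.
#' @param reference `"A"` or `"B"`: which species' score sign defines the
#'   subset.
#' @return Spearman's rho (average ranks for ties).
#' @export
correlate_scores <- function(pairs, direction = c("up", "down"),
                             reference = c("A", "B")) {
  direction <- match.arg(direction)
  reference <- match.arg(reference)
  ref <- if (reference == "A") pairs$score_A else pairs$score_B
  sel <- if (direction == "up") ref > 0L else ref < 0L
  if (sum(sel) < 3L) {
    stop("fewer than 3 qualifying pairs; correlation undefined")
  }
  cor(pairs$score_A[sel], pairs$score_B[sel], method = "spearman")
}

#' Classify cross-species regulatory divergence of ortholog pairs
#'
#' A pair is tagged `A_up_only` when species A's score passes `es_min`, the
#' absolute score difference between the species is at least `diff_min`, and
#' fewer than `other_support_max` datasets call the gene up in species B
#' (support is the same-direction dataset count, not the net score, so a
#' 3-up/3-down gene still counts as supported). The other three `*_only`
#' tags are symmetric. Tags are assigned per direction, so a pair can carry
#' two tags (e.g. up in one species and down in the other). `common_up` /
#' `common_down` require the score threshold in both species and exclude
#' the corresponding `*_only` tags.
#'
#' @param pairs data.frame from [build_ortholog_pairs()].
#' @param es_min Minimum absolute Expression Score in the regulated species
#'   (default 5).
#' @param diff_min Minimum absolute between-species score difference
#'   (default 8).
#' @param other_support_max Pairs qualify only when fewer than this many
#'   datasets support the same direction in the other species (default 3).
#' @return `pairs` with added logical columns `A_up_only`, `B_up_only`,
#'   `A_down_only`, `B_down_only`, `common_up`, `common_down` and
#'   `passes_filter` (any `*_only` tag).
#' @export
classify_divergence <- function(pairs, es_min = 5L, diff_min = 8L,
                                other_support_max = 3L) {
  d <- abs(pairs$score_A - pairs$score_B)
  out <- pairs
  out$A_up_only <- pairs$score_A >= es_min & d >= diff_min &
    pairs$n_up_B < other_support_max
  out$B_up_only <- pairs$score_B >= es_min & d >= diff_min &
    pairs$n_up_A < other_support_max
  out$A_down_only <- pairs$score_A <= -es_min & d >= diff_min &
    pairs$n_down_B < other_support_max
  out$B_down_only <- pairs$score_B <= -es_min & d >= diff_min &
    pairs$n_down_A < other_support_max
  out$common_up <- pairs$score_A >= es_min & pairs$score_B >= es_min &
    !(out$A_up_only | out$B_up_only)
  out$common_down <- pairs$score_A <= -es_min & pairs$score_B <= -es_min &
    !(out$A_down_only | out$B_down_only)
  out$passes_filter <- out$A_up_only | out$B_up_only |
    out$A_down_only | out$B_down_only
  out
}

#' Annotate ortholog pairs with binding-site conservation near the TSS
#'
#' For each pair, asks whether any consensus peak of species A whose
#' midpoint lies within `window` bp of the A gene's TSS maps through the
#' genome alignment onto (>= 1 bp overlap) a consensus peak of species B
#' whose midpoint lies within `window` bp of the B gene's TSS. This is the
#' distinction between a conserved binding site and species-specific sites
#' serving the same target gene.
#'
#' @param pairs data.frame with columns `gene_A`, `gene_B`.
#' @param annotation_A,annotation_B TSS annotations (see
#'   [read_annotation()]).
#' @param consensus_A,consensus_B GRanges of consensus peaks from
#'   [build_consensus_peaks()].
#' @param chains `grnx_chains` alignment mapping genome A to genome B.
#' @param window TSS window in bp (default 5000).
#' @param min_match Passed to [map_intervals()].
#' @return Logical vector along `pairs`: TRUE when the pair shares a
#'   conserved TSS-proximal binding site.
#' @export
annotate_site_conservation <- function(pairs, annotation_A, annotation_B,
                                       consensus_A, consensus_B, chains,
                                       window = 5000L, min_match = 0.1) {
  mid_A <- peak_midpoints(consensus_A)
  mid_B <- peak_midpoints(consensus_B)
  chrom_A <- as.character(seqnames(consensus_A))
  chrom_B <- as.character(seqnames(consensus_B))
  mapped <- map_intervals(consensus_A, chains, min_match = min_match)
  ok <- mapped$status == "mapped"
  img <- GRanges(mapped$target_chrom[ok],
                 IRanges(mapped$target_start[ok], mapped$target_end[ok]))
  img_idx <- which(ok)
  tss_A <- setNames(annotation_A$tss, annotation_A$gene_id)
  chr_gA <- setNames(annotation_A$chrom, annotation_A$gene_id)
  tss_B <- setNames(annotation_B$tss, annotation_B$gene_id)
  chr_gB <- setNames(annotation_B$chrom, annotation_B$gene_id)
  vapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_A[i]; gb <- pairs$gene_B[i]
    if (is.na(tss_A[ga]) || is.na(tss_B[gb])) return(FALSE)
    near_A <- which(chrom_A == chr_gA[ga] & abs(mid_A - tss_A[ga]) <= window)
    near_B <- which(chrom_B == chr_gB[gb] & abs(mid_B - tss_B[gb]) <= window)
    if (!length(near_A) || !length(near_B)) return(FALSE)
    sel <- img_idx %in% near_A
    if (!any(sel)) return(FALSE)
    any(countOverlaps(img[sel], consensus_B[near_B],
                      ignore.strand = TRUE) > 0L)
  }, logical(1))
}

#' Intersect the two species' direct-target sets over ortholog pairs
#'
#' Returns the pairs called direct targets in both species, annotated as
#' sustained through a conserved (overlapping, alignable) binding site or
#' through species-specific sites near the orthologous TSSs.
#'
#' @param pairs data.frame from [build_ortholog_pairs()].
#' @param targets_A,targets_B data.frames from [call_direct_targets()] for
#'   the two species.
#' @param conserved_site Logical vector along `pairs` from
#'   [annotate_site_conservation()].
#' @return data.frame of common direct-target pairs with a `binding_site`
#'   column (`"conserved"` / `"species_specific"`).
#' @export
intersect_direct_targets <- function(pairs, targets_A, targets_B,
                                     conserved_site) {
  if (length(conserved_site) != nrow(pairs)) {
    stop("conserved_site annotation does not match pairs; ",
         "run annotate_site_conservation() on the same pair table")
  }
  da <- targets_A$is_direct_target[match(pairs$gene_A, targets_A$gene_id)]
  db <- targets_B$is_direct_target[match(pairs$gene_B, targets_B$gene_id)]
  keep <- !is.na(da) & !is.na(db) & da & db
  out <- pairs[keep, , drop = FALSE]
  out$binding_site <- ifelse(conserved_site[keep], "conserved",
                             "species_specific")
  rownames(out) <- NULL
  out
}

#' Curated reference list of common mouse/human direct p53 target genes
#'
#' Loads the packaged transcription of the published core set of 86 genes
#' called direct p53 targets in both mouse and human, each annotated as
#' sustained through a conserved binding site or through species-specific
#' binding sites.
#'
#' @return data.frame with columns `gene` (human symbol) and `binding_site`
#'   (`"conserved"` / `"species_specific"`).
#' @export
common_targets_table <- function() {
  path <- system.file("extdata", "common_direct_targets.tsv",
                      package = "grnx", mustWork = TRUE)
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
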
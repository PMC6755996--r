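# Normalise peak input: accepts a GRanges with a dataset_id metadata column
# or a (named) list of GRanges, one per dataset. Internal.
flatten_peaks <- function(peaks) {
  if (inherits(peaks, "GRanges")) {
    if (is.null(mcols(peaks)$dataset_id)) {
      mcols(peaks)$dataset_id <- "dataset_1"
    }
    return(peaks)
  }
  if (is.list(peaks)) {
    ids <- names(peaks)
    if (is.null(ids)) ids <- paste0("dataset_", seq_along(peaks))
    grs <- lapply(seq_along(peaks), function(i) {
      gr <- peaks[[i]]
      mcols(gr)$dataset_id <- ids[i]
      gr
    })
    return(do.call(c, grs))
  }
  stop("peaks must be a GRanges or a list of GRanges")
}

# Midpoint convention: for a 0-based half-open interval [s0, e0) of length L
# the midpoint is s0 + floor(L / 2); in the 1-based closed GRanges view this
# is start + floor(width / 2). Internal.
peak_midpoints <- function(gr) {
  start(gr) + floor(width(gr) / 2)
}

#' Assign ChIP peaks to transcription start sites
#'
#' A dataset counts as binding evidence for a gene when at least one of its
#' peaks has its midpoint within `window` bp of the gene's TSS (inclusive on
#' both boundaries). Each dataset contributes at most one count per gene.
#' Peak-center-to-TSS distance is the assignment criterion, mirroring the
#' usual promoter-window practice (5000 bp for p53, 1000 bp for E2F4/DREAM).
#'
#' @param peaks GRanges with a `dataset_id` metadata column, or a named list
#'   of per-dataset GRanges.
#' @param annotation data.frame with columns `gene_id`, `chrom`, `tss`
#'   (1-based), `strand` (see [read_annotation()]).
#' @param window Half-width of the promoter window in bp.
#' @param dataset_config Optional data.frame mapping `dataset_id` to
#'   `study_id` for the distinct-study tally.
#' @return data.frame with one row per annotated gene: `gene_id`,
#'   `n_datasets_bound`, `n_studies_bound`, `dataset_ids` (comma-separated,
#'   sorted).
#' @export
assign_peaks_to_tss <- function(peaks, annotation, window,
                                dataset_config = NULL) {
  stopifnot(window > 0)
  gr <- flatten_peaks(peaks)
  known <- unique(annotation$chrom)
  off <- !(as.character(seqnames(gr)) %in% known)
  if (any(off)) {
    warning(sum(off), " peak(s) on chromosomes absent from the annotation; skipped")
    gr <- gr[!off]
  }
  mids <- peak_midpoints(gr)
  mid_gr <- GRanges(as.character(seqnames(gr)), IRanges(mids, mids))
  win_gr <- GRanges(annotation$chrom,
                    IRanges(pmax(annotation$tss - window, 1L),
                            annotation$tss + window))
  hits <- findOverlaps(mid_gr, win_gr, ignore.strand = TRUE)
  out <- data.frame(gene_id = annotation$gene_id,
                    n_datasets_bound = 0L, n_studies_bound = 0L,
                    dataset_ids = "", stringsAsFactors = FALSE)
  if (length(hits)) {
    ds <- mcols(gr)$dataset_id[queryHits(hits)]
    gene_idx <- subjectHits(hits)
    u <- unique(data.frame(gene = gene_idx, ds = ds, stringsAsFactors = FALSE))
    cnt <- table(factor(u$gene, levels = seq_len(nrow(annotation))))
    out$n_datasets_bound <- as.integer(cnt)
    st <- dataset_studies(u$ds, dataset_config)
    us <- unique(data.frame(gene = u$gene, st = st, stringsAsFactors = FALSE))
    out$n_studies_bound <- as.integer(
      table(factor(us$gene, levels = seq_len(nrow(annotation)))))
    agg <- vapply(split(u$ds, u$gene),
                  function(x) paste(sort(x), collapse = ","), "")
    out$dataset_ids[as.integer(names(agg))] <- agg
  }
  out
}

#' Merge peaks across datasets into consensus peaks with support counts
#'
#' Peaks that overlap by at least 1 bp across (or within) datasets are merged
#' by single linkage into one consensus interval spanning their union. The
#' support of a consensus peak is the number of distinct datasets that
#' contribute at least one peak to it; consensus peaks with support below
#' `min_support` are dropped.
#'
#' @inheritParams assign_peaks_to_tss
#' @param min_support Minimum number of distinct supporting datasets
#'   (default 1 = keep everything).
#' @return GRanges sorted by (chrom, start) with metadata columns `support`
#'   and `dataset_ids` (comma-separated, sorted).
#' @export
build_consensus_peaks <- function(peaks, min_support = 1L) {
  gr <- flatten_peaks(peaks)
  if (length(gr) == 0L) {
    out <- GRanges()
    mcols(out)$support <- integer(0)
    mcols(out)$dataset_ids <- character(0)
    return(out)
  }
  merged <- reduce(granges(gr), min.gapwidth = 0L, ignore.strand = TRUE)
  hits <- findOverlaps(gr, merged, ignore.strand = TRUE)
  ds <- mcols(gr)$dataset_id[queryHits(hits)]
  u <- unique(data.frame(cons = subjectHits(hits), ds = ds,
                         stringsAsFactors = FALSE))
  support <- as.integer(table(factor(u$cons, levels = seq_along(merged))))
  ids <- character(length(merged))
  agg <- vapply(split(u$ds, u$cons), function(x) paste(sort(x), collapse = ","), "")
  ids[as.integer(names(agg))] <- agg
  mcols(merged)$support <- support
  mcols(merged)$dataset_ids <- ids
  merged <- merged[support >= min_support]
  GenomicRanges::sort(merged, ignore.strand = TRUE)
}
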
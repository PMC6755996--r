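#' Map genomic intervals to another genome through a chain alignment
#'
#' Projects each interval through the aligned blocks of a chain-format
#' pairwise alignment. An interval is considered mapped when at least
#' `min_match` of its bases fall inside aligned blocks of a single chain; the
#' chain covering the most bases of the interval wins, with ties broken by
#' file order. The target interval spans from the image of the first mapped
#' base to the image of the last mapped base (so insertions in the target
#' genome inside the interval are spanned, as in conventional liftover
#' practice).
#'
#' @param intervals A [GenomicRanges::GRanges] on the source genome.
#' @param chains A `grnx_chains` object from [read_chain()], mapping source
#'   (`t`) to target (`q`).
#' @param min_match Minimum fraction of interval bases that must be covered
#'   by aligned blocks, in `(0, 1]`. Default 0.1, the usual cross-species
#'   liftover setting.
#' @return A data.frame with one row per input interval: `chrom`, `start`,
#'   `end` (source, 1-based closed), `status` (`"mapped"`/`"unmapped"`),
#'   `mapped_fraction`, `chain_id`, `target_chrom`, `target_start`,
#'   `target_end` (1-based closed; NA when unmapped). Metadata columns of
#'   `intervals` are carried through.
#' @export
map_intervals <- function(intervals, chains, min_match = 0.1) {
  stopifnot(is.numeric(min_match), length(min_match) == 1L,
            min_match > 0, min_match <= 1)
  if (!inherits(chains, "grnx_chains")) stop("chains must be a grnx_chains object")
  n <- length(intervals)
  out <- data.frame(
    chrom = as.character(seqnames(intervals)),
    start = start(intervals), end = end(intervals),
    status = rep("unmapped", n), mapped_fraction = rep(0, n),
    chain_id = rep(NA_character_, n),
    target_chrom = rep(NA_character_, n),
    target_start = rep(NA_integer_, n), target_end = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
  if (n == 0L) {
    return(cbind(out, as.data.frame(mcols(intervals))))
  }
  bt <- chain_block_table(chains)
  # overlap source intervals with chain blocks (1-based closed comparison)
  block_gr <- GRanges(bt$t_name, IRanges(bt$t_start0 + 1L, bt$t_end0))
  hits <- findOverlaps(granges(intervals), block_gr, ignore.strand = TRUE)
  if (length(hits)) {
    qh <- queryHits(hits); sh <- subjectHits(hits)
    ov_start <- pmax(start(intervals)[qh], bt$t_start0[sh] + 1L)
    ov_end <- pmin(end(intervals)[qh], bt$t_end0[sh])
    covered <- ov_end - ov_start + 1L
    key <- paste(qh, bt$chain[sh])
    cov_by_chain <- rowsum(covered, key)
    ik <- as.integer(sub(" .*", "", rownames(cov_by_chain)))
    ck <- as.integer(sub(".* ", "", rownames(cov_by_chain)))
    # best chain per interval: most covered bases, ties to earliest chain
    ord <- order(ik, -cov_by_chain[, 1L], ck)
    first <- !duplicated(ik[ord])
    best <- data.frame(interval = ik[ord][first], chain = ck[ord][first],
                       covered = cov_by_chain[ord, 1L][first])
    frac <- best$covered / width(intervals)[best$interval]
    out$mapped_fraction[best$interval] <- frac
    mapped <- best$interval[frac >= min_match]
    best_chain <- best$chain[frac >= min_match]
    if (length(mapped)) {
      sel <- match(paste(qh, bt$chain[sh]),
                   paste(mapped, best_chain), nomatch = 0L) > 0L
      qs <- qh[sel]; ss <- sh[sel]
      os <- pmax(start(intervals)[qs], bt$t_start0[ss] + 1L)
      oe <- pmin(end(intervals)[qs], bt$t_end0[ss])
      delta <- bt$q_start0[ss] - bt$t_start0[ss]
      img_s <- os + delta
      img_e <- oe + delta
      # image of the first and last mapped base per interval
      o <- order(qs, img_s)
      firsts <- !duplicated(qs[o])
      first_iv <- qs[o][firsts]
      first_img <- img_s[o][firsts]
      o2 <- order(qs, img_e)
      lasts <- rev(!duplicated(rev(qs[o2])))
      last_iv <- qs[o2][lasts]
      last_img <- img_e[o2][lasts]
      out$status[mapped] <- "mapped"
      out$chain_id[mapped] <- vapply(best_chain, function(ci) chains[[ci]]$id, "")
      out$target_chrom[mapped] <-
        vapply(best_chain, function(ci) chains[[ci]]$q_name, "")
      out$target_start[first_iv] <- first_img
      out$target_end[last_iv] <- last_img
    }
  }
  extra <- as.data.frame(mcols(intervals))
  if (ncol(extra)) out <- cbind(out, extra)
  rownames(out) <- NULL
  out
}

#' Classify cross-genome binding-site turnover
#'
#' Given intervals mapped to the other genome with [map_intervals()] and the
#' target species' consensus binding sites, counts sites that could not be
#' mapped (sequence absent from the target genome), sites mapped to a region
#' with no binding in the target species (turnover), and sites mapped onto a
#' target binding site (conserved binding; any >= 1 bp overlap counts). The
#' conserved fraction follows the "sites present in both genomes" convention:
#' unmappable sites are excluded from the denominator.
#'
#' @param mapped data.frame from [map_intervals()].
#' @param target_peaks [GenomicRanges::GRanges] of binding sites in the
#'   target genome (e.g. consensus peaks from [build_consensus_peaks()]).
#' @return A list with `counts` (named integer vector: `unmappable`,
#'   `mapped_nonoverlapping`, `mapped_overlapping`), `conserved_fraction`
#'   (in `[0, 1]`, NA if nothing mapped) and `conserved_pct`.
#' @export
classify_turnover <- function(mapped, target_peaks) {
  is_mapped <- mapped$status == "mapped"
  n_unmap <- sum(!is_mapped)
  n_over <- 0L
  if (any(is_mapped)) {
    tg <- GRanges(mapped$target_chrom[is_mapped],
                  IRanges(mapped$target_start[is_mapped],
                          mapped$target_end[is_mapped]))
    n_over <- sum(countOverlaps(tg, target_peaks, ignore.strand = TRUE) > 0L)
  }
  n_nonover <- sum(is_mapped) - n_over
  denom <- n_over + n_nonover
  frac <- if (denom > 0L) n_over / denom else NA_real_
  list(
    counts = c(unmappable = n_unmap,
               mapped_nonoverlapping = as.integer(n_nonover),
               mapped_overlapping = as.integer(n_over)),
    conserved_fraction = frac,
    conserved_pct = 100 * frac
  )
}

#' Average conservation-score profile around site centers
#'
#' Computes, for each base-pair offset in `-flank .. +flank` relative to the
#' site center, the arithmetic mean of a per-base conservation track over all
#' sites whose full window lies within the chromosome. Positions absent from
#' the track are excluded from the mean (not imputed as zero). The center of
#' a site of length L is `start + floor(L / 2)` in 0-based terms, matching
#' the midpoint convention used for peak-to-TSS assignment.
#'
#' @param sites [GenomicRanges::GRanges] of sites.
#' @param track [GenomicRanges::GRanges] with a numeric `score` column, e.g.
#'   from [read_bedgraph_track()]; intervals must not overlap.
#' @param flank Half-window in bp (default 2500).
#' @return data.frame with columns `offset`, `mean_score`, `n_sites` (number
#'   of sites contributing a non-missing value at that offset); `mean_score`
#'   is NA where `n_sites` is 0.
#' @export
conservation_profile <- function(sites, track, flank = 2500L) {
  if (length(sites) == 0L) stop("empty site set")
  flank <- as.integer(flank)
  centers <- start(sites) + floor(width(sites) / 2)
  chroms <- as.character(seqnames(sites))
  width_w <- 2L * flank + 1L
  sums <- numeric(width_w)
  ns <- integer(width_w)
  tr_chrom <- as.character(seqnames(track))
  sl <- seqlengths(track)
  for (chr in unique(chroms)) {
    tsel <- tr_chrom == chr
    if (!any(tsel)) next
    te <- end(track)[tsel]
    len <- if (!is.na(sl[chr])) sl[chr] else max(te)
    vec <- rep(NA_real_, len)
    ts <- start(track)[tsel]
    sc <- mcols(track)$score[tsel]
    vec[sequence(te - ts + 1L, from = ts)] <- rep(sc, te - ts + 1L)
    cc <- centers[chroms == chr]
    cc <- cc[cc - flank >= 1L & cc + flank <= len]
    for (c0 in cc) {
      sl_vals <- vec[(c0 - flank):(c0 + flank)]
      ok <- !is.na(sl_vals)
      sums[ok] <- sums[ok] + sl_vals[ok]
      ns <- ns + ok
    }
  }
  data.frame(
    offset = seq(-flank, flank),
    mean_score = ifelse(ns > 0L, sums / pmax(ns, 1L), NA_real_),
    n_sites = ns
  )
}
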
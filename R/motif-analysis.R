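IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Build a log-odds motif model from an IUPAC consensus
#'
#' Three built-in models cover the motifs relevant to p53/DREAM biology: the
#' canonical p53 response element (two decameric half sites RRRCWWGYYY with
#' no spacer), the E2F element (TTSSSSS) and the CHR element (TTYGAA).
#' Permitted bases at each position receive weight 1 and non-permitted bases
#' the pseudocount, columns are normalised to probabilities, and scores are
#' log2 odds against a uniform background. A window is a hit when its score
#' reaches `threshold` times the maximum attainable score; `N` bases score
#' as background (log-odds 0).
#'
#' @param name `"p53RE"`, `"E2F"`, `"CHR"`, or any label when `consensus`
#'   is supplied.
#' @param consensus Optional IUPAC consensus string overriding the built-in
#'   one for `name`.
#' @param pseudocount Weight given to non-permitted bases (default 0.25).
#' @param threshold Fraction of the maximum log-odds score required for a
#'   hit, in `(0, 1]` (default 0.85).
#' @return An object of class `grnx_motif`: list with `name`, `consensus`,
#'   `matrix` (4 x width log-odds, rows A/C/G/T), `width`, `threshold`,
#'   `max_score`, `min_score` (the hit cutoff).
#' @examples
#' m <- motif_model("p53RE")
#' m$width  # 20
#' @export
motif_model <- function(name = c("p53RE", "E2F", "CHR"), consensus = NULL,
                        pseudocount = 0.25, threshold = 0.85) {
  if (is.null(consensus)) {
    name <- match.arg(name)
    consensus <- switch(name,
      p53RE = strrep("RRRCWWGYYY", 2L),
      E2F = "TTSSSSS",
      CHR = "TTYGAA"
    )
  }
  stopifnot(threshold > 0, threshold <= 1, pseudocount > 0)
  letters <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(letters, names(IUPAC_BASES))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  w <- length(letters)
  mat <- vapply(letters, function(l) {
    wt <- rep(pseudocount, 4L)
    names(wt) <- c("A", "C", "G", "T")
    wt[IUPAC_BASES[[l]]] <- 1
    log2((wt / sum(wt)) / 0.25)
  }, numeric(4L))
  rownames(mat) <- c("A", "C", "G", "T")
  colnames(mat) <- NULL
  max_score <- sum(apply(mat, 2L, max))
  structure(
    list(name = if (is.character(name)) name[1] else "custom",
         consensus = toupper(consensus), matrix = mat, width = w,
         threshold = threshold, max_score = max_score,
         min_score = threshold * max_score),
    class = "grnx_motif"
  )
}

# Score every window of one strand of a sequence. Returns the numeric score
# vector (length 0 when the sequence is shorter than the motif). Internal.
score_windows <- function(seq_chars_idx, model) {
  W <- model$width
  L <- length(seq_chars_idx)
  if (L < W) return(numeric(0))
  M5 <- rbind(model$matrix, N = rep(0, W))  # row 5: N / unknown = background
  npos <- L - W + 1L
  sc <- numeric(npos)
  for (j in seq_len(W)) {
    sc <- sc + M5[seq_chars_idx[j:(j + npos - 1L)], j]
  }
  sc
}

seq_to_idx <- function(seq) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  idx[is.na(idx)] <- 5L
  idx
}

#' Scan a sequence for motif hits on both strands
#'
#' Slides the motif model over the sequence and its reverse complement and
#' reports every window whose log-odds score is at least the model's cutoff
#' (`threshold * max_score`, inclusive). Overlapping hits on opposite
#' strands are reported separately. Coordinates are 1-based on the input
#' (plus) strand.
#'
#' @param seq A [Biostrings::DNAString], or a character string over
#'   `A/C/G/T/N`.
#' @param model A `grnx_motif` from [motif_model()].
#' @return data.frame with columns `start`, `end`, `strand`, `score`,
#'   sorted by start then strand; zero rows when nothing matches.
#' @export
scan_sequence <- function(seq, model) {
  idx <- seq_to_idx(seq)
  L <- length(idx)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0))
  if (L == 0L) return(empty)
  W <- model$width
  fwd <- score_windows(idx, model)
  hits_f <- which(fwd >= model$min_score)
  # reverse complement: complement is 5 - idx for ACGT (A<->T, C<->G), N stays
  ridx <- rev(ifelse(idx == 5L, 5L, 5L - idx))
  rv <- score_windows(ridx, model)
  hits_r <- which(rv >= model$min_score)
  out <- rbind(
    if (length(hits_f)) data.frame(start = hits_f, end = hits_f + W - 1L,
                                   strand = "+", score = fwd[hits_f]),
    if (length(hits_r)) data.frame(start = L - (hits_r + W - 1L) + 1L,
                                   end = L - hits_r + 1L,
                                   strand = "-", score = rv[hits_r]),
    empty
  )
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

resolve_genome <- function(genome) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  if (!is.null(names(genome))) names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Fraction of peaks containing at least one motif hit
#'
#' @param peaks GRanges of peaks (e.g. consensus peaks).
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param model A `grnx_motif` from [motif_model()].
#' @return list with `fraction`, `n_with_motif`, `n_peaks`.
#' @export
fraction_peaks_with_motif <- function(peaks, genome, model) {
  if (length(peaks) == 0L) stop("empty peak set")
  genome <- resolve_genome(genome)
  chrom <- as.character(seqnames(peaks))
  miss <- setdiff(unique(chrom), names(genome))
  if (length(miss)) stop("peak chromosome(s) absent from genome: ",
                         paste(miss, collapse = ", "))
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (any(start(peaks) < 1L) || any(end(peaks) > lens[chrom])) {
    stop("peak coordinates beyond contig ends")
  }
  has <- vapply(seq_along(peaks), function(i) {
    s <- subseq(genome[[chrom[i]]], start(peaks)[i], end(peaks)[i])
    nrow(scan_sequence(s, model)) > 0L
  }, logical(1))
  list(fraction = mean(has), n_with_motif = sum(has), n_peaks = length(peaks))
}

#' Genome-wide motif hit count
#'
#' Total number of hits over both strands of every contig.
#'
#' @inheritParams fraction_peaks_with_motif
#' @return Integer count.
#' @export
genome_wide_motif_count <- function(genome, model) {
  genome <- resolve_genome(genome)
  sum(vapply(seq_along(genome), function(i) {
    nrow(scan_sequence(genome[[i]], model))
  }, integer(1)))
}

#' Genomic-feature enrichment of a peak set
#'
#' Partitions the genome into promoter (<1 kb from a TSS), promoter
#' (1-5 kb), 5' UTR, 3' UTR, exon, intron and distal intergenic, with that
#' priority order resolving overlaps; uncovered bases fall to distal
#' intergenic. Each peak is assigned one feature by its midpoint, and the
#' observed fraction per feature is compared with the fraction of the
#' genome the feature occupies.
#'
#' @param peaks GRanges of peaks.
#' @param annotation TSS table (see [read_annotation()]); promoter classes
#'   are windows around these TSSs (both sides).
#' @param features GRanges with a `feature` metadata column over
#'   `five_utr`, `three_utr`, `exon`, `intron`.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return data.frame with columns `feature`, `n_peaks`, `observed_frac`,
#'   `expected_frac`, `enrichment` (NA where the expected fraction is 0).
#' @export
feature_enrichment <- function(peaks, annotation, features, chrom_sizes) {
  clip <- function(gr) {
    len <- chrom_sizes[as.character(seqnames(gr))]
    GRanges(seqnames(gr),
            IRanges(pmax(start(gr), 1L), pmin(end(gr), len)))
  }
  tss_gr <- function(half) {
    clip(GRanges(annotation$chrom,
                 IRanges(annotation$tss - half, annotation$tss + half)))
  }
  feat_gr <- function(cls) {
    sel <- mcols(features)$feature == cls
    reduce(granges(features[sel]), ignore.strand = TRUE)
  }
  whole <- GRanges(names(chrom_sizes), IRanges(1L, unname(chrom_sizes)))
  classes <- list(
    promoter_lt1kb = reduce(tss_gr(1000L)),
    promoter_1to5kb = reduce(tss_gr(5000L)),
    five_utr = feat_gr("five_utr"),
    three_utr = feat_gr("three_utr"),
    exon = feat_gr("exon"),
    intron = feat_gr("intron")
  )
  mask <- GRanges()
  partition <- list()
  for (cls in names(classes)) {
    gr <- GenomicRanges::setdiff(classes[[cls]], mask, ignore.strand = TRUE)
    partition[[cls]] <- gr
    mask <- reduce(c(mask, gr), ignore.strand = TRUE)
  }
  partition$distal_intergenic <-
    GenomicRanges::setdiff(whole, mask, ignore.strand = TRUE)
  total_bp <- sum(as.numeric(chrom_sizes))
  expected <- vapply(partition, function(gr) sum(as.numeric(width(gr))),
                     numeric(1)) / total_bp
  mids <- peak_midpoints(peaks)
  mid_gr <- GRanges(as.character(seqnames(peaks)), IRanges(mids, mids))
  observed <- vapply(partition, function(gr) {
    sum(countOverlaps(mid_gr, gr, ignore.strand = TRUE) > 0L)
  }, numeric(1))
  data.frame(
    feature = names(partition),
    n_peaks = as.integer(observed),
    observed_frac = observed / length(peaks),
    expected_frac = expected,
    enrichment = ifelse(expected > 0, (observed / length(peaks)) / expected,
                        NA_real_),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
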
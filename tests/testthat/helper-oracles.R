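# Independent brute-force reference implementations used to cross-check the
# package's vectorised code paths on small fixtures.

# Tally expression scores gene by gene, row by row.
oracle_scores <- function(calls, lfc_min = 0.5, p_max = 0.05,
                          min_present = 3L) {
  genes <- sort(unique(calls$gene_id))
  rows <- lapply(genes, function(g) {
    sub <- calls[calls$gene_id == g, , drop = FALSE]
    up <- 0L; down <- 0L
    for (i in seq_len(nrow(sub))) {
      sig <- sub$adj_p[i] <= p_max
      if (sig && sub$log2fc[i] >= lfc_min) up <- up + 1L
      else if (sig && sub$log2fc[i] <= -lfc_min) down <- down + 1L
    }
    data.frame(gene_id = g, n_up = up, n_down = down,
               n_present = nrow(sub), score = up - down,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[out$n_present >= min_present, , drop = FALSE]
}

# All-pairs peak-midpoint-to-TSS distance check.
oracle_assign <- function(peaks, annotation, window) {
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  mid <- GenomicRanges::start(peaks) +
    floor(GenomicRanges::width(peaks) / 2)
  ds <- GenomicRanges::mcols(peaks)$dataset_id
  vapply(seq_len(nrow(annotation)), function(i) {
    hit <- chrom == annotation$chrom[i] &
      abs(mid - annotation$tss[i]) <= window
    length(unique(ds[hit]))
  }, integer(1))
}

# Single-linkage merging of >=1 bp overlaps via union-find.
oracle_consensus <- function(peaks) {
  n <- length(peaks)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  st <- GenomicRanges::start(peaks); en <- GenomicRanges::end(peaks)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j] && st[i] <= en[j] && st[j] <= en[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ds <- GenomicRanges::mcols(peaks)$dataset_id
  out <- lapply(unique(roots), function(r) {
    sel <- roots == r
    data.frame(chrom = chrom[sel][1], start = min(st[sel]),
               end = max(en[sel]), support = length(unique(ds[sel])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Base-by-base image computation through a chain set for one interval
# (1-based closed input coordinates).
oracle_map_one <- function(chrom, s, e, chains, min_match = 0.1) {
  per_chain <- lapply(seq_along(chains), function(ci) {
    ch <- chains[[ci]]
    if (ch$t_name != chrom) return(NULL)
    b <- ch$blocks
    t0 <- ch$t_start + c(0L, cumsum(b$size[-nrow(b)] + b$dt[-nrow(b)]))
    q0 <- ch$q_start + c(0L, cumsum(b$size[-nrow(b)] + b$dq[-nrow(b)]))
    imgs <- rep(NA_integer_, e - s + 1L)
    for (p in s:e) {
      for (k in seq_len(nrow(b))) {
        if (p - 1L >= t0[k] && p - 1L < t0[k] + b$size[k]) {
          imgs[p - s + 1L] <- q0[k] + (p - 1L - t0[k]) + 1L
          break
        }
      }
    }
    list(ci = ci, covered = sum(!is.na(imgs)), imgs = imgs,
         q_name = ch$q_name)
  })
  per_chain <- Filter(Negate(is.null), per_chain)
  if (!length(per_chain)) {
    return(list(status = "unmapped", fraction = 0))
  }
  cov <- vapply(per_chain, `[[`, integer(1), "covered")
  best <- per_chain[[which.max(cov)]]  # ties: earliest (which.max semantics)
  frac <- best$covered / (e - s + 1L)
  if (frac < min_match || best$covered == 0L) {
    return(list(status = "unmapped", fraction = frac))
  }
  imgs <- best$imgs[!is.na(best$imgs)]
  list(status = "mapped", fraction = frac, target_chrom = best$q_name,
       target_start = imgs[1], target_end = imgs[length(imgs)])
}

# Exhaustive per-position motif scoring on both strands.
oracle_scan <- function(seq_string, model) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_at <- function(chars, pos) {
    s <- 0
    for (j in seq_len(model$width)) {
      b <- chars[pos + j - 1L]
      s <- s + if (b %in% c("A", "C", "G", "T")) model$matrix[b, j] else 0
    }
    s
  }
  chars <- strsplit(toupper(seq_string), "")[[1]]
  L <- length(chars)
  rc <- rev(unname(comp[chars]))
  hits <- list()
  if (L >= model$width) {
    for (p in 1:(L - model$width + 1L)) {
      sf <- score_at(chars, p)
      if (sf >= model$min_score) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = p, end = p + model$width - 1L, strand = "+", score = sf)
      }
      sr <- score_at(rc, p)
      if (sr >= model$min_score) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = L - (p + model$width - 1L) + 1L, end = L - p + 1L,
          strand = "-", score = sr)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Direct tail summation of the hypergeometric upper tail P(X >= k).
oracle_hyper <- function(k, K, N, n) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Long-format expression calls for one species of a scenario.
expr_calls <- function(scenario, species) {
  ex <- scenario$expression[[species]]
  out <- Map(function(df, id) { df$dataset_id <- id; df },
             ex$data, names(ex$data))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

precision_recall <- function(called, truth) {
  tp <- length(intersect(called, truth))
  c(precision = if (length(called)) tp / length(called) else NA_real_,
    recall = if (length(truth)) tp / length(truth) else NA_real_)
}
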
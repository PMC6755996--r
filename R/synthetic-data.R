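REGULATION_CLASSES <- c("conserved_up", "conserved_down",
                        "A_up_only", "B_up_only",
                        "A_down_only", "B_down_only",
                        "opposite", "unregulated")

# Run code with a fixed RNG seed, restoring the caller's RNG state. Internal.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Configure a two-species synthetic scenario
#'
#' Defines the study conditions emulated by [generate_scenario()]: how many
#' genes and one-to-one orthologs the two genomes share, the mix of
#' regulation classes planted on ortholog pairs, how many expression and
#' ChIP datasets are simulated per species and how noisy they are, and the
#' structure of the pairwise genome alignment. Defaults emulate a
#' mouse/human-style p53 compendium: 15 expression datasets per species,
#' 9 p53 + 7 E2F4 ChIP sets for species A and 28 p53 + 9 DREAM/E2F4 sets
#' for species B.
#'
#' @param n_genes_per_species Number of genes per species (one gene per
#'   genomic locus; loci are at least 12 kb so promoter windows of
#'   neighbouring genes do not collide).
#' @param frac_one_to_one Fraction of genes with a one-to-one ortholog.
#' @param regulation_class_probs Named probabilities over the planted
#'   classes `conserved_up`, `conserved_down`, `A_up_only`, `B_up_only`,
#'   `A_down_only`, `B_down_only`, `opposite`, `unregulated`; must sum to 1.
#' @param n_expression_datasets_per_species Expression datasets per species.
#' @param detection_sensitivity Probability that a truly regulated gene is
#'   called in one expression dataset.
#' @param false_call_rate Probability that an unregulated gene is spuriously
#'   called in one expression dataset.
#' @param n_chip_datasets List `list(A = c(p53 =, e2f4 =), B = c(p53 =,
#'   e2f4 =))` of ChIP dataset counts per factor per species.
#' @param peak_dropout Probability that a true binding site is missed by one
#'   ChIP dataset.
#' @param genome_length Genome length in bp per species (default
#'   `12000 * n_genes_per_species`).
#' @param conserved_block_fraction Fraction of gene loci inside alignable
#'   blocks; loci of conserved regulation classes are always alignable.
#' @param rng_seed Integer seed; one seed, one byte stream.
#' @return A validated list of class `grn_scenario_config`.
#' @export
scenario_config <- function(n_genes_per_species = 600L,
                            frac_one_to_one = 0.8,
                            regulation_class_probs = c(
                              conserved_up = 0.10, conserved_down = 0.10,
                              A_up_only = 0.06, B_up_only = 0.06,
                              A_down_only = 0.05, B_down_only = 0.05,
                              opposite = 0.02, unregulated = 0.56),
                            n_expression_datasets_per_species = 15L,
                            detection_sensitivity = 0.9,
                            false_call_rate = 0.02,
                            n_chip_datasets = list(
                              A = c(p53 = 9L, e2f4 = 7L),
                              B = c(p53 = 28L, e2f4 = 9L)),
                            peak_dropout = 0.2,
                            genome_length = NULL,
                            conserved_block_fraction = 0.5,
                            rng_seed = 1L) {
  cfg <- list(
    n_genes_per_species = as.integer(n_genes_per_species),
    frac_one_to_one = frac_one_to_one,
    regulation_class_probs = regulation_class_probs,
    n_expression_datasets_per_species =
      as.integer(n_expression_datasets_per_species),
    detection_sensitivity = detection_sensitivity,
    false_call_rate = false_call_rate,
    n_chip_datasets = n_chip_datasets,
    peak_dropout = peak_dropout,
    genome_length = if (is.null(genome_length)) {
      12000L * as.integer(n_genes_per_species)
    } else as.integer(genome_length),
    conserved_block_fraction = conserved_block_fraction,
    rng_seed = as.integer(rng_seed)
  )
  probs <- cfg$regulation_class_probs
  if (!setequal(names(probs), REGULATION_CLASSES)) {
    stop("configuration error: regulation_class_probs must be named over: ",
         paste(REGULATION_CLASSES, collapse = ", "))
  }
  if (any(probs < 0 | probs > 1) || abs(sum(probs) - 1) > 1e-9) {
    stop("configuration error: regulation_class_probs must lie in [0,1] ",
         "and sum to 1")
  }
  for (p in c("frac_one_to_one", "detection_sensitivity", "false_call_rate",
              "peak_dropout", "conserved_block_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop("configuration error: ", p, " must be in [0, 1]")
    }
  }
  counts <- c(cfg$n_genes_per_species,
              cfg$n_expression_datasets_per_species,
              unlist(cfg$n_chip_datasets))
  if (any(counts < 1L)) stop("configuration error: all counts must be >= 1")
  if (cfg$genome_length < 12000L * cfg$n_genes_per_species) {
    stop("configuration error: genome_length must allow >= 12 kb per gene")
  }
  structure(cfg, class = "grn_scenario_config")
}

# Sample a concrete instance of an IUPAC consensus. Internal.
realize_consensus <- function(consensus) {
  vapply(strsplit(consensus, "")[[1]], function(l) {
    opts <- IUPAC_BASES[[l]]
    opts[sample.int(length(opts), 1L)]
  }, "")
}

# Study id for dataset j: studies hold 1-2 datasets (15 datasets -> 10
# studies, mirroring a typical compendium). Internal.
study_of <- function(j) ceiling(2L * j / 3L)

#' Generate a complete two-species test universe with known ground truth
#'
#' Builds, from one seed, everything the pipeline consumes: noisy
#' differential-expression tables with planted up/down regulation, ChIP peak
#' sets with per-dataset dropout around planted binding sites, TSS/gene-model
#' annotation, a one-to-one orthology table, a block-structured chain
#' alignment between the two single-chromosome genomes, a per-base
#' conservation track elevated over alignable blocks and conserved sites,
#' and genome sequences with p53 response elements embedded at every planted
#' p53 site (E2F + CHR elements at DREAM sites). The ground truth records
#' each gene's regulation class, direct-target status and true sites.
#'
#' Noise model: truly regulated genes are called in a dataset with
#' probability `detection_sensitivity`; detected calls draw
#' `|log2FC| = 0.5 + Gamma(2, rate 4)` and `adj_p ~ U(0, 0.05)`, missed ones
#' fall below one threshold or the other. Unregulated genes draw
#' `log2FC ~ N(0, 0.2)` truncated below the call threshold and uniform
#' p-values, and are forced to a spurious call (random direction) with
#' probability `false_call_rate` — so the noise-free limit recovers the
#' planted truth exactly.
#'
#' @param config A `grn_scenario_config` from [scenario_config()].
#' @return A list of class `grn_scenario` with elements `config`,
#'   `expression` (per species: named list of DE data.frames plus a dataset
#'   config), `chip` (per species and factor: GRanges with `dataset_id`),
#'   `chip_config`, `annotation`, `features`, `chrom_sizes`, `orthology`,
#'   `chains` (A to B), `conservation` (per species GRanges with `score`),
#'   `genome` (per species DNAStringSet) and `truth` (`genes`, `sites`).
#' @export
generate_scenario <- function(config = scenario_config()) {
  if (!inherits(config, "grn_scenario_config")) {
    config <- do.call(scenario_config, config)
  }
  with_seed(config$rng_seed, build_scenario(config))
}

build_scenario <- function(cfg) {
  n <- cfg$n_genes_per_species
  L <- cfg$genome_length
  S <- L %/% n
  n_pairs <- round(cfg$frac_one_to_one * n)
  chromA <- "chrA"; chromB <- "chrB"

  ## --- gene classes -------------------------------------------------------
  class_pair <- sample(REGULATION_CLASSES, n_pairs, replace = TRUE,
                       prob = cfg$regulation_class_probs[REGULATION_CLASSES])
  opp_up_in_A <- sample(c(TRUE, FALSE), n_pairs, replace = TRUE)

  dir_for <- function(class, species) {
    up <- class == "conserved_up" |
      (class == "A_up_only" & species == "A") |
      (class == "B_up_only" & species == "B") |
      (class == "opposite" &
         ((species == "A" & opp_up_in_A[seq_along(class)]) |
          (species == "B" & !opp_up_in_A[seq_along(class)])))
    down <- class == "conserved_down" |
      (class == "A_down_only" & species == "A") |
      (class == "B_down_only" & species == "B") |
      (class == "opposite" & !up & class == "opposite")
    ifelse(up, "up", ifelse(down, "down", "none"))
  }
  dir_A <- c(dir_for(class_pair, "A"), rep("none", n - n_pairs))
  dir_B <- c(dir_for(class_pair, "B"), rep("none", n - n_pairs))
  class_all <- c(class_pair, rep("unregulated", n - n_pairs))

  ## --- genome layout and alignment ---------------------------------------
  locus_start_A <- (seq_len(n) - 1L) * S + 1L
  tss_A <- locus_start_A + S %/% 2L + sample(-500:500, n, replace = TRUE)
  strand_A <- sample(c("+", "-"), n, replace = TRUE)

  conserved_locus <- class_all %in% c("conserved_up", "conserved_down")
  target_aligned <- max(round(cfg$conserved_block_fraction * n),
                        sum(conserved_locus))
  aligned <- conserved_locus
  extra <- target_aligned - sum(aligned)
  if (extra > 0L) {
    pool <- which(!aligned)
    aligned[sample(pool, min(extra, length(pool)))] <- TRUE
  }

  runs <- rle(aligned)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  blk_idx <- which(runs$values)
  n_blocks <- length(blk_idx)
  drift_per_gap <- if (n_blocks > 1L) {
    sample(-300:300, n_blocks - 1L, replace = TRUE)
  } else integer(0)
  cumdrift_block <- c(0L, cumsum(drift_per_gap))
  # per-locus offset of the B genome relative to A
  cd <- integer(n)
  if (n_blocks > 0L) {
    for (k in seq_len(n_blocks)) {
      from <- run_start[blk_idx[k]]
      cd[from:n] <- cumdrift_block[k]
    }
  }
  LB <- L + if (n_blocks > 0L) cumdrift_block[n_blocks] else 0L

  tss_B <- integer(n); strand_B <- character(n)
  paired <- seq_len(n) <= n_pairs
  tss_B[paired] <- tss_A[paired] + cd[paired] +
    sample(-200:200, sum(paired), replace = TRUE)
  strand_B[paired] <- strand_A[paired]
  if (any(!paired)) {
    locus_start_B <- locus_start_A + cd
    tss_B[!paired] <- locus_start_B[!paired] + S %/% 2L +
      sample(-500:500, sum(!paired), replace = TRUE)
    strand_B[!paired] <- sample(c("+", "-"), sum(!paired), replace = TRUE)
  }

  gene_A <- sprintf("gA%04d", seq_len(n))
  gene_B <- sprintf("gB%04d", seq_len(n))

  ## --- true binding sites -------------------------------------------------
  even_width <- function(k, lo, hi) 2L * sample((lo / 2):(hi / 2), k, replace = TRUE)
  site_rows <- list()
  add_sites <- function(species, tf, idx, tss, offset_max, widths, conserved,
                        mirror_from = NULL) {
    if (!length(idx)) return(NULL)
    if (is.null(mirror_from)) {
      center <- tss[idx] + sample(-offset_max:offset_max, length(idx),
                                  replace = TRUE)
    } else {
      center <- mirror_from
    }
    st <- center - widths %/% 2L
    data.frame(species = species, factor = tf,
               gene_id = if (species == "A") gene_A[idx] else gene_B[idx],
               chrom = if (species == "A") chromA else chromB,
               start = st, end = st + widths - 1L, center = center,
               conserved = conserved, stringsAsFactors = FALSE)
  }

  upA <- which(dir_A == "up"); upB <- which(dir_B == "up")
  dnA <- which(dir_A == "down"); dnB <- which(dir_B == "down")

  wA_p53 <- even_width(length(upA), 300L, 500L)
  sitesA_p53 <- add_sites("A", "p53", upA, tss_A, 2000L, wA_p53,
                          class_all[upA] == "conserved_up")
  consB <- upB[class_all[upB] == "conserved_up"]
  ownB <- setdiff(upB, consB)
  mirror_center <- sitesA_p53$center[match(gene_A[consB], sitesA_p53$gene_id)] +
    cd[consB]
  mirror_w <- (sitesA_p53$end - sitesA_p53$start + 1L)[
    match(gene_A[consB], sitesA_p53$gene_id)]
  sitesB_p53 <- rbind(
    add_sites("B", "p53", consB, tss_B, 2000L, mirror_w, TRUE,
              mirror_from = mirror_center),
    add_sites("B", "p53", ownB, tss_B, 2000L,
              even_width(length(ownB), 300L, 500L), FALSE)
  )

  wA_e2 <- even_width(length(dnA), 200L, 300L)
  sitesA_e2 <- add_sites("A", "e2f4", dnA, tss_A, 800L, wA_e2,
                         class_all[dnA] == "conserved_down")
  consBd <- dnB[class_all[dnB] == "conserved_down"]
  ownBd <- setdiff(dnB, consBd)
  mirror_center_d <- sitesA_e2$center[match(gene_A[consBd], sitesA_e2$gene_id)] +
    cd[consBd]
  mirror_w_d <- (sitesA_e2$end - sitesA_e2$start + 1L)[
    match(gene_A[consBd], sitesA_e2$gene_id)]
  sitesB_e2 <- rbind(
    add_sites("B", "e2f4", consBd, tss_B, 800L, mirror_w_d, TRUE,
              mirror_from = mirror_center_d),
    add_sites("B", "e2f4", ownBd, tss_B, 800L,
              even_width(length(ownBd), 200L, 300L), FALSE)
  )
  sites <- rbind(sitesA_p53, sitesB_p53, sitesA_e2, sitesB_e2)
  if (is.null(sites)) {
    sites <- data.frame(species = character(0), factor = character(0),
                        gene_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        center = integer(0), conserved = logical(0))
  }
  sites$motif_embedded <- rep(TRUE, nrow(sites))
  rownames(sites) <- NULL

  ## --- expression datasets ------------------------------------------------
  nd <- cfg$n_expression_datasets_per_species
  make_expression <- function(species, dir) {
    genes <- if (species == "A") gene_A else gene_B
    datasets <- list()
    for (j in seq_len(nd)) {
      reg <- dir != "none"
      sign <- ifelse(dir == "up", 1, ifelse(dir == "down", -1, 0))
      detected <- reg & (runif(n) < cfg$detection_sensitivity)
      lfc <- numeric(n); p <- numeric(n)
      k <- sum(detected)
      lfc[detected] <- sign[detected] * (0.5 + rgamma(k, shape = 2, rate = 4))
      p[detected] <- runif(k, 0, 0.05)
      missed <- reg & !detected
      km <- sum(missed)
      lfc[missed] <- sign[missed] * runif(km, 0, 0.45)
      p[missed] <- runif(km, 0.051, 1)
      null <- !reg
      kn <- sum(null)
      # truncated below the call threshold: spurious calls come only from
      # the explicit false-call flips, so the noise-free limit is exact
      lfc[null] <- pmax(pmin(rnorm(kn, 0, 0.2), 0.49), -0.49)
      p[null] <- runif(kn)
      flip <- null & (runif(n) < cfg$false_call_rate)
      kf <- sum(flip)
      if (kf) {
        fsign <- sample(c(-1, 1), kf, replace = TRUE)
        lfc[flip] <- fsign * (0.5 + rgamma(kf, shape = 2, rate = 4))
        p[flip] <- runif(kf, 0, 0.05)
      }
      id <- sprintf("%s_expr%02d", species, j)
      datasets[[id]] <- data.frame(gene_id = genes, log2fc = lfc, adj_p = p,
                                   stringsAsFactors = FALSE)
    }
    config <- data.frame(
      dataset_id = names(datasets),
      study_id = sprintf("%s_ES%02d", species, study_of(seq_len(nd))),
      species = species, lfc_min = NA_real_, p_max = NA_real_,
      stringsAsFactors = FALSE
    )
    list(data = datasets, config = config)
  }
  expression <- list(A = make_expression("A", dir_A),
                     B = make_expression("B", dir_B))

  ## --- ChIP datasets ------------------------------------------------------
  chip <- list(A = list(), B = list())
  chip_config <- list()
  for (species in c("A", "B")) {
    chrom <- if (species == "A") chromA else chromB
    glen <- if (species == "A") L else LB
    for (tf in c("p53", "e2f4")) {
      ndc <- cfg$n_chip_datasets[[species]][[tf]]
      tr <- sites[sites$species == species & sites$factor == tf, , drop = FALSE]
      grs <- list()
      for (j in seq_len(ndc)) {
        id <- sprintf("%s_%s_%02d", species, tf, j)
        keep <- runif(nrow(tr)) >= cfg$peak_dropout
        st <- tr$start[keep] - sample(0:100, sum(keep), replace = TRUE)
        en <- tr$end[keep] + sample(0:100, sum(keep), replace = TRUE)
        n_noise <- rpois(1L, max(1, 0.1 * nrow(tr)))
        ns <- sample.int(max(glen - 400L, 1L), n_noise)
        starts <- c(st, ns)
        gr <- GRanges(rep(chrom, length(starts)),
                      IRanges(starts, c(en, ns + 399L)))
        mcols(gr)$dataset_id <- rep(id, length(gr))
        grs[[id]] <- gr
        chip_config[[length(chip_config) + 1L]] <- data.frame(
          dataset_id = id,
          study_id = sprintf("%s_%s_S%02d", species, tf, study_of(j)),
          factor = tf, species = species, stringsAsFactors = FALSE)
      }
      chip[[species]][[tf]] <- do.call(c, unname(grs))
    }
  }
  chip_config <- do.call(rbind, chip_config)

  ## --- annotation, gene models, orthology ---------------------------------
  make_annotation <- function(species) {
    data.frame(
      gene_id = if (species == "A") gene_A else gene_B,
      chrom = if (species == "A") chromA else chromB,
      tss = if (species == "A") tss_A else tss_B,
      strand = if (species == "A") strand_A else strand_B,
      stringsAsFactors = FALSE
    )
  }
  annotation <- list(A = make_annotation("A"), B = make_annotation("B"))

  gene_model <- function(tss, strand, chrom, glen) {
    # strand-aware segments downstream of the TSS:
    # 5'UTR 200, exon 300, intron 600, exon 300, intron 600, exon 300, 3'UTR 300
    seg_len <- c(200L, 300L, 600L, 300L, 600L, 300L, 300L)
    seg_feat <- c("five_utr", "exon", "intron", "exon", "intron", "exon",
                  "three_utr")
    rows <- list()
    for (i in seq_along(tss)) {
      off <- cumsum(c(0L, seg_len))[seq_along(seg_len)]
      if (strand[i] == "+") {
        st <- tss[i] + off
        en <- st + seg_len - 1L
      } else {
        en <- tss[i] - off
        st <- en - seg_len + 1L
      }
      ok <- st >= 1L & en <= glen
      rows[[i]] <- data.frame(chrom = chrom, start = st[ok], end = en[ok],
                              feature = seg_feat[ok], stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end))
    mcols(gr)$feature <- df$feature
    gr
  }
  features <- list(
    A = gene_model(tss_A, strand_A, chromA, L),
    B = gene_model(tss_B, strand_B, chromB, LB)
  )

  orthology <- data.frame(
    gene_A = gene_A[seq_len(n_pairs)], gene_B = gene_B[seq_len(n_pairs)],
    homology_type = "one2one", stringsAsFactors = FALSE
  )
  unpairedA <- which(!paired); unpairedB <- which(!paired)
  if (length(unpairedA) >= 1L && length(unpairedB) >= 2L) {
    orthology <- rbind(orthology, data.frame(
      gene_A = gene_A[unpairedA[1L]],
      gene_B = gene_B[unpairedB[1:2]],
      homology_type = "one2many", stringsAsFactors = FALSE))
  }

  ## --- chain alignment ----------------------------------------------------
  chains <- NULL
  if (n_blocks > 0L) {
    blk_from <- run_start[blk_idx]; blk_to <- run_end[blk_idx]
    t0 <- (blk_from - 1L) * S
    t1 <- blk_to * S
    sizes <- t1 - t0
    dt <- if (n_blocks > 1L) t0[-1L] - t1[-n_blocks] else integer(0)
    dq <- dt + drift_per_gap
    q0 <- t0 + cumdrift_block
    ch <- list(
      score = sum(sizes), t_name = chromA, t_size = L, t_strand = "+",
      t_start = t0[1L], t_end = t1[n_blocks],
      q_name = chromB, q_size = LB, q_strand = "+",
      q_start = q0[1L], q_end = q0[n_blocks] + sizes[n_blocks],
      id = "1",
      blocks = data.frame(size = sizes,
                          dt = c(dt, NA_integer_), dq = c(dq, NA_integer_))
    )
    chains <- structure(list(ch), class = "grnx_chains")
  }

  ## --- conservation tracks -------------------------------------------------
  make_track <- function(chrom, glen, block_gr, cons_sites) {
    nb <- ceiling(glen / 25)
    st <- (seq_len(nb) - 1L) * 25L + 1L
    en <- pmin(seq_len(nb) * 25L, glen)
    val <- runif(nb, 0.02, 0.12)
    bins <- GRanges(chrom, IRanges(st, en))
    if (length(block_gr)) {
      val[countOverlaps(bins, block_gr) > 0L] <-
        val[countOverlaps(bins, block_gr) > 0L] + 0.15
    }
    if (nrow(cons_sites)) {
      cs <- GRanges(cons_sites$chrom, IRanges(cons_sites$start, cons_sites$end))
      hot <- countOverlaps(bins, cs) > 0L
      val[hot] <- 0.55 + runif(sum(hot), 0, 0.3)
    }
    mcols(bins)$score <- round(val, 4)
    seqlengths(bins) <- setNames(glen, chrom)
    bins
  }
  block_gr_A <- if (n_blocks > 0L) {
    GRanges(chromA, IRanges((run_start[blk_idx] - 1L) * S + 1L,
                            run_end[blk_idx] * S))
  } else GRanges()
  block_gr_B <- if (n_blocks > 0L) {
    GRanges(chromB, IRanges((run_start[blk_idx] - 1L) * S + 1L + cumdrift_block,
                            run_end[blk_idx] * S + cumdrift_block))
  } else GRanges()
  conservation <- list(
    A = make_track(chromA, L, block_gr_A,
                   sites[sites$species == "A" & sites$conserved, , drop = FALSE]),
    B = make_track(chromB, LB, block_gr_B,
                   sites[sites$species == "B" & sites$conserved, , drop = FALSE])
  )

  ## --- genome sequences with embedded motifs ------------------------------
  make_genome <- function(chrom, glen, sp_sites) {
    chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
    p53_sites <- sp_sites[sp_sites$factor == "p53", , drop = FALSE]
    for (i in seq_len(nrow(p53_sites))) {
      c0 <- p53_sites$center[i]
      motif <- realize_consensus(strrep("RRRCWWGYYY", 2L))
      pos <- (c0 - 10L):(c0 + 9L)
      ok <- pos >= 1L & pos <= glen
      chars[pos[ok]] <- motif[ok]
    }
    e2_sites <- sp_sites[sp_sites$factor == "e2f4", , drop = FALSE]
    for (i in seq_len(nrow(e2_sites))) {
      c0 <- e2_sites$center[i]
      motif <- c(realize_consensus("TTSSSSS"), realize_consensus("TTYGAA"))
      pos <- (c0 - 7L):(c0 + 5L)
      ok <- pos >= 1L & pos <= glen
      chars[pos[ok]] <- motif[ok]
    }
    ss <- DNAStringSet(paste0(chars, collapse = ""))
    names(ss) <- chrom
    ss
  }
  genome <- list(
    A = make_genome(chromA, L, sites[sites$species == "A", , drop = FALSE]),
    B = make_genome(chromB, LB, sites[sites$species == "B", , drop = FALSE])
  )

  ## --- ground truth --------------------------------------------------------
  truth_genes <- rbind(
    data.frame(species = "A", gene_id = gene_A, class = class_all,
               direction = dir_A, direct_target = dir_A == "up",
               dream_target = dir_A == "down",
               ortholog = ifelse(paired, gene_B, NA_character_),
               chrom = chromA, tss = tss_A, strand = strand_A,
               locus_aligned = aligned, stringsAsFactors = FALSE),
    data.frame(species = "B", gene_id = gene_B, class = class_all,
               direction = dir_B, direct_target = dir_B == "up",
               dream_target = dir_B == "down",
               ortholog = ifelse(paired, gene_A, NA_character_),
               chrom = chromB, tss = tss_B, strand = strand_B,
               locus_aligned = aligned, stringsAsFactors = FALSE)
  )

  structure(list(
    config = cfg, species = c("A", "B"),
    expression = expression,
    chip = chip, chip_config = chip_config,
    annotation = annotation, features = features,
    chrom_sizes = list(A = setNames(L, chromA), B = setNames(LB, chromB)),
    orthology = orthology, chains = chains,
    conservation = conservation, genome = genome,
    truth = list(genes = truth_genes, sites = sites,
                 class_counts = table(factor(class_pair,
                                             levels = REGULATION_CLASSES)))
  ), class = "grn_scenario")
}

#' Write a scenario to disk as a fixture bundle in standard formats
#'
#' Materialises every component of a [generate_scenario()] result in the
#' external formats the pipeline reads: DE tables and configs as TSV, peaks
#' as 3-column BED, annotation as TSV plus feature BED, orthology as TSV,
#' the alignment as a UCSC chain file, conservation as bedGraph, genomes as
#' FASTA and the ground truth as TSVs. A manifest listing every file with
#' its role, format and md5 checksum is written last.
#'
#' @param scenario A `grn_scenario`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest data.frame (`file`, `role`, `format`, `md5`),
#'   invisibly written to `manifest.tsv` as well.
#' @export
write_fixture_bundle <- function(scenario, out_dir) {
  stopifnot(inherits(scenario, "grn_scenario"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  entries <- list()
  emit <- function(rel, role, format) {
    entries[[length(entries) + 1L]] <<- data.frame(
      file = rel, role = role, format = format, stringsAsFactors = FALSE)
    file.path(out_dir, rel)
  }
  sub <- function(d) dir.create(file.path(out_dir, d), showWarnings = FALSE)
  for (d in c("expression", "chip", "annotation", "alignment",
              "conservation", "genome", "truth", "config")) sub(d)

  for (sp in c("A", "B")) {
    ex <- scenario$expression[[sp]]
    for (id in names(ex$data)) {
      write.table(ex$data[[id]],
                  emit(file.path("expression", paste0(id, ".tsv")),
                       "expression_dataset", "tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  expr_cfg <- rbind(scenario$expression$A$config, scenario$expression$B$config)
  write.table(expr_cfg, emit("config/expression_datasets.tsv",
                             "expression_config", "tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (sp in c("A", "B")) {
    for (tf in names(scenario$chip[[sp]])) {
      gr <- scenario$chip[[sp]][[tf]]
      cfg_ids <- scenario$chip_config$dataset_id[
        scenario$chip_config$species == sp & scenario$chip_config$factor == tf]
      for (id in cfg_ids) {
        write_bed(gr[mcols(gr)$dataset_id == id],
                  emit(file.path("chip", paste0(id, ".bed")),
                       "chip_dataset", "bed"))
      }
    }
  }
  write.table(scenario$chip_config, emit("config/chip_datasets.tsv",
                                         "chip_config", "tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (sp in c("A", "B")) {
    write.table(scenario$annotation[[sp]],
                emit(file.path("annotation", paste0("annotation_", sp, ".tsv")),
                     "annotation", "tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(scenario$features[[sp]],
              emit(file.path("annotation", paste0("features_", sp, ".bed")),
                   "features", "bed"),
              name = mcols(scenario$features[[sp]])$feature)
  }
  write.table(scenario$orthology, emit("config/orthology.tsv",
                                       "orthology", "tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(scenario$chains)) {
    write_chain(scenario$chains, emit("alignment/A_to_B.chain",
                                      "alignment", "chain"))
  }
  for (sp in c("A", "B")) {
    tr <- scenario$conservation[[sp]]
    df <- data.frame(chrom = as.character(seqnames(tr)),
                     start = start(tr) - 1L, end = end(tr),
                     score = mcols(tr)$score)
    write.table(df, emit(file.path("conservation",
                                   paste0("conservation_", sp, ".bedGraph")),
                         "conservation", "bedGraph"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    writeXStringSet(scenario$genome[[sp]],
                    emit(file.path("genome", paste0("genome_", sp, ".fa")),
                         "genome", "fasta"))
  }
  write.table(scenario$truth$genes, emit("truth/genes.tsv",
                                         "truth_genes", "tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(scenario$truth$sites, emit("truth/sites.tsv",
                                         "truth_sites", "tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- do.call(rbind, entries)
  manifest$md5 <- unname(md5sum(file.path(out_dir, manifest$file)))
  write.table(manifest, file.path(out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
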
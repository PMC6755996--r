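default_thresholds <- function() {
  list(
    lfc_min = 0.5, p_max = 0.05, min_present = 3L,
    window_p53 = 5000L, window_e2f4 = 1000L,
    es_min = 5L, chip_min = list(A = 3L, B = 5L), min_studies = 2L,
    diff_min = 8L, other_support_max = 3L,
    min_support = list(p53 = 4L, e2f4 = 4L),
    min_match = 0.1, flank = 2500L, motif_threshold = 0.85
  )
}

#' Build a pipeline configuration pointing at a fixture bundle
#'
#' Convenience constructor producing the configuration list [run_pipeline()]
#' expects, wired to the directory layout written by
#' [write_fixture_bundle()].
#'
#' @param bundle_dir Directory written by [write_fixture_bundle()].
#' @param out_dir Report output directory.
#' @param thresholds Named list overriding entries of the default threshold
#'   set (see [run_pipeline()]).
#' @param seed Seed recorded in the config (the pipeline itself is
#'   deterministic; the seed is for any downstream resampling).
#' @return A configuration list.
#' @export
fixture_pipeline_config <- function(bundle_dir, out_dir, thresholds = list(),
                                    seed = 1L) {
  thr <- utils::modifyList(default_thresholds(), thresholds)
  species <- lapply(c(A = "A", B = "B"), function(sp) {
    list(
      expression_dir = file.path(bundle_dir, "expression"),
      annotation = file.path(bundle_dir, "annotation",
                             paste0("annotation_", sp, ".tsv")),
      features = file.path(bundle_dir, "annotation",
                           paste0("features_", sp, ".bed")),
      genome = file.path(bundle_dir, "genome", paste0("genome_", sp, ".fa")),
      conservation = file.path(bundle_dir, "conservation",
                               paste0("conservation_", sp, ".bedGraph"))
    )
  })
  list(
    out_dir = out_dir, seed = seed, thresholds = thr,
    expression_config = file.path(bundle_dir, "config",
                                  "expression_datasets.tsv"),
    chip_dir = file.path(bundle_dir, "chip"),
    chip_config = file.path(bundle_dir, "config", "chip_datasets.tsv"),
    orthology = file.path(bundle_dir, "config", "orthology.tsv"),
    chain = file.path(bundle_dir, "alignment", "A_to_B.chain"),
    gene_sets = NULL,
    species = species
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full cross-species meta-analysis pipeline from a configuration
#'
#' Executes every stage in dependency order — expression scoring, binding
#' scoring and consensus peaks, direct-target and DREAM-candidate calling,
#' ortholog pairing with correlation and divergence classification,
#' cross-genome peak mapping with turnover counts and conservation
#' profiles, motif content and genomic-feature enrichment, optional gene-set
#' over-representation, and the common-direct-target report — writing each
#' stage's tables under `out_dir` and logging row counts to `summary.txt`.
#' The effective configuration (defaults resolved) is serialized to
#' `effective_config.yaml`; re-running from identical config and inputs
#' reproduces the report byte for byte.
#'
#' @param config A configuration list (see [fixture_pipeline_config()]) or
#'   the path to a YAML file with the same structure.
#' @return A report list with every stage's result, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  thr <- utils::modifyList(default_thresholds(),
                           if (is.null(config$thresholds)) list()
                           else config$thresholds)
  config$thresholds <- thr
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  cfg_path <- file.path(out_dir, "effective_config.yaml")
  yaml::write_yaml(config, cfg_path)
  # hash the configuration minus the output location, so that re-running the
  # same analysis into another directory reproduces the tables byte for byte
  hash_cfg <- config
  hash_cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(hash_cfg, tmp)
  cfg_hash <- unname(md5sum(tmp))
  unlink(tmp)
  hdr <- c(paste0("grnx ", as.character(packageVersion("grnx"))),
           paste0("config_hash ", cfg_hash))
  report <- list(config = config)

  expr_cfg <- run_stage("expression_config",
                        read_dataset_config(config$expression_config))
  chip_cfg <- run_stage("chip_config", read_dataset_config(config$chip_config))

  ## 1. expression scores
  scores <- list()
  for (sp in c("A", "B")) {
    scores[[sp]] <- run_stage(paste0("expression_scores_", sp), {
      ids <- expr_cfg$dataset_id[expr_cfg$species == sp]
      paths <- setNames(
        file.path(config$species[[sp]]$expression_dir, paste0(ids, ".tsv")), ids)
      calls <- read_de_tables(paths)
      compute_expression_scores(calls, dataset_config = expr_cfg,
                                min_present = thr$min_present,
                                lfc_min = thr$lfc_min, p_max = thr$p_max)
    })
    write_tsv(scores[[sp]],
              file.path(out_dir, paste0("expression_scores_", sp, ".tsv")), hdr)
    note("expression_scores_", sp, ": ", nrow(scores[[sp]]), " genes")
  }
  report$expression_scores <- scores

  ## 2. binding scores and consensus peaks
  annot <- lapply(c(A = "A", B = "B"),
                  function(sp) read_annotation(config$species[[sp]]$annotation))
  binding <- list(); consensus <- list()
  for (sp in c("A", "B")) {
    binding[[sp]] <- list(); consensus[[sp]] <- list()
    for (tf in c("p53", "e2f4")) {
      sel <- chip_cfg$species == sp & chip_cfg$factor == tf
      ids <- chip_cfg$dataset_id[sel]
      if (!length(ids)) next
      peaks <- run_stage(paste0("read_chip_", sp, "_", tf), {
        read_peak_beds(setNames(
          file.path(config$chip_dir, paste0(ids, ".bed")), ids))
      })
      window <- if (tf == "p53") thr$window_p53 else thr$window_e2f4
      binding[[sp]][[tf]] <- run_stage(paste0("binding_scores_", sp, "_", tf),
        assign_peaks_to_tss(peaks, annot[[sp]], window = window,
                            dataset_config = chip_cfg))
      consensus[[sp]][[tf]] <- run_stage(paste0("consensus_", sp, "_", tf),
        build_consensus_peaks(peaks, min_support = thr$min_support[[tf]]))
      write_tsv(binding[[sp]][[tf]],
                file.path(out_dir, paste0("binding_scores_", sp, "_", tf, ".tsv")),
                hdr)
      write_bed(consensus[[sp]][[tf]],
                file.path(out_dir, paste0("consensus_", sp, "_", tf, ".bed")),
                score = mcols(consensus[[sp]][[tf]])$support)
      note("binding_", sp, "_", tf, ": ",
           sum(binding[[sp]][[tf]]$n_datasets_bound > 0), " bound genes, ",
           length(consensus[[sp]][[tf]]), " consensus peaks")
    }
  }
  report$binding_scores <- binding
  report$consensus_peaks <- consensus

  ## 3. target calling
  targets <- list(); dream <- list()
  for (sp in c("A", "B")) {
    chip_min <- if (is.list(thr$chip_min)) thr$chip_min[[sp]] else thr$chip_min
    targets[[sp]] <- run_stage(paste0("direct_targets_", sp),
      call_direct_targets(scores[[sp]], binding[[sp]]$p53,
                          es_min = thr$es_min, chip_min = chip_min,
                          min_studies = thr$min_studies))
    write_tsv(targets[[sp]],
              file.path(out_dir, paste0("direct_targets_", sp, ".tsv")), hdr)
    note("direct_targets_", sp, ": ", sum(targets[[sp]]$is_direct_target))
    if (!is.null(binding[[sp]]$e2f4)) {
      dream[[sp]] <- run_stage(paste0("dream_candidates_", sp),
        call_dream_candidates(scores[[sp]], binding[[sp]]$e2f4,
                              es_max = -thr$es_min,
                              min_studies = thr$min_studies))
      write_tsv(dream[[sp]],
                file.path(out_dir, paste0("dream_candidates_", sp, ".tsv")), hdr)
      note("dream_candidates_", sp, ": ", sum(dream[[sp]]$is_dream_candidate))
    }
  }
  report$direct_targets <- targets
  report$dream_candidates <- dream

  ## 4. ortholog comparison
  orthology <- run_stage("orthology", read_orthology(config$orthology))
  pairs <- run_stage("ortholog_pairs",
                     build_ortholog_pairs(orthology, scores$A, scores$B))
  write_tsv(pairs, file.path(out_dir, "ortholog_pairs.tsv"), hdr)
  note("ortholog_pairs: ", nrow(pairs))
  rho <- run_stage("spearman", {
    grid <- expand.grid(direction = c("up", "down"), reference = c("A", "B"),
                        stringsAsFactors = FALSE)
    grid$rho <- vapply(seq_len(nrow(grid)), function(i) {
      tryCatch(correlate_scores(pairs, grid$direction[i], grid$reference[i]),
               error = function(e) NA_real_)
    }, numeric(1))
    grid
  })
  write_tsv(rho, file.path(out_dir, "spearman.tsv"), hdr)
  divergence <- run_stage("divergence",
    classify_divergence(pairs, es_min = thr$es_min, diff_min = thr$diff_min,
                        other_support_max = thr$other_support_max))
  write_tsv(divergence, file.path(out_dir, "divergence.tsv"), hdr)
  note("divergent pairs: ", sum(divergence$passes_filter))
  report$pairs <- pairs; report$spearman <- rho; report$divergence <- divergence

  ## 5. cross-genome mapping, turnover, conservation profiles
  chains <- run_stage("chain", read_chain(config$chain))
  turnover <- list(); profiles <- list()
  cons_track <- lapply(c(A = "A", B = "B"), function(sp) {
    p <- config$species[[sp]]$conservation
    if (is.null(p) || !file.exists(p)) NULL else read_bedgraph_track(p)
  })
  mapped <- list(
    A_to_B = run_stage("map_A_to_B",
      map_intervals(consensus$A$p53, chains, min_match = thr$min_match)),
    B_to_A = run_stage("map_B_to_A",
      map_intervals(consensus$B$p53, invert_chain(chains),
                    min_match = thr$min_match))
  )
  turnover$A_to_B <- classify_turnover(mapped$A_to_B, consensus$B$p53)
  turnover$B_to_A <- classify_turnover(mapped$B_to_A, consensus$A$p53)
  for (d in names(turnover)) {
    tv <- turnover[[d]]
    write_tsv(data.frame(direction = d, t(tv$counts),
                         conserved_pct = tv$conserved_pct),
              file.path(out_dir, paste0("turnover_", d, ".tsv")), hdr)
    note("turnover_", d, ": ", tv$counts[["mapped_overlapping"]],
         " conserved / ", sum(tv$counts[c("mapped_overlapping",
                                          "mapped_nonoverlapping")]),
         " mapped (", round(tv$conserved_pct, 1), "%)")
  }
  for (sp in c("A", "B")) {
    if (is.null(cons_track[[sp]]) || !length(consensus[[sp]]$p53)) next
    profiles[[sp]] <- run_stage(paste0("profile_", sp),
      conservation_profile(consensus[[sp]]$p53, cons_track[[sp]],
                           flank = thr$flank))
    write_tsv(profiles[[sp]],
              file.path(out_dir, paste0("conservation_profile_", sp, "_p53.tsv")),
              hdr)
  }
  report$mapped <- mapped; report$turnover <- turnover
  report$profiles <- profiles

  ## 6. motif content and feature enrichment
  model <- motif_model("p53RE", threshold = thr$motif_threshold)
  motif_rows <- list(); feat <- list()
  for (sp in c("A", "B")) {
    gpath <- config$species[[sp]]$genome
    if (is.null(gpath) || !file.exists(gpath)) next
    genome <- readDNAStringSet(gpath)
    names(genome) <- sub("\\s.*$", "", names(genome))
    fr <- run_stage(paste0("motif_fraction_", sp),
      fraction_peaks_with_motif(consensus[[sp]]$p53, genome, model))
    gw <- run_stage(paste0("motif_genomewide_", sp),
      genome_wide_motif_count(genome, model))
    motif_rows[[sp]] <- data.frame(species = sp, n_peaks = fr$n_peaks,
                                   n_with_motif = fr$n_with_motif,
                                   fraction = fr$fraction,
                                   genome_wide_hits = gw)
    note("motif_", sp, ": ", round(100 * fr$fraction, 1), "% of ",
         fr$n_peaks, " peaks; ", gw, " genome-wide hits")
    feats <- rtracklayer::import(config$species[[sp]]$features, format = "BED")
    mcols(feats)$feature <- mcols(feats)$name
    sizes <- setNames(Biostrings::width(genome), names(genome))
    feat[[sp]] <- run_stage(paste0("feature_enrichment_", sp),
      feature_enrichment(consensus[[sp]]$p53, annot[[sp]], feats, sizes))
    write_tsv(feat[[sp]],
              file.path(out_dir, paste0("feature_enrichment_", sp, ".tsv")), hdr)
  }
  if (length(motif_rows)) {
    write_tsv(do.call(rbind, motif_rows),
              file.path(out_dir, "motif_fractions.tsv"), hdr)
  }
  report$motif <- motif_rows; report$feature_enrichment <- feat

  ## 7. gene-set over-representation (optional input)
  if (!is.null(config$gene_sets) && file.exists(config$gene_sets)) {
    sets <- read_gmt(config$gene_sets)
    for (sp in c("A", "B")) {
      q <- targets[[sp]]$gene_id[targets[[sp]]$is_direct_target]
      uni <- scores[[sp]]$gene_id
      if (length(q)) {
        enr <- run_stage(paste0("enrichment_", sp),
                         enrich_terms(q, sets, uni))
        write_tsv(enr, file.path(out_dir, paste0("enrichment_", sp, ".tsv")),
                  hdr)
        report$enrichment[[sp]] <- enr
      }
    }
  } else {
    note("enrichment: skipped (no gene_sets input)")
  }

  ## 8. common direct targets with binding-site conservation
  common <- run_stage("common_targets", {
    cons_flag <- annotate_site_conservation(
      pairs, annot$A, annot$B, consensus$A$p53, consensus$B$p53, chains,
      window = thr$window_p53, min_match = thr$min_match)
    intersect_direct_targets(pairs, targets$A, targets$B, cons_flag)
  })
  write_tsv(common, file.path(out_dir, "common_targets.tsv"), hdr)
  note("common_targets: ", nrow(common), " pairs (",
       sum(common$binding_site == "conserved"), " conserved site, ",
       sum(common$binding_site == "species_specific"), " species-specific)")
  report$common_targets <- common

  writeLines(c(paste0("# grnx pipeline summary (config ", cfg_hash, ")"),
               log_lines),
             file.path(out_dir, "summary.txt"))
  report$summary <- log_lines
  invisible(report)
}
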
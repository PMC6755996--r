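mk_scores <- function(gene, score, n_up = pmax(score, 0L),
                      n_down = pmax(-score, 0L)) {
  data.frame(gene_id = gene, n_up = n_up, n_down = n_down,
             n_ns = 15L - n_up - n_down, n_present = 15L, score = score,
             n_up_studies = pmin(n_up, 10L), n_down_studies = pmin(n_down, 10L),
             stringsAsFactors = FALSE)
}

test_that("pairing keeps only scored one-to-one orthologs", {
  orth <- data.frame(
    gene_A = c("a1", "a2", "a3", "a4", "a4"),
    gene_B = c("b1", "b2", "b3", "b4", "b5"),
    homology_type = c("one2one", "one2one", "one2one", "one2many", "one2many"))
  sa <- mk_scores(c("a1", "a2"), c(5L, -3L))
  sb <- mk_scores(c("b1", "b2", "b3"), c(4L, 0L, 2L))
  pairs <- build_ortholog_pairs(orth, sa, sb)
  expect_equal(pairs$gene_A, c("a1", "a2"))  # a3 unscored in A, a4 one2many
  expect_equal(pairs$score_B, c(4L, 0L))
  # a gene in two one2one rows is an input error
  bad <- rbind(orth, data.frame(gene_A = "a1", gene_B = "b9",
                                homology_type = "one2one"))
  expect_error(build_ortholog_pairs(bad, sa, sb), "more than one")
})

test_that("pair count equals a brute-force recount on the fixture", {
  sc <- SC_TINY
  sa <- compute_expression_scores(expr_calls(sc, "A"), sc$expression$A$config)
  sb <- compute_expression_scores(expr_calls(sc, "B"), sc$expression$B$config)
  pairs <- build_ortholog_pairs(sc$orthology, sa, sb)
  oo <- sc$orthology[sc$orthology$homology_type == "one2one", ]
  expected <- sum(oo$gene_A %in% sa$gene_id & oo$gene_B %in% sb$gene_id)
  expect_equal(nrow(pairs), expected)
})

test_that("Spearman correlation matches rank-then-Pearson to 1e-12", {
  set.seed(31)
  pairs <- data.frame(gene_A = paste0("a", 1:50), gene_B = paste0("b", 1:50),
                      score_A = sample(-15:15, 50, TRUE),
                      score_B = sample(-15:15, 50, TRUE))
  pairs$n_up_A <- pmax(pairs$score_A, 0L); pairs$n_down_A <- pmax(-pairs$score_A, 0L)
  pairs$n_up_B <- pmax(pairs$score_B, 0L); pairs$n_down_B <- pmax(-pairs$score_B, 0L)
  for (dir in c("up", "down")) for (ref in c("A", "B")) {
    rho <- correlate_scores(pairs, dir, ref)
    refv <- if (ref == "A") pairs$score_A else pairs$score_B
    sel <- if (dir == "up") refv > 0 else refv < 0
    expected <- cor(rank(pairs$score_A[sel]), rank(pairs$score_B[sel]),
                    method = "pearson")
    expect_equal(rho, expected, tolerance = 1e-12)
  }
  # degenerate extremes
  p2 <- pairs; p2$score_B <- p2$score_A
  expect_equal(correlate_scores(p2, "up", "A"), 1)
  p3 <- pairs; p3$score_B <- -p3$score_A
  expect_equal(correlate_scores(p3, "up", "A"), -1)
  expect_error(correlate_scores(pairs[1:2, ], "up", "A"), "fewer than 3")
})

div_pair <- function(score_A, score_B, n_up_A = pmax(score_A, 0L),
                     n_down_A = pmax(-score_A, 0L),
                     n_up_B = pmax(score_B, 0L),
                     n_down_B = pmax(-score_B, 0L)) {
  data.frame(gene_A = "a", gene_B = "b", score_A = score_A, score_B = score_B,
             n_up_A = n_up_A, n_down_A = n_down_A,
             n_up_B = n_up_B, n_down_B = n_down_B)
}

test_that("divergence tags reproduce the published worked examples", {
  # GADD45A-like: strongly up in one species, silent in the other
  g <- classify_divergence(div_pair(16L, 0L, n_up_B = 0L))
  expect_true(g$A_up_only)
  expect_false(g$B_up_only || g$A_down_only || g$B_down_only)
  expect_true(g$passes_filter)
  # PSRC1-like: down in A (score -18), up in B (score 15) -> two tags
  p <- classify_divergence(div_pair(-18L, 15L, n_up_A = 0L, n_down_B = 0L))
  expect_true(p$A_down_only)
  expect_true(p$B_up_only)
  # below es_min nothing fires
  n <- classify_divergence(div_pair(4L, 4L))
  expect_false(any(unlist(n[c("A_up_only", "B_up_only", "A_down_only",
                              "B_down_only", "passes_filter")])))
  # support in the other species vetoes the tag even with a big difference
  v <- classify_divergence(div_pair(12L, 2L, n_up_B = 3L))
  expect_false(v$A_up_only)
})

test_that("common tags require both species and exclude the *_only tags", {
  c1 <- classify_divergence(div_pair(10L, 9L))
  expect_true(c1$common_up)
  expect_false(c1$passes_filter)
  c2 <- classify_divergence(div_pair(-10L, -9L))
  expect_true(c2$common_down)
  tags <- classify_divergence(div_pair(16L, 0L, n_up_B = 0L))
  expect_false(tags$common_up)
})

test_that("divergence classification is antisymmetric under species swap", {
  set.seed(17)
  n <- 200L
  pairs <- data.frame(
    gene_A = paste0("a", 1:n), gene_B = paste0("b", 1:n),
    score_A = sample(-15:15, n, TRUE), score_B = sample(-15:15, n, TRUE))
  pairs$n_up_A <- pmax(pairs$score_A, 0L) + sample(0:2, n, TRUE)
  pairs$n_down_A <- pmax(-pairs$score_A, 0L) + sample(0:2, n, TRUE)
  pairs$n_up_B <- pmax(pairs$score_B, 0L) + sample(0:2, n, TRUE)
  pairs$n_down_B <- pmax(-pairs$score_B, 0L) + sample(0:2, n, TRUE)
  swapped <- data.frame(
    gene_A = pairs$gene_B, gene_B = pairs$gene_A,
    score_A = pairs$score_B, score_B = pairs$score_A,
    n_up_A = pairs$n_up_B, n_down_A = pairs$n_down_B,
    n_up_B = pairs$n_up_A, n_down_B = pairs$n_down_A)
  d1 <- classify_divergence(pairs)
  d2 <- classify_divergence(swapped)
  expect_identical(d1$A_up_only, d2$B_up_only)
  expect_identical(d1$A_down_only, d2$B_down_only)
  expect_identical(d1$common_up, d2$common_up)
  expect_identical(d1$passes_filter, d2$passes_filter)
})

test_that("common direct targets split into conserved and specific sites", {
  sc <- SC_NF
  sa <- compute_expression_scores(expr_calls(sc, "A"), sc$expression$A$config)
  sb <- compute_expression_scores(expr_calls(sc, "B"), sc$expression$B$config)
  pairs <- build_ortholog_pairs(sc$orthology, sa, sb)
  bsA <- assign_peaks_to_tss(sc$chip$A$p53, sc$annotation$A, 5000L,
                             sc$chip_config)
  bsB <- assign_peaks_to_tss(sc$chip$B$p53, sc$annotation$B, 5000L,
                             sc$chip_config)
  tA <- call_direct_targets(sa, bsA, chip_min = 3L)
  tB <- call_direct_targets(sb, bsB, chip_min = 5L)
  consA <- build_consensus_peaks(sc$chip$A$p53, min_support = 4L)
  consB <- build_consensus_peaks(sc$chip$B$p53, min_support = 4L)
  flag <- annotate_site_conservation(pairs, sc$annotation$A, sc$annotation$B,
                                     consA, consB, sc$chains)
  common <- intersect_direct_targets(pairs, tA, tB, flag)
  truth <- sc$truth$genes
  planted <- truth$gene_id[truth$species == "A" & truth$class == "conserved_up"]
  expect_setequal(common$gene_A, planted)
  # planted conserved_up pairs share the (mirrored) binding site
  expect_true(all(common$binding_site == "conserved"))
  expect_equal(nrow(common),
               sum(common$binding_site == "conserved") +
                 sum(common$binding_site == "species_specific"))
  expect_error(intersect_direct_targets(pairs, tA, tB, flag[-1]),
               "annotation does not match")
})

test_that("pairs binding only non-alignable sites are species-specific", {
  pairs <- data.frame(gene_A = "a1", gene_B = "b1")
  annA <- data.frame(gene_id = "a1", chrom = "chrA", tss = 50000L, strand = "+")
  annB <- data.frame(gene_id = "b1", chrom = "chrB", tss = 50000L, strand = "+")
  consA <- GenomicRanges::GRanges("chrA", IRanges::IRanges(49000L, 49400L))
  consB <- GenomicRanges::GRanges("chrB", IRanges::IRanges(52000L, 52400L))
  # identity-like chain covering the whole region
  ch <- structure(list(list(
    score = 1e5, t_name = "chrA", t_size = 100000L, t_strand = "+",
    t_start = 0L, t_end = 100000L, q_name = "chrB", q_size = 100000L,
    q_strand = "+", q_start = 0L, q_end = 100000L, id = "1",
    blocks = data.frame(size = 100000L, dt = NA_integer_, dq = NA_integer_))),
    class = "grnx_chains")
  # both genes bound, but images do not overlap -> species-specific
  flag <- annotate_site_conservation(pairs, annA, annB, consA, consB, ch)
  expect_false(flag)
  # move the B site onto the image of the A site -> conserved
  consB2 <- GenomicRanges::GRanges("chrB", IRanges::IRanges(49300L, 49700L))
  expect_true(annotate_site_conservation(pairs, annA, annB, consA, consB2, ch))
})

test_that("curated common-target table carries the published split", {
  tab <- common_targets_table()
  expect_equal(nrow(tab), 86L)
  expect_equal(sum(tab$binding_site == "conserved"), 58L)
  expect_equal(sum(tab$binding_site == "species_specific"), 28L)
  expect_false(anyDuplicated(tab$gene) > 0)
  expect_equal(round(100 * mean(tab$binding_site == "conserved")), 67)
})
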
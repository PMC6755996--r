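test_that("regulation calls respect inclusive thresholds", {
  expect_equal(call_regulation(0.5, 0.05), "up")
  expect_equal(call_regulation(-0.6, 0.01), "down")
  expect_equal(call_regulation(0.8, 0.2), "ns")
  expect_equal(call_regulation(0.49, 0.01), "ns")
  expect_equal(call_regulation(-0.5, 0.05), "down")
  expect_equal(
    call_regulation(c(1, -1, 0.2), c(0.01, 0.01, 0.01)),
    c("up", "down", "ns"))
  expect_error(call_regulation(NA_real_, 0.01), "non-finite")
  expect_error(call_regulation(Inf, 0.01), "non-finite")
  expect_error(call_regulation(1, 1.5), "adj_p")
})

make_calls <- function(gene, verdicts) {
  n <- length(verdicts)
  data.frame(
    gene_id = gene, dataset_id = paste0("d", seq_len(n)),
    log2fc = ifelse(verdicts == "up", 1, ifelse(verdicts == "down", -1, 0)),
    adj_p = ifelse(verdicts == "ns", 0.5, 0.01),
    stringsAsFactors = FALSE
  )
}

test_that("expression scores tally up minus down over present datasets", {
  calls <- rbind(
    make_calls("g1", rep(c("up", "ns"), c(10, 5))),
    make_calls("g2", rep(c("up", "down", "ns"), c(3, 3, 9))),
    make_calls("g3", c("up", "up"))  # present in only 2 datasets
  )
  es <- compute_expression_scores(calls)
  expect_equal(es$gene_id, c("g1", "g2"))
  expect_equal(es$score, c(10L, 0L))
  expect_equal(es$n_present, c(15L, 15L))
  expect_equal(es$n_up + es$n_down + es$n_ns, es$n_present)
  # the sparsely measured gene survives a looser presence filter
  expect_true("g3" %in% compute_expression_scores(calls, min_present = 2)$gene_id)
})

test_that("duplicate gene/dataset rows are rejected", {
  calls <- make_calls("g1", c("up", "up", "ns"))
  calls$dataset_id[2] <- "d1"
  expect_error(compute_expression_scores(calls), "duplicate")
})

test_that("per-dataset threshold overrides are honoured", {
  calls <- data.frame(
    gene_id = "g1", dataset_id = c("d1", "d2", "d3"),
    log2fc = c(0.8, 0.8, 0.8), adj_p = c(0.01, 0.01, 0.01))
  cfg <- data.frame(dataset_id = c("d1", "d2", "d3"),
                    study_id = c("s1", "s2", "s3"),
                    lfc_min = c(NA, 1.0, NA), p_max = NA_real_)
  es <- compute_expression_scores(calls, dataset_config = cfg)
  expect_equal(es$score, 2L)  # d2 demands |lfc| >= 1 and calls ns
  expect_equal(es$n_up_studies, 2L)
})

test_that("scores match an independent brute-force tally on a noisy fixture", {
  calls <- expr_calls(SC_TINY, "A")
  es <- compute_expression_scores(calls, SC_TINY$expression$A$config)
  ref <- oracle_scores(calls)
  expect_equal(es$gene_id, ref$gene_id)
  expect_identical(es$score, ref$score)
  expect_identical(es$n_up, ref$n_up)
  expect_identical(es$n_down, ref$n_down)
  expect_identical(es$n_present, ref$n_present)
})

test_that("negating every fold change negates every score", {
  calls <- expr_calls(SC_TINY, "B")
  flipped <- calls
  flipped$log2fc <- -flipped$log2fc
  a <- compute_expression_scores(calls)
  b <- compute_expression_scores(flipped)
  expect_equal(a$gene_id, b$gene_id)
  expect_identical(a$score, -b$score)
  expect_identical(a$n_up, b$n_down)
})

test_that("noise-free planted signals give exact extreme scores", {
  esA <- compute_expression_scores(expr_calls(SC_NF, "A"),
                                   SC_NF$expression$A$config)
  esB <- compute_expression_scores(expr_calls(SC_NF, "B"),
                                   SC_NF$expression$B$config)
  truth <- SC_NF$truth$genes
  upA <- truth$gene_id[truth$species == "A" & truth$direction == "up"]
  noneB <- truth$gene_id[truth$species == "B" & truth$direction == "none"]
  expect_true(all(esA$score[esA$gene_id %in% upA] == 15L))
  expect_true(all(esB$score[esB$gene_id %in% noneB] == 0L))
})

test_that("score histogram merges sparse extreme groups inward", {
  hist0 <- score_group_histogram(c(0L, 0L, 0L))
  expect_equal(hist0, data.frame(score = 0L, n_genes = 3L))
  scores <- c(-13L, rep(-12L, 5L), rep(0L, 10L), rep(6L, 3L))
  h <- score_group_histogram(scores, merge_min_size = 2L)
  expect_false(-13L %in% h$score)
  expect_equal(h$n_genes[h$score == -12L], 6L)  # singleton folded inward
  expect_equal(sum(h$n_genes), length(scores))
  # merging off by default
  expect_true(-13L %in% score_group_histogram(scores)$score)
})

test_that("noise-free histogram reflects planted class sizes", {
  es <- compute_expression_scores(expr_calls(SC_NF, "A"),
                                  SC_NF$expression$A$config)
  h <- score_group_histogram(es)
  truth <- SC_NF$truth$genes[SC_NF$truth$genes$species == "A", ]
  expect_equal(h$n_genes[h$score == 15L], sum(truth$direction == "up"))
  expect_equal(h$n_genes[h$score == -15L], sum(truth$direction == "down"))
  expect_equal(h$n_genes[h$score == 0L], sum(truth$direction == "none"))
})

test_that("leave-one-out concordance is perfect for identical datasets", {
  calls <- rbind(
    do.call(rbind, lapply(1:3, function(d) {
      data.frame(gene_id = paste0("g", 1:20), dataset_id = paste0("d", d),
                 log2fc = rep(c(1, 0), each = 10),
                 adj_p = rep(c(0.01, 0.8), each = 10))
    }))
  )
  loo <- leave_one_out_concordance(calls)
  top <- loo[loo$remaining_score == 2L, ]
  expect_true(all(top$recovery == 1))
  expect_error(leave_one_out_concordance(calls[calls$dataset_id != "d3", ]),
               "at least 3")
})

test_that("a pure-noise dataset recovers regulated genes at the noise rate", {
  set.seed(7)
  n <- 4000L
  rate <- 0.04
  informative <- lapply(1:2, function(d) {
    data.frame(gene_id = paste0("g", 1:n), dataset_id = paste0("d", d),
               log2fc = rep(c(1, 0), each = n / 2),
               adj_p = rep(c(0.01, 0.8), each = n / 2))
  })
  flip <- runif(n) < rate
  noise <- data.frame(
    gene_id = paste0("g", 1:n), dataset_id = "noise",
    log2fc = ifelse(flip, sample(c(1, -1), n, TRUE), 0),
    adj_p = ifelse(flip, 0.01, 0.8))
  loo <- leave_one_out_concordance(do.call(rbind, c(informative, list(noise))))
  nz <- loo[loo$dataset_id == "noise" & loo$remaining_score == 2L &
              loo$direction == "up", ]
  # spurious calls split between directions: expect ~ rate / 2
  expect_lt(abs(nz$recovery - rate / 2),
            3 * sqrt((rate / 2) * (1 - rate / 2) / nz$n_genes))
})

test_that("recovery rises with the remaining-score bin on synthetic data", {
  calls <- expr_calls(SC_TINY, "A")
  loo <- leave_one_out_concordance(calls, SC_TINY$expression$A$config)
  up <- loo[loo$direction == "up" & loo$n_genes >= 2, ]
  trend <- cor(up$remaining_score, up$recovery, method = "spearman")
  expect_gt(trend, 0)
})
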
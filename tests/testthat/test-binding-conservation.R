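library(GenomicRanges)

# helper: build a chain set in code and round-trip it through the writer
make_chains <- function(chain_specs, path = tempfile(fileext = ".chain")) {
  chains <- structure(lapply(seq_along(chain_specs), function(i) {
    cs <- chain_specs[[i]]
    cs$id <- as.character(i)
    cs
  }), class = "grnx_chains")
  write_chain(chains, path)
  read_chain(path)
}

identity_chain <- function(len = 100000L, t_name = "chrA", q_name = "chrB") {
  list(score = len, t_name = t_name, t_size = len, t_strand = "+",
       t_start = 0L, t_end = len, q_name = q_name, q_size = len,
       q_strand = "+", q_start = 0L, q_end = len,
       blocks = data.frame(size = len, dt = NA_integer_, dq = NA_integer_))
}

gapped_chain <- function() {
  # blocks: [0,1000) -> [0,1000); gap dt=500/dq=300; [1500,2500) -> [1300,2300)
  list(score = 2000, t_name = "chrA", t_size = 10000L, t_strand = "+",
       t_start = 0L, t_end = 2500L, q_name = "chrB", q_size = 10000L,
       q_strand = "+", q_start = 0L, q_end = 2300L,
       blocks = data.frame(size = c(1000L, 1000L), dt = c(500L, NA),
                           dq = c(300L, NA)))
}

test_that("chain parser validates structure and reports line numbers", {
  ch <- make_chains(list(gapped_chain()))
  expect_s3_class(ch, "grnx_chains")
  expect_equal(ch[[1]]$blocks$size, c(1000L, 1000L))
  bad <- tempfile()
  writeLines(c("chain 1 chrA 100 + 0 50 chrB 100 + 0 40 1", "50 x y"), bad)
  expect_error(read_chain(bad), "line 2")
  bad2 <- tempfile()
  writeLines(c("chain 1 chrA 100 + 0 50 chrB 100 + 0 40 1", "30"), bad2)
  expect_error(read_chain(bad2), "span")
})

test_that("identity chains map every interval onto itself", {
  ch <- make_chains(list(identity_chain()))
  iv <- GRanges("chrA", IRanges(c(10L, 5000L, 99000L), width = 200L))
  m <- map_intervals(iv, ch)
  expect_true(all(m$status == "mapped"))
  expect_equal(m$mapped_fraction, rep(1, 3))
  expect_equal(m$target_start, start(iv))
  expect_equal(m$target_end, end(iv))
})

test_that("intervals inside source gaps stay unmapped", {
  ch <- make_chains(list(gapped_chain()))
  m <- map_intervals(GRanges("chrA", IRanges(1100L, 1400L)), ch)
  expect_equal(m$status, "unmapped")
  expect_equal(m$mapped_fraction, 0)
  # an interval straddling the gap maps, spanning the target-side gap
  m2 <- map_intervals(GRanges("chrA", IRanges(901L, 1600L)), ch)
  expect_equal(m2$status, "mapped")
  expect_equal(m2$target_start, 901L)
  expect_equal(m2$target_end, 1400L)  # 1600 shifted by dt-dq = -200
  expect_equal(m2$mapped_fraction, 200 / 700, tolerance = 1e-12)
})

test_that("min_match controls whether partial overlaps map", {
  ch <- make_chains(list(gapped_chain()))
  iv <- GRanges("chrA", IRanges(951L, 1450L))  # 50 of 500 bases aligned
  expect_equal(map_intervals(iv, ch, min_match = 0.1)$status, "mapped")
  expect_equal(map_intervals(iv, ch, min_match = 0.2)$status, "unmapped")
})

test_that("mapping agrees with the per-base oracle on random fixtures", {
  set.seed(23)
  specs <- list(
    gapped_chain(),
    list(score = 1000, t_name = "chrA", t_size = 10000L, t_strand = "+",
         t_start = 3000L, t_end = 4200L, q_name = "chrC", q_size = 10000L,
         q_strand = "+", q_start = 100L, q_end = 1500L,
         blocks = data.frame(size = c(400L, 500L), dt = c(300L, NA),
                             dq = c(500L, NA)))
  )
  ch <- make_chains(specs)
  iv <- GRanges("chrA", IRanges(sample(1:4500, 120, TRUE),
                                width = sample(20:600, 120, TRUE)))
  m <- map_intervals(iv, ch, min_match = 0.1)
  for (i in seq_along(iv)) {
    ref <- oracle_map_one("chrA", start(iv)[i], end(iv)[i], ch, 0.1)
    expect_equal(m$status[i], ref$status, info = paste("interval", i))
    expect_equal(m$mapped_fraction[i], ref$fraction, tolerance = 1e-12)
    if (ref$status == "mapped") {
      expect_equal(m$target_chrom[i], ref$target_chrom)
      expect_equal(m$target_start[i], ref$target_start)
      expect_equal(m$target_end[i], ref$target_end)
    }
  }
})

test_that("mapping then inverse mapping returns the original interval", {
  ch <- make_chains(list(gapped_chain()))
  iv <- GRanges("chrA", IRanges(c(100L, 1600L), width = 150L))
  fwd <- map_intervals(iv, ch)
  back <- map_intervals(
    GRanges(fwd$target_chrom, IRanges(fwd$target_start, fwd$target_end)),
    invert_chain(ch))
  expect_equal(back$target_start, start(iv))
  expect_equal(back$target_end, end(iv))
})

test_that("turnover classification partitions the input and matches counts", {
  # construct a mapped table with known categories
  n_un <- 5L; n_non <- 8L; n_ov <- 3L
  mapped <- data.frame(
    chrom = "chrA",
    start = seq_len(n_un + n_non + n_ov) * 1000L,
    end = seq_len(n_un + n_non + n_ov) * 1000L + 100L,
    status = rep(c("unmapped", "mapped", "mapped"), c(n_un, n_non, n_ov)),
    mapped_fraction = 1,
    chain_id = "1",
    target_chrom = "chrB",
    target_start = c(rep(NA, n_un), seq_len(n_non) * 1000L,
                     100000L + seq_len(n_ov) * 1000L),
    target_end = c(rep(NA, n_un), seq_len(n_non) * 1000L + 100L,
                   100000L + seq_len(n_ov) * 1000L + 100L))
  target <- GRanges("chrB", IRanges(100000L, 110000L))
  tv <- classify_turnover(mapped, target)
  expect_equal(unname(tv$counts), c(n_un, n_non, n_ov))
  expect_equal(sum(tv$counts), nrow(mapped))
  expect_equal(tv$conserved_fraction, n_ov / (n_ov + n_non))
  # shuffling input order leaves the counts unchanged
  tv2 <- classify_turnover(mapped[sample(nrow(mapped)), ], target)
  expect_equal(tv2$counts, tv$counts)
  # nothing overlapping -> 0%
  tv0 <- classify_turnover(mapped[mapped$status == "mapped", ][1:3, ], target)
  expect_equal(tv0$conserved_pct, 0)
})

test_that("a constant track yields a flat profile equal to the constant", {
  track <- GRanges("chr1", IRanges(seq(1L, 9981L, by = 10L), width = 10L))
  track$score <- 0.7
  GenomeInfoDb::seqlengths(track) <- c(chr1 = 10000L)
  sites <- GRanges("chr1", IRanges(c(4000L, 6000L), width = 100L))
  prof <- conservation_profile(sites, track, flank = 500L)
  expect_equal(nrow(prof), 1001L)
  expect_true(all(prof$mean_score == 0.7))
  expect_true(all(prof$n_sites == 2L))
})

test_that("a single in-bounds site returns the raw track slice", {
  set.seed(5)
  vals <- round(runif(1000), 3)
  track <- GRanges("chr1", IRanges(1:1000, width = 1L))
  track$score <- vals
  GenomeInfoDb::seqlengths(track) <- c(chr1 = 1000L)
  site <- GRanges("chr1", IRanges(500L, 501L))  # center 501
  prof <- conservation_profile(site, track, flank = 100L)
  expect_equal(prof$mean_score, vals[401:601])
  # sites whose window leaves the chromosome are dropped entirely
  edge <- GRanges("chr1", IRanges(c(30L, 500L), width = 2L))
  prof2 <- conservation_profile(edge, track, flank = 100L)
  expect_true(all(prof2$n_sites == 1L))
  expect_error(conservation_profile(GRanges(), track), "empty")
})

test_that("positions missing from the track are excluded, not zeroed", {
  track <- GRanges("chr1", IRanges(c(1L, 201L), c(100L, 300L)))
  track$score <- c(1, 0.5)
  GenomeInfoDb::seqlengths(track) <- c(chr1 = 300L)
  site <- GRanges("chr1", IRanges(150L, 151L))  # center 151
  prof <- conservation_profile(site, track, flank = 100L)
  covered <- prof[prof$n_sites > 0L, ]
  expect_true(all(covered$mean_score %in% c(1, 0.5)))
  gap <- prof[prof$n_sites == 0L, ]
  expect_gt(nrow(gap), 0L)
  expect_true(all(is.na(gap$mean_score)))
})

test_that("planted conserved sites show a centered conservation bump", {
  sc <- SC_TINY
  sites <- sc$truth$sites
  consA <- sites[sites$species == "A" & sites$conserved &
                   sites$factor == "p53", ]
  expect_gt(nrow(consA), 0L)
  gr <- GRanges(consA$chrom, IRanges(consA$start, consA$end))
  prof <- conservation_profile(gr, sc$conservation$A, flank = 2000L)
  center <- mean(prof$mean_score[abs(prof$offset) <= 50], na.rm = TRUE)
  edge <- mean(prof$mean_score[abs(prof$offset) >= 1900], na.rm = TRUE)
  expect_gt(center, edge)
})

test_that("binding-conserved sites out-conserve turned-over sites on synthetic data", {
  sc <- SC_TINY
  consA <- build_consensus_peaks(sc$chip$A$p53, min_support = 4L)
  consB <- build_consensus_peaks(sc$chip$B$p53, min_support = 4L)
  m <- map_intervals(consA, sc$chains)
  ok <- m$status == "mapped"
  expect_gte(sum(ok), 4L)
  img <- GRanges(m$target_chrom[ok], IRanges(m$target_start[ok],
                                             m$target_end[ok]))
  over <- countOverlaps(img, consB) > 0
  src <- consA[ok]
  profile_center <- function(gr) {
    p <- conservation_profile(gr, sc$conservation$A, flank = 1000L)
    mean(p$mean_score[abs(p$offset) <= 100], na.rm = TRUE)
  }
  expect_true(any(over) && any(!over))
  expect_gt(profile_center(src[over]), profile_center(src[!over]))
})
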
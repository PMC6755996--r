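---
title: "grnx: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{grnx: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Individual genome-wide experiments on p53-dependent regulation agree poorly
with one another: any two DE datasets from the same cell line and treatment
often overlap only partially, and ChIP peak sets vary with antibody,
protocol and caller. `grnx` implements a step-wise meta-analysis that turns
this heterogeneity into a confidence measure instead of trying to remove
it. The unit of evidence is a *dataset-level verdict*: a gene is called up-
or down-regulated in one dataset iff `|log2FC| >= lfc_min` and
`adj_p <= p_max`. The per-gene **Expression Score** is the number of
datasets voting up minus the number voting down. The score is deliberately
a count, not an effect-size average: datasets from different platforms are
not directly comparable, but their verdicts are.

The same logic applies to binding: a ChIP dataset supports a gene when at
least one of its peaks has its midpoint within a fixed promoter window of
the gene's TSS, and the per-gene binding score counts supporting datasets.
Direct-target calling intersects the two evidence streams and additionally
requires both to span at least two independent studies, which protects the
calls against a single study contributing several concordant datasets.

Assumptions worth making explicit:

* *Presence* means the gene appears as a row in a dataset's table,
  whatever the verdict. Probe-to-gene collapsing is upstream of this
  package; one row per gene per dataset is required, and duplicated
  (gene, dataset) rows are an error rather than silently merged.
* Scores treat all datasets symmetrically. Noisy datasets dilute scores
  rather than invalidate them; the leave-one-out concordance diagnostic
  (`leave_one_out_concordance()`) is the tool for spotting them.
* The DREAM arm uses E2F4 binding as a proxy for DREAM occupancy, so
  "DREAM candidate" means *repressed and E2F4-bound*, not a mechanistic
  claim.

# Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `lfc_min` | 0.5 | log2 | common threshold across heterogeneous platforms; inclusive |
| `p_max` | 0.05 | adj. p | inclusive; per-dataset overrides via the dataset config |
| `min_present` | 3 | datasets | below this a score is mostly noise |
| `window` (p53 / E2F4) | 5000 / 1000 | bp around TSS | p53 enhancers sit further out than the core-promoter DREAM elements |
| `es_min` | 5 | score | direct-target expression threshold |
| `chip_min` | 3 (9-set panel), 5 (28-set panel) | datasets | scales with panel size |
| `min_studies` | 2 | studies | explicit two-study rule for both evidence types |
| `diff_min` | 8 | score | between-species difference for divergence |
| `other_support_max` | 3 | datasets | "fewer than 3 datasets support it in the other species" |
| `min_support` | 4 | datasets | high-confidence consensus peaks |
| `min_match` | 0.1 | fraction | cross-species liftover practice (same-assembly tools use 0.95) |
| `flank` | 2500 | bp | conservation profile half-window |
| motif `threshold` | 0.85 | fraction of max log-odds | stringent but tolerant of one weak position |

On `min_support`: published analyses of this kind quote high-confidence
site sets with slightly inconsistent panel arithmetic (e.g. "at least 4 of
7" against a 9-dataset panel described elsewhere). Rather than guessing,
the support threshold is an explicit parameter everywhere, defaulting to 4.

# Committed interpretations

Several choices are interpretations of informally stated procedures; they
are deliberate and recorded here.

* **Divergence support is direction-specific.** "Fewer than three datasets
  supported its regulation in the other species" is evaluated against the
  same-direction dataset count (`n_up` or `n_down`), not the net score: a
  3-up/3-down gene nets to zero but is clearly not unsupported. One pair
  can legitimately carry two `*_only` tags (down in one species, up in the
  other — the PSRC1-like pattern).
* **Spearman subsetting by reference-species score sign.** The up/down
  correlation split restricts pairs to those with reference score > 0
  (resp. < 0) and is reported for both reference orientations, because the
  subset, and hence rho, depends on which species anchors it.
* **The two-study rule is an explicit post-filter** in both species and
  both evidence arms, including the DREAM arm, whose thresholds mirror the
  direct-target ones symmetrically (nothing is printed for the repressed
  side in the source analyses).
* **Peak midpoint, not any-overlap, defines TSS proximity**, with the
  even-length midpoint at `start + floor(len/2)` (0-based terms). This
  makes the window semantics unambiguous and matches center-to-TSS
  distance conventions.
* **Best chain wins.** An interval maps through the single chain covering
  most of its bases (ties: first chain in file order); the target interval
  spans the images of the first and last mapped bases. Only plus-strand
  co-linear chains are supported — inversions are out of scope.
* **Binding-site overlap means ≥ 1 bp**, both for consensus merging
  (single linkage) and for cross-genome conservation calls; adjacency does
  not merge.
* **The p53RE model is spacer-free**: two `RRRCWWGYYY` half sites head to
  tail. The log-odds matrix gives permitted bases weight 1 and
  non-permitted bases a 0.25 pseudocount against a uniform background; `N`
  scores 0 (background). A hit requires `threshold × max_score`, so
  raising the threshold can only lose hits.
* **Missing conservation-track positions are excluded from profile means**
  rather than imputed as 0: wiggle-style tracks are sparse, and
  zero-imputation biases profiles downward exactly where data are missing.
* **The ORA universe defaults to the scored genes of the species**, not
  the whole annotation — the set the analysis could in principle have
  called.

# The synthetic-data generator

`generate_scenario()` builds a complete two-species universe from one seed:
two single-chromosome genomes with one gene per ≥ 12 kb locus (so
neighbouring promoter windows never collide), ortholog pairs laid out
co-linearly, a multinomial draw of regulation classes over the pairs
(conserved up/down, four species-specific classes, an "opposite" class
planted as DREAM repression in one species and a p53 site in the other, and
unregulated), expression datasets with planted verdicts, ChIP panels with
per-dataset dropout plus Poisson background peaks, a block-structured chain
alignment with indels between blocks, a banded conservation track and
genome sequences with response elements embedded at every planted site.

The noise model is chosen so each knob maps to one failure mode:

* Regulated genes are *detected* in a dataset with probability
  `detection_sensitivity`; detected calls draw
  `|log2FC| = 0.5 + Gamma(shape 2, rate 4)` and `adj_p ~ U(0, 0.05)`, so
  threshold crossings are governed by the sensitivity parameter, not by
  the effect-size distribution. Missed calls fail the p threshold.
* Unregulated genes draw `log2FC ~ N(0, 0.2)` truncated at ±0.49 and
  uniform p-values; spurious calls are injected only by an explicit flip
  with probability `false_call_rate`. The truncation is what makes the
  noise-free limit exact: with sensitivity 1 and false-call rate 0, every
  planted class is recovered perfectly, which the test suite asserts.
* ChIP datasets miss each true site independently with probability
  `peak_dropout` and add ~10% background peaks at random positions.

Loci of conserved classes are always inside alignable blocks (their sites
must have images); additional random loci are aligned to reach
`conserved_block_fraction`. Between consecutive blocks the target genome
drifts by up to ±300 bp, which exercises coordinate shifts in the mapper.

What the generator does **not** emulate: read-level noise, peak-width and
score distributions of real callers, multi-chromosome karyotypes,
inversions, paralog interference in orthology, correlated errors between
datasets from the same study, and realistic motif divergence (elements are
embedded verbatim). Passing tests therefore demonstrate correctness of the
integration and comparison machinery under a controllable error model, not
performance on real compendia.

# Numerical and degenerate-input choices

* All thresholds are inclusive (`>=` / `<=`) exactly as documented.
* Score-group histogram merging (off by default) folds groups smaller than
  `merge_min_size` into the adjacent observed group nearer zero,
  cascading, never across zero; totals are preserved.
* `correlate_scores()` refuses subsets smaller than 3 pairs rather than
  returning an unstable number; ties get average ranks via R's
  `cor(method = "spearman")`.
* Empty peak sets are an error for motif fractions (a 0/0 fraction);
  feature classes with zero expected bases report `NA` enrichment instead
  of dividing by zero; turnover with nothing mapped reports an `NA`
  conserved fraction.
* Consensus support counts distinct datasets, never peaks, and is
  invariant to input file order; the same holds for binding scores.
* The pipeline writes no timestamps, and the config hash excludes the
  output directory, so identical inputs give byte-identical reports.

# Problem sizes

The shipped tests run two 40-gene scenarios (one at default noise, one
noise-free) for unit and property checks, a 1000-gene scenario for the
score-calibration check, and the default 600-gene scenario for the
precision/recall acceptance checks; oracle-equivalence fixtures stay below
10^5 bp and 10^3 genes so the brute-force references remain exact and fast.
The acceptance script runs the default 600-gene scenario end to end. These
sizes are the package's chosen study conditions for verification, small
enough to iterate on while large enough for the binomial expectations the
tests assert.

# Known limitations

* Only plus-strand, co-linear chain alignments are supported.
* No probe-collapse rule is provided; callers must supply one row per gene
  per dataset.
* The motif model is a consensus-derived PWM, not a fitted matrix; it is
  meant for reproducible screening, not for matching any specific motif
  library's hit lists.
* Real-compendium headline counts (tens of thousands of scored genes,
  hundreds of targets) require the original public datasets and genomes;
  this package reproduces the method and the arithmetic of the published
  summary tables, and verifies behaviour on synthetic data with known
  truth.
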
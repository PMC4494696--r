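---
title: "DGE tag profiling: models, parameters and design choices"
author: "tagdge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DGE tag profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

## The assay and what the package computes

Digital gene expression (DGE) tag profiling of the NlaIII/MmeI type
represents each polyadenylated transcript by a single 21-bp *tag*: NlaIII
retains the cDNA fragment from the most 3' CATG site to the poly(A)
tail, and MmeI cuts 17 bp downstream of that site, so every tag is
`CATG` plus 17 transcript-specific bases.  The number of times a tag is
sequenced is proportional to the abundance of its transcript and, unlike
shotgun RNA-seq, does not depend on transcript length.  Recovering the
transcript behind each tag requires mapping the 21-mers back to
reference sequence sets (transcriptomes, EST collections, a genome
draft).

`tagdge` implements the full computational side of such an experiment on
three FACS-sorted cell fractions (X1, proliferating stem cells; X2,
progeny plus some proliferating cells; Xin, differentiated cells):

* **virtual digestion** (`extract_theoretical_tags()`,
  `build_tag_index()`): the database of all theoretical CATG+17 tags per
  reference set, on both strands by default so that antisense
  transcription is detectable;
* **mapping** (`map_tags_exact()`, `map_tags_mismatch()`,
  `summarize_mapping()`, `reference_overlap()`);
* **expression statistics** (`filter_by_cutoff()`, `normalize_cpm()`,
  `compare_libraries()`, `splash_coordinates()`,
  `correlate_fractions()`, `fraction_assignments()`);
* **noise calibration and saturation** (`randomize_library()`,
  `randomize_reference()`, `specificity_scan()`, `recommend_cutoff()`,
  `saturation_curve()`);
* **functional enrichment** (`propagate_annotations()`,
  `hypergeom_two_tailed()`, `enrich_fraction_sets()`);
* **3'-UTR proximity** (`longest_orf()`, `place_transcripts()`,
  `proximity_profile()`);
* a **synthetic-data generator** (`synthetic_config()`,
  `generate_transcriptome()`, `generate_genome()`,
  `simulate_dge_library()`) providing ground truth for every stage, and
  `run_dge_pipeline()` tying them together.

## The binomial comparison test

Tag counts are normalised to counts per million (cpm), using the
library's *pre-filter* depth as denominator so that discarding rare tags
does not rescale the survivors (a switchable choice; the alternative
would renormalise after filtering).  To compare a tag between two
libraries, the cpm values are rounded *half-up* to pseudo-counts
$x \ge y$ and the tag's reads are treated as $x + y$ independent
observations, each equally likely to have come from either library:

$$ p \;=\; P(X \ge x), \qquad X \sim \mathrm{Binomial}(x+y,\ 1/2), $$

evaluated by exact tail summation in log space.  For $y = 0$ this
reduces to $p = 0.5^{x}$ exactly, and the half-up rounding convention is
what makes printed values such as $p(5.73, 0) = 2^{-6} = 1.56\times
10^{-2}$ and $p(5.22, 0) = 2^{-5} = 3.12\times 10^{-2}$ reproducible.
For pairs in which both sides are positive, published tables produced
with proprietary DGE software deviate from this rounded-cpm tail by tens
of percent (for example 23.11 vs 8.31 gives $5.34\times 10^{-3}$ by
exact summation where $3.67\times 10^{-3}$ has been printed); the
internal continuous-valued formula behind such values is not recoverable,
so only zero-side pairs are treated as exactly reproducible anchors.
The test is symmetric in its arguments, returns $p = 1$ for $x = y = 0$,
and `log10_p` stays exact when the p-value itself underflows.

No multiple-testing correction is applied by default — candidate
selection uses the raw $p < 0.001$ rule — but
`adjust_comparison()` adds a Benjamini–Hochberg column when wanted.

Two caveats this model inherits from the assay: the binomial law is
exact for counts, whereas the test is applied to rounded *cpm*; when a
library is much shallower than one million reads its cpm values exceed
its counts and the test becomes anti-conservative for that library.  At
the simulated depths (0.3–1 M reads) this inflates the candidate list of
the shallowest fraction; the planted-truth tests therefore score
recovery of known markers rather than specificity of the full list.

## Splashplot and fraction assignment

Three-fraction expression is projected onto signed log2 differences:
$x = \mathrm{sign}(X1 - Xin)\log_2|X1 - Xin|$ (and likewise $y$ with
X2), with differences of at most 1 cpm collapsed to the axis because the
logarithm of sub-unit differences would invert the sign semantics.
Quadrants then classify fraction specificity.  A tag's fraction is the
argmax of its cpm, accepted only if the tag differs from at least one
other fraction at $p < 0.001$.

## The occurrence cutoff and its null model

Tags seen only a handful of times may be sequencing artefacts.  The
calibration maps increasingly filtered versions of a library (cutoffs 1,
5, 10, 15, 20) and compares them with randomized libraries that resemble
the data in size and nucleotide abundance.  Two randomization
granularities are provided:

* `randomize_library(preserve_counts = TRUE)` keeps the exact
  rank-abundance vector and redraws only the tag sequences.  This
  isolates *sequence* specificity, but it makes the cutoff question
  degenerate by construction: each random tag maps with the same
  probability regardless of its assigned count, so the expected number
  of random hits at cutoff $c$ is proportional to the fixed number of
  candidate tags at $c$, and the hit ratio between cutoffs can only
  mirror the observed count distribution (about 5–7x between cutoffs 1
  and 5 in realistic libraries, and only 2.4x in typical published
  totals) — never the order-of-magnitude collapse the calibration looks
  for.
* `randomize_library(preserve_counts = FALSE)` randomizes at *read*
  level: the same number of reads is drawn as i.i.d. random 21-mers.
  Random reads essentially never recur, so virtually none survives a
  cutoff of five.  This is the null model `specificity_scan()` uses: it
  measures how much sequence noise each cutoff would let through, and it
  reproduces the rationale for the classic choice — reliable tags recur
  five times or more, noise tags occur about once.

`recommend_cutoff()` returns the smallest scanned cutoff after which the
random pass-through drops by less than one order of magnitude.  The drop
is estimated from actual random hits when the reference is large enough
for random matches to occur; against compact references (where a random
21-mer virtually never matches the index, as in the synthetic studies)
it uses the mean number of randomized tags passing each cutoff, of which
the expected hit count is a constant multiple.  On the default synthetic
scenario the recommendation is 5 across seeds.

Saturation analysis subsamples reads without replacement (hypergeometric
marginals) in steps of 200,000 by default and counts distinct mapped
tags per reference set; the implementation permutes the read vector once
and uses first-occurrence positions, so the curve ends exactly at the
full-library value.

## Tag mapping choices

* All theoretical tags per transcript are indexed; the **3'-most rule**
  is applied at mapping time: among observed tags hitting the same
  (reference, strand), only those at the maximal position keep the hit,
  ties are all kept (discarding them would silently lose counts), and a
  tag losing every hit is counted as orphan for that reference set.  The
  rule expresses the biology of transcripts — a transcript's real tag is
  the one closest to its 3' end — so the pipeline disables it for genome
  contigs, which concatenate many transcripts.
* Non-ACGT bases disqualify a window rather than being expanded into all
  compatible tags, which would inflate the index without adding exact
  matches.
* Mismatch-tolerant genome mapping (up to 2 substitutions, any of the 21
  positions including the CATG anchor) uses pigeonhole seeding on the
  three 7-mer thirds of the tag, verified by direct comparison; the test
  suite holds it against a naive full Hamming scan.
* Coordinates are 1-based and inclusive; `position` is the first base of
  CATG on the indexed strand, and minus-strand occurrences also carry
  the equivalent forward-strand interval, matching the GFF3 convention
  used for placements.
* Contamination screening is ordinary mapping against an additional
  reference set, not a special operation.

## GO enrichment

Annotations are propagated through is_a parent edges (cycle-checked)
before testing, so a term implies all its ancestors.  Enrichment of each
fraction's transcript set against the background of annotated sequences
uses the *minimum-likelihood two-tailed* hypergeometric test — the sum
of all outcome probabilities no larger than the observed one — which
captures both over- and under-representation in one p-value (threshold
$10^{-5}$ by default).  Effect sizes are Haldane-corrected log2 odds
ratios of the 2x2 study-by-term table.  The default background is the
set of sequences with at least one propagated annotation: unannotated
sequences carry no information in a term test, though any background can
be passed explicitly.

## The synthetic generator: what it emulates, and what not

Defaults were fixed once to mirror a scaled-down three-fraction study:

| parameter | default | why |
|---|---|---|
| `n_transcripts` | 150 | large enough for stable statistics, small enough for fast tests |
| `length_mean`, `length_sd` | 500, 150 nt | short-transcript regime where DGE shines |
| `gc_fraction` | 0.32 | AT-rich composition typical of flatworm sequence |
| `library_depths` | 1,000,000 / 958,000 / 321,000 | the X1:X2:Xin depth proportions of a sorted-fraction experiment, scaled so the deepest library is 1 M reads |
| baseline expression | log-normal, meanlog 1, sdlog 1.5 | heavy-tailed rank-abundance curves DGE libraries show |
| `de_spec` | 15 X1 / 3 X2 / 6 Xin transcripts at 8-fold | a minority of fraction-specific transcripts, X2 poorest in its own markers |
| `x2_mixture` | X2 = 0.6 X1 + 0.4 Xin | the intermediate fraction shares most of its transcripts with X1, making X1–X2 the most correlated pair |
| `antisense_rate` | 0.05 | antisense transcription at clearly lower level than sense |
| `error_rate` | 0.005 per read | single-substitution error after purity filtering; an artifact choice, since no published figure exists for the instrument |
| `novel_rate`, `n_withheld` | 0.01, 10 | reads from transcripts absent from the reference, producing orphan tags |

Markers are planted only on transcripts the assay can observe (not
withheld, not tagless).  The simulator pads a terminal CATG having fewer
than 17 downstream bases with the poly(A) tail; the reference index does
*not* pad by default, which deliberately produces a small orphan
fraction mirroring real unmapped-tag discussions.  Reads are simulated
at tag level — the analysis consumes tag counts only — with no quality
scores, no PCR duplicates and no FASTQ layer.  Consequently, passing
tests demonstrate correctness of the statistics and bookkeeping on data
with known truth, not robustness to alignment artefacts, sample
contamination or biological variability absent from this model.

## 3'-UTR proximity

Transcripts are oriented by their longest ATG-to-stop ORF across all six
frames (ties: forward strand, then smallest start) and placed on the
genome by exact substring search on both strands, or by supplied GFF3
placements.  The 3'-end coordinate is the placement end on the plus
strand and the start on the minus strand.  Genome-mapped tags within
1,000 bp of the *nearest* 3' end (nearest only, to avoid double counting
between adjacent transcripts) are binned by signed distance — positive
downstream — in 50-nt bins, and coverage is reported as the fraction of
CATG targets in the downstream windows that carry a sequenced tag (the
window-restricted denominator; a genome-wide denominator would dilute
the quantity with sites no 3'-anchored protocol could reach).
Poly(A)-site prediction and spliced projection are out of scope.

## Numerical and degenerate-input conventions

* Rounding of cpm pseudo-counts is half-up (`round_half_up()`), never
  banker's.
* Tail sums are computed in log space with a log-sum-exp guard;
  `p_value` is clamped to the smallest positive double on underflow
  while `log10_p` stays exact.
* An all-orphan mapping reports contigs-per-tag as 0 with a `degenerate`
  flag rather than `NA`, so summary tables stay numeric.
* Constant expression columns make Pearson correlation undefined; the
  coefficient is reported as `NA` with a warning.
* A library in which every tag falls below the cutoff is an error, not
  an empty library.
* All randomness funnels through explicit integer seeds;
  `run_dge_pipeline()` re-run with the same seed writes byte-identical
  numeric outputs.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the generator at its
default scale (150 transcripts, up to one million reads per library,
five replicate seeds for recovery and calibration checks, 60,000-read
libraries for the quick end-to-end fixtures, 100 kb genomes for the
mismatch-mapper oracle).  These sizes were chosen as the smallest at
which the statistical properties under test are stable; all operations
scale linearly in reads and tags, and the full-scale study (8.3 M reads,
98 k distinct tags) runs in minutes.

## Known limitations

* The comparison test reproduces published zero-side p-values exactly;
  both-sides pairs from proprietary software differ as described above.
* cpm-based pseudo-counts make the test anti-conservative for libraries
  well below one million reads (see the binomial section).
* The mismatch mapper tolerates substitutions only — no indels — as
  exact 21-mer semantics require.
* The ontology layer handles parent (is_a) edges; relationship typing
  beyond that is collapsed when importing richer ontologies.
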
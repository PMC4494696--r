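# tagdge

Digital gene expression (DGE) tag profiling for sorted cell fractions.

DGE of the NlaIII/MmeI type sequences a single 21-bp *tag* per
polyadenylated transcript — `CATG` (the 3'-most NlaIII site) plus the 17
bases MmeI leaves downstream — and counts how often each tag occurs.
Counts are proportional to transcript abundance and free of
transcript-length bias, which makes the assay well suited to comparing
FACS-sorted cell populations such as proliferating stem cells (X1),
their progeny (X2) and differentiated cells (Xin) in planarians.  The
analytical work happens after sequencing: recovering the transcript
behind each 21-mer and deciding which count differences are real.

`tagdge` implements that analysis end to end:

* **virtual digestion** — the database of all theoretical `CATG`+17 tags
  of a reference set (`build_tag_index()`), on both strands so sense and
  antisense transcription can be told apart;
* **tag mapping** — exact matching with the *3'-most rule* (when several
  observed tags hit one transcript, only the one closest to the 3' end
  keeps the hit), mismatch-tolerant genome rescue (≤ 2 substitutions,
  pigeonhole-seeded), per-reference summaries and multi-reference
  overlap counts;
* **expression statistics** — counts-per-million normalisation, the
  exact equal-chance binomial comparison test
  p = P(X ≥ x), X ~ Binomial(x + y, ½) on half-up-rounded cpm
  pseudo-counts (so a tag at 39.27 cpm against zero gives
  p = 2⁻³⁹ = 1.82·10⁻¹²), splashplot coordinates
  (signed log₂ |X1 − Xin| vs signed log₂ |X2 − Xin|) and Pearson /
  Spearman fraction correlations;
* **noise calibration** — randomized-library scans over occurrence
  cutoffs 1/5/10/15/20 with an order-of-magnitude drop rule
  (`specificity_scan()`, `recommend_cutoff()`), and saturation curves of
  distinct mapped tags under read-level subsampling;
* **GO enrichment** — minimum-likelihood two-tailed hypergeometric test
  with ancestor propagation and Haldane-corrected log-odds;
* **3'-UTR proximity** — longest-ORF transcript orientation, exact
  genome placement, and signed-distance histograms of genome-only tags
  around annotated 3' ends;
* a fully seeded **synthetic-data generator** that emulates the
  three-fraction experiment (heavy-tailed expression, planted
  fold-changes, antisense tags, sequencing error, novel transcripts)
  with complete ground truth, so every stage is testable offline.

## Worked example

Simulate the default three-fraction study and run the core steps:

```r
library(tagdge)

cfg <- synthetic_config(seed = 101)
st  <- generate_transcriptome(cfg)
st
#> Synthetic DGE study: 150 transcripts ( 10 withheld ), 3 libraries
#>   depths: X1=1000000 X2=958000 Xin=321000
#>   planted DE: 24 transcripts; seed 101

lib_x1 <- simulate_dge_library(st, "X1")
lib_x1
#> Tag library 'X1': 1753 distinct tags, 1e+06 total reads

ix <- build_tag_index(reference_sequences(st), "transcriptome")
summarize_mapping(map_tags_exact(filter_by_cutoff(lib_x1, 5), ix))
#>   reference_set total mapped one_match multi_match orphan contigs_per_tag
#> 1 transcriptome   447    253       253           0    194               1
```

Of the 447 reliable tags (seen ≥ 5 times), 253 map to the reference;
the orphans are the simulated sequencing-error variants, antisense tags
of the poly(A)-padded kind the index deliberately omits, and tags of the
ten transcripts withheld from the reference — the same categories that
explain unmapped tags in real libraries.

```r
compare_libraries(c(nanos_like = 39.27), c(nanos_like = 0))
#>          tag cpm_a cpm_b pseudo_a pseudo_b  p_value log10_p direction
#> 1 nanos_like  39.3     0       39        0 1.82e-12   -11.7       a>b
```

A tag at 39.27 cpm in X1 and absent from Xin is significant at
p = 2⁻³⁹: the chance that all 39 of its rounded-cpm observations fell
into one library if both were equally likely.

```r
sc <- specificity_scan(lib_x1, ix, n_rand = 5, seed = 101)
as.data.frame(sc)[, 1:5]
#>   cutoff candidates observed_hits random_candidates_mean random_hits_mean
#> 1      1       1753           264                  1e+06                0
#> 2      5        447           253                  0e+00                0
#> 3     10        339           243                  0e+00                0
#> 4     15        321           234                  0e+00                0
#> 5     20        307           224                  0e+00                0
recommend_cutoff(sc)
#> [1] 5
```

Read-level randomized libraries pass a million distinct singletons at
cutoff 1 and essentially nothing at cutoff 5 — requiring five
occurrences removes the noise, and stricter cutoffs buy nothing more.

The whole workflow, including comparisons, candidate selection,
correlations, saturation, enrichment and the 3'-proximity profile, runs
in one call and writes schema-commented TSVs plus a YAML manifest:

```r
res <- run_dge_pipeline("myrun", synthetic = cfg, seed = 101)
dge_report("myrun")       # saturation + splashplot figures (PDF)
```

See the vignette (`vignettes/dge-tag-profiling.Rmd`) for the models,
parameter rationale and numerical conventions.

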
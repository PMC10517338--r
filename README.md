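# utrcensus

Curation and benchmarking of pathogenic variants in 5′ and 3′
untranslated regions (UTRs).

Variants in UTRs cause rare disease through regulatory mechanisms —
upstream open reading frames, polyadenylation signals, miRNA binding
sites, promoter elements, mRNA secondary structure — and classifying
them is dominated by two problems: the same genomic position can be
3′ UTR on one transcript and missense on another, and variant-effect
predictors are mechanism-specific, so evaluating them without
stratifying pathogenic variants by mechanism misrepresents what they
can do. `utrcensus` is for clinical-genomics and regulatory-genomics
analysts who need to (a) curate UTR variants reproducibly across
overlapping transcript annotations and (b) benchmark effect predictors
against mechanism-labelled truth sets.

## What it provides

* **Transcript-context scoring.** `locate_variant()` classifies a
  variant's span on each transcript (UTR-exonic, CDS-exonic,
  splice-proximal within 8 bp of an intron/exon boundary, intronic,
  spanning), and `confidence_score()` collapses the calls on all other
  transcripts into a 0/1/2 confidence that the effect is UTR-mediated:
  0 if any other transcript puts the variant in a CDS exon or a splice
  region, 1 if merely intronic or in the opposite UTR, 2 otherwise.
  `resolve_inclusion()` applies APPRIS-principal / MANE Select / MANE
  Plus Clinical conflict rules plus origin and variant-type exclusions.
* **Filters.** Significance classes (P/LP/conflicting), the strict
  > 5%-in-any-subpopulation discard rule, variant-type classification
  with the 50-base indel/SV boundary, and tandem-repeat penetrance
  bands (5–34 normal, 35–49 premutation, > 50 fully penetrant).
* **A curated census.** 94 P/LP UTR variants (26 3′, 68 5′) with
  transcript HGVS, ClinVar and study classifications and curated
  molecular mechanism, shipped as checksummed TSV fixtures, with
  summaries: `stratify_mechanism()`, `cross_tabulate()`,
  `unique_genes()`.
* **Benchmark assembly and effect aggregation.** Putative-benign
  selection from UTR exons at total AF > 1%, mechanism-matched group
  assignment per predictor archetype, and the three aggregation
  schemes: window/track CAGE-style aggregation
  `mean_tracks log2(1 + sum_windows)` over the centre ± 2 windows of a
  strand-averaged tensor; ensemble-mean differences for mRNA-stability
  predictors (plus the six-channel one-hot/frame/splice input builder);
  and log2 mean-ribosome-load fold change. PhyloP-style annotation
  takes the max score over multi-base reference spans.
* **Statistics.** Two-sided Mann-Whitney rank-sum tests (exact by
  enumeration for tie-free samples up to n1+n2 = 25, else
  tie/continuity-corrected normal approximation), rank-based ROC/AUC
  with the exact identity AUC = U/(n1·n2), Youden-J threshold
  selection, and the stratified report `evaluate_benchmark()`.
* **Synthetic data.** `simulate_annotation()` / `simulate_benchmark()`
  generate transcript models, variant/AF tables, effect scores and
  conservation tracks with controllable group structure, so the entire
  pipeline runs and is tested without any external downloads.

## Worked example

```r
library(utrcensus)

parse_hgvs_utr("NM_000518.4:c.*110_*114del")
#> <NM_000518.4 3' UTR deletion offsets 110..114>

cen3 <- load_census("utr3")
stratify_mechanism(cen3)
#>          mirna_binding         mrna_stability polyadenylation_signal
#>                      7                      3                     10
#>    secondary_structure          splicing_3utr           undetermined
#>                      1                      1                      4

cross_tabulate(cen3)[c("P", "LP"), 1:3]
#>            clinvar_class
#> study_class  P LP P_and_LP_conflicting
#>          P   6  0                    0
#>          LP 12  4                    4
```

The census splits 26 3′ UTR variants into six mechanism strata
(polyadenylation-signal impact is the largest, n = 10), and the
cross-tabulation shows the curation at work: all 6 study-pathogenic
variants were ClinVar-pathogenic, while the 20 likely-pathogenic calls
came from 12 pathogenic, 4 likely-pathogenic and 4 conflicting ClinVar
records. Benchmarking against a stability-type predictor groups those
26 into 13 model-matched (polyadenylation + stability mechanisms) and
13 mismatched. On synthetic data with the default effect structure:

```r
bm <- simulate_benchmark(simulation_config(seed = 42))
evaluate_benchmark(bm$dataset, bm$scores, use_abs = TRUE)
#> Benchmark report (absolute scores)
#>   groups: matched=30 mismatched=30 benign=30
#>   matched_vs_benign      U=838.0 p=1.01e-08 (normal_approx)
#>   matched_vs_mismatched  U=731.0 p=3.37e-05 (normal_approx)
#>   plp_vs_benign          U=1496.0 p=3.45e-07 (normal_approx)
#>   matched-vs-benign AUC=0.931 best_threshold=1.16
```

Model-matched variants separate from both benign variants and
mismatched P/LP variants; the AUC is the rank-based pair statistic for
the matched-vs-benign classification task and the threshold maximises
Youden's J. See `vignette("utr-variant-curation")` for the model,
conventions and limitations.

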
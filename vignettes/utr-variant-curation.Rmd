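---
title: "Curating and benchmarking pathogenic UTR variants"
author: "utrcensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and benchmarking pathogenic UTR variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrcensus)
```

## The problem

Variants in 5′ and 3′ untranslated regions (UTRs) cause rare disease
through regulatory mechanisms — upstream open reading frames (uORFs),
polyadenylation signals, miRNA binding sites, promoter elements, iron
response elements, mRNA secondary structure — rather than by changing a
protein sequence. Classifying them is harder than classifying coding
variants for two reasons this package addresses directly:

1. **Transcript context is ambiguous.** The same genomic position can be
   3′ UTR on one isoform and missense on another. Whether a ClinVar
   variant "is" a UTR variant depends on which transcript you ask.
2. **Effect predictors are mechanism-specific.** A ribosome-load
   predictor knows about uORFs, not about polyadenylation. Evaluating
   predictors without stratifying pathogenic variants by mechanism
   understates what the models actually know.

The package implements a curation pipeline (filters, transcript-context
confidence scoring, inclusion rules), ships a curated census of 94
pathogenic/likely-pathogenic (P/LP) UTR variants with mechanism labels,
and provides the benchmark-assembly, effect-aggregation and statistical
machinery to evaluate variant-effect predictors against it.

## Transcript-context model

A `transcript_model` holds strand-aware exon intervals and a CDS span;
UTR intervals are derived as exonic territory minus the CDS span, split
by side of the CDS respecting strand. All internal coordinates are
1-based inclusive (GFF convention); bedGraph input is converted at the
parser boundary. This single convention keeps HGVS, GTF and track
arithmetic consistent.

`locate_variant()` classifies a variant's full reference span on one
transcript: `utr5_exonic`, `utr3_exonic` or `cds_exonic` only when the
span lies entirely inside one interval of that region; `spanning` when it
crosses a region boundary; `intronic`, splitting off
`splice_proximal_intronic` when the span sits within 8 bases of an
intron/exon boundary. The 8-base window is the operational definition of
"splicing variant" here and is configurable, because annotation
releases and community practice drift. Exonic positions near a boundary
are *not* splice-proximal: the definition is strictly intronic.

Two cases the region grammar leaves open were decided as follows:

* **Insertions** (empty reference allele) are located by their two
  flanking bases: an insertion is UTR-exonic iff both flanks fall in the
  same UTR exonic interval. This is the strictest reading of "located
  entirely within" a region.
* **Spanning calls on other transcripts** (below) count as
  coding/splicing conflicts, because a span that crosses a region
  boundary necessarily touches non-UTR sequence. The conservative choice
  costs a confidence point in rare edge cases but never inflates
  confidence.

## The confidence score

`confidence_score()` summarises what a UTR variant hits on every other
overlapping transcript into an integer 0/1/2:

| other-transcript calls                        | score |
|-----------------------------------------------|-------|
| any CDS-exonic, splice-proximal, or spanning  | 0     |
| else any intronic or opposite-side UTR-exonic | 1     |
| else (same-side UTR, or no overlap)           | 2     |

Higher scores mean higher confidence that the effect is mediated by the
UTR of the preferred transcript. The score depends only on the multiset
of calls, so it is invariant to the order of the other transcripts, and
adding a transcript can only lower it (both properties are tested).
Non-coding transcript models are skipped: with no CDS there is no UTR,
and the pipeline requires coding transcripts throughout.

`resolve_inclusion()` applies the curation rules on top: a variant is
kept only when UTR-exonic on the designated APPRIS-principal transcript,
germline, not a repeat expansion or multi-region structural variant, and
free of conflicts on clinically preferred transcripts. A non-UTR impact
on a MANE Select or MANE Plus Clinical transcript of the gene excludes
the variant regardless of mechanistic evidence by default (the
conservative stance; `mane_override = TRUE` relaxes it), while a non-UTR
impact on an APPRIS *alternative* transcript excludes only when the
mechanistic evidence is absent or favours the non-UTR effect. "Non-UTR
impact" is operationalised as any overlapping call that is not
UTR-exonic; a transcript the variant does not overlap at all is not an
impact. Evidence context is an input column — the package does not mine
literature.

## Filters

* **Significance**: keep P, LP, and conflicting-P/LP records; the
  mapping from free-text significance strings to classes is data
  (`clinvar_significance_map()`), because the strings vary by release.
* **Allele frequency**: discard when any subpopulation frequency is
  strictly above 5% (strong benign evidence). Records without frequency
  data are kept — absence of observation is rarity. The putative-benign
  threshold used in benchmark assembly (strictly above 1%) is a separate
  configuration key on purpose: it is deliberately *more* inclusive, so
  that most UTRs contribute a matched benign variant.
* **Variant type**: SNV / indel (net length ≤ 50) / SV (> 50) / delins,
  computed on left-normalised alleles so the measure is canonical;
  CNV and repeat expansions come from symbolic descriptors. The default
  repeat bands (5–34 normal, 35–49 premutation, > 50 fully penetrant)
  deliberately leave a count of exactly 50 unclassified: the published
  band edges do not cover it, and the band table is configurable rather
  than silently patched.

## The census

`load_census()` returns the packaged census: 26 3′ UTR and 68 5′ UTR
P/LP variants, each with transcript HGVS, gene, ClinVar class, study
class and curated mechanism. The fixtures are versioned TSVs with
recorded checksums — they are data, not code — and every HGVS string
parses with `parse_hgvs_utr()`. Mechanism labels are normalised from the
prose section headers through an explicit mapping
(`normalize_mechanism()`). The `functional_evidence` column is nullable:
per-variant flags are not printed in the source tables, so no count is
asserted on them.

```{r census}
cen <- load_census("both")
stratify_mechanism(load_census("utr3"))
cross_tabulate(load_census("utr3"))
length(unique_genes(cen))
```

## Benchmarks and effect aggregation

`assemble_benign()` selects putative-benign variants: total allele
frequency strictly above 1%, full span inside a UTR *exon* of a
transcript carrying a P/LP census variant, deduplicated by
(chrom, pos, ref, alt) so overlapping transcripts cannot double-count
a variant in the rank tests. `assign_groups()` then labels each census
entry `plp_matched` or `plp_mismatched` for a given model
(undetermined mechanisms are mismatched) and attaches the benign group.

The default model map pairs predictor archetypes with mechanism sets:
ribosome-load models with uORF and novel-upstream-start mechanisms;
mRNA-stability models with polyadenylation and stability mechanisms
(that two-mechanism union is hard-coded verbatim as the default);
transcription-level models with promoter activity, promoter methylation
and 5′ UTR splicing. The inclusion of 5′ splicing under "operating at
the level of transcription" is an interpretation, so the map is a
configuration object, not a constant.

Three aggregation schemes turn predictor outputs into a single signed
effect per variant (`raw`), with `abs = |raw|` carried alongside:

* `transcription_effect()`: average forward/reverse strands, subset to
  the centre window ± 2 (five windows total) and the supplied track
  subset, per track compute $\log_2(1 + \sum_{\text{windows}})$, average
  over tracks; effect = alt − ref. The centre window index is metadata
  supplied by the model runner, never inferred; the track subset is a
  required explicit argument because the relevant subset depends on the
  predictor.
* `stability_effect()`: effect = mean over the prediction ensemble for
  alt minus the same for ref (the archetype uses 50 cross-validation
  models; any K ≥ 1 is accepted). `build_six_channel_track()` builds the
  per-nucleotide input (one-hot A/C/G/T, coding-frame indicator,
  splice-site indicator). The frame channel marks the *first base of
  each codon* — an indicator, not a frame index {0,1,2}; the choice is
  documented because the encoding is underdetermined.
* `orf_effect()`: mean-ribosome-load fold change. "Fold change" does not
  pin down a scale, so both are exposed; the default is
  $\log_2(\text{alt}/\text{ref})$, symmetric around zero so that the
  absolute value is meaningful.

All three are antisymmetric under ref/alt swap (raw negates, abs is
invariant), except the ratio scale of `orf_effect()`, which inverts.

`phylop_annotate()` attaches a conservation score: the track value at
the position for a single-base reference, the maximum over the
reference span for multi-base variants. Positions without coverage are
skipped; a fully uncovered span yields `NA` — absence is a value, not an
error, which maximises usable annotation when tracks are incomplete.

## Statistics

`rank_sum_test()` computes the Mann-Whitney U from midranks. With
tie-free samples and $n_1 + n_2 \le 25$ (the curated group sizes fit
comfortably) the two-sided p-value is exact: twice the smaller tail of
the exact null distribution, capped at 1 — the common exact-test
doubling convention. Otherwise a normal approximation with tie
correction and a 0.5 continuity correction toward the mean is used.
Tests verify the exact branch against full enumeration of labelings and
the approximation against the reference implementation in `stats`.

`roc_auc()` computes the AUC as the rank-based pair statistic
$(\#\{p > n\} + \tfrac12\#\{p = n\}) / (n_p n_n)$, which equals
$U/(n_1 n_2)$ exactly — the identity is tested to $10^{-12}$. The best
separating threshold maximises Youden's J ($TPR - FPR$) on the pooled
score grid under the rule score ≥ threshold ⇒ positive; "best
separation" does not name a criterion, so a single deterministic,
standard one was fixed and is recorded in the result. Ties resolve to
the lowest threshold.

`evaluate_benchmark()` reports the three stratified contrasts — matched
vs benign, matched vs mismatched, all P/LP vs benign — plus the
matched-vs-benign ROC, on absolute scores by default. The absolute-value
default reflects that regulatory pathogenicity is conferred through both
expression increase and decrease, so magnitude is the informative axis
when mechanisms of both signs are pooled. No multiple-testing correction
is applied across models: the contrasts are reported as unadjusted
pairwise tests.

## The synthetic generator

`simulate_annotation()` and `simulate_benchmark()` generate every input
the pipeline reads — transcript annotation (writable as GTF), variant
and allele-frequency tables, effect scores, conservation tracks — as
pure functions of a `simulation_config()` (the caller's RNG state is
saved and restored).

What it emulates, and the defaults:

* **Group structure**: matched effects at magnitude 3 with Rademacher
  (±1) signs plus unit-SD noise; benign effects are zero-centred unit
  noise; n = 30 per group. These are the calibration conditions under
  which the evaluation layer is required to recover the configured
  ordering. The mismatched magnitude is stated nowhere upstream; it is
  fixed once at half the matched effect (1.5), which places the
  mismatched group clearly between matched and benign — the
  mismatched-vs-benign median contrast then stands at roughly three
  standard errors at n = 30, so the configured median ordering is
  recovered in well over 95% of replicates, whereas a magnitude equal to
  the noise SD would sit near 1.5 standard errors and be unrecoverable
  at that rate.
* **Conservation**: P/LP positions score N(2, 1), benign N(0, 1).
* **Allele frequencies**: a long-tailed Beta(0.3, 8) with mass on both
  sides of the 1% and 5% thresholds, so both frequency filters are
  exercised.
* **Annotation**: plus-strand genes with 1–2 exons per UTR around a
  single CDS exon; `alt_overlap` engineers alternative transcripts that
  put a known call (CDS-exonic, splice-proximal, deep intronic,
  opposite-UTR) at the variant position, so every confidence-score
  outcome is reachable by construction.

What it does **not** emulate: sequence-level biology. No uORFs,
polyadenylation motifs, or miRNA seeds are simulated — the generator
controls score *distributions*, not the sequence features that produce
them. Passing tests therefore demonstrate that the pipeline's logic and
statistics are correct under the configured effect structure, not that
any particular predictor works on real genomes. External headline
numbers (ClinVar yield rates, real-model AUCs, the PhyloP 1.6
threshold) depend on database releases and pretrained weights and are
out of scope by design.

## Problem sizes and numerical choices

The shipped verification suite runs at desk scale: exact rank-sum
enumeration over all labelings for group sizes up to 6+6 (1,000 random
cases), nested-loop oracles for the aggregation schemes (1,000 random
tensors, tolerance $10^{-12}$), 500 seeded benchmark replicates at
n = 30/group for the recovery properties, and 10,000 null replicates at
n = 20/20 for the empirical type-I error (required to land in
[0.04, 0.06] at α = 0.05). `scripts/acceptance.R` recomputes the census
counts and these simulation metrics from scratch at 200 replicates.

Degenerate inputs are defined, not crashed: single-member groups get
exact tests; identical distributions give AUC 0.5 and J = 0 with the
lowest grid threshold; an all-tied pooled sample has zero variance and
p = 1; empty AF maps pass the frequency filter.

## Known limitations

* The HGVS parser covers the UTR grammar the pipeline needs
  (substitution, del, dup, ins, delins with `c.-N`/`c.*N` offsets);
  protein-level, inversion and complex rearrangements are out of scope,
  and intronic offsets are rejected by design.
* Confidence scoring requires the variant to be UTR-exonic on the
  preferred transcript; a variant that is splice-proximal on the
  preferred transcript itself is simply not eligible, mirroring the
  eligibility rule rather than extending it.
* The inclusion rules consume an evidence-context column; they do not
  attempt to grade the evidence itself (ACMG/AMP synthesis is human
  judgment and stays upstream).
* BigWig conservation tracks are not parsed natively; convert to
  bedGraph or construct a `conservation_track()` from any data.frame.
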
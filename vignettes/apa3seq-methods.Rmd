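---
title: "apa3seq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{apa3seq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apa3seq)
```

This vignette explains the models and procedures behind `apa3seq`, the
parameters that matter and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the design was genuinely open.

## The measurement model

A 3'-end-seq library (QuantSeq REV and similar) captures the 3'-terminal
fragment of polyadenylated transcripts, so the transcript-3'-most aligned
base of each read estimates a cleavage/polyadenylation position. Three
error processes separate raw termini from usable polyA sites:

1. **Internal priming.** The oligo-dT primer can anneal to genomically
   encoded A stretches, producing reads whose termini mark nothing. A
   read is removed when the transcript-sense genomic sequence immediately
   3' of its cleavage base begins with six or more consecutive `A`, or
   contains at least six `A` within its first 10 nt. The window starts at
   the first base *after* the cleavage base: the cleaved transcript ends
   at the cleavage base, so only downstream genomic sequence can have
   templated the primer. On the minus strand the genomic window is
   reverse-complemented before testing, and bases beyond a contig end
   count as non-A (logged once). With a 10-nt window the
   six-consecutive-A clause is implied by the 6-of-10 clause; both are
   implemented independently so either threshold can be changed.

2. **Cleavage heterogeneity.** True cleavage scatters over a few
   nucleotides, so termini are clustered single-linkage with a maximum
   intra-cluster gap (`max_gap`, default 25 nt — wide enough to absorb
   few-nt scatter, narrow enough to keep sites hundreds of nt apart
   separable) and a minimum cluster size (`min_reads`, default 3). The
   representative position is the modal terminus; ties break towards the
   transcript 3' end, where cleavage is conventionally reported. Both
   parameters are exposed because upstream tools in this space document
   only "default settings".

3. **Irreproducibility.** A site must be detected (count ≥
   `detection_min_reads`, default 1) in at least a fraction
   `min_replication` (default 0.75) of the replicates of its
   best-supported condition. Whether the rate should be computed per
   condition or across all samples is ambiguous in common usage; the
   default is per condition — a site genuinely induced by the knockdown
   should not be penalised for absence in control — and `scope =
   "overall"` selects the stricter alternative. With 3+3 replicates the
   0.75 cutoff means exactly "detected in 3/3 of some condition".

PAS detection scans the transcript-sense sequence for twelve canonical
hexamer variants whose start lies 10–40 nt upstream of the representative
position, keeping the hit closest to the 21-nt canonical offset. The
window and set reflect standard PAS biology; they matter only for
annotation, not for site calling.

## Differential usage and ΔPUI

Usage is compositional: per gene and sample, site counts are normalised
to fractions. Condition usage pools replicate counts before normalising
(this weights replicates by depth; per-replicate averaging is available
via the per-sample table). The gene-level effect size is the distal
site's condition usage change, ΔPUI = u_distal(kd) − u_distal(ctrl), so
positive values mean 3'UTR lengthening; because usage sums to one, the
proximal site of a two-site gene moves equally and oppositely.

Significance comes from a two-sided Fisher exact test on the
replicate-pooled 2×2 table (site vs rest-of-gene) × (control vs
knockdown), BH-adjusted across all tested sites. The test is implemented
directly as a vectorised hypergeometric tail sum (the conventional
"probabilities no larger than observed" definition, relative slack
1 + 1e-7) so that exhaustive sweeps over many tables are cheap;
`stats::fisher.test` serves as an independent cross-check in the unit
tests, and a binomial-coefficient enumeration is the oracle in the
acceptance checks. Degenerate tables (a zero margin) return p = 1 and
are flagged. Pooling sacrifices replicate-level dispersion; a
dispersion-aware per-replicate test is a documented extension point, and
the thresholding logic (|ΔPUI| > 0.10, adjusted p < 0.05, both strict)
is deliberately independent of the test used.

Genes need at least two called sites; genes with more report the two
sites with the largest absolute usage changes, ties broken by larger
pooled count and then by the 5'-most position so the selection is
deterministic under permutation of the input.

## Cryptic classification

A site is cryptic when control usage ≤ 0.05, knockdown usage ≥ 0.10 and
the increase is ≥ 0.10 — all boundaries inclusive, implemented with a
1e-12 tolerance so that fractions like 0.15 − 0.05 pass the inclusive
boundary despite floating-point representation. Region categories are
strand-aware and partition assigned sites: `downstream_of_annotated_end`
(3' of the gene's most distal annotated transcription end — the
union-of-transcripts end is used as the reproducible proxy for a curated
"annotated 3' end"), `premature` (5' of the stop codon's genomic
boundary: intron or CDS, truncating the transcript), and `utr_internal`
(the remainder; this third bucket is the package's exhaustiveness device
rather than a claim that such sites are biologically distinct). Genes
without CDS records cannot be called `premature` and are classified
against the annotated end only, with a warning.

Coupling with cryptic splicing takes junction calls as *input* (junction
discovery is out of scope): a premature event couples to a junction when
both lie in the same gene and the site falls within the junction's
intron, i.e. the coupling window is the remainder of the intron 3' of a
cryptic 3' splice site — the geometry of a cryptic exon followed by
premature polyadenylation in the same intron.

## Site strength

Strength is scored on a 205-nt transcript-sense window, 102 nt each side
of the cleavage base (the odd length makes "centered" unambiguous);
contig-edge windows are N-padded and flagged. The default scorer is a
transparent heuristic, not a trained model: a linear predictor over PAS
hexamer quality (best weight in the −40..−10 region), U + GU dinucleotide
content of the +5..+40 downstream element, and a penalty for A runs
longer than 5 nt, interpreted as the log odds of a logistic site
probability (natural log; 0 ⇔ p = 0.5). Its weights are fixed constants:
the scorer's role in the comparative analyses is ordinal (ranking sites),
and fitting them would only disguise that. Externally computed scores —
e.g. from a published neural scorer — can be injected as a
`site_id`/`score` table behind the same interface, which is the intended
route when calibrated strengths are needed.

Group comparisons use `stats::wilcox.test` (exact for small tie-free
samples, normal approximation with tie correction otherwise) with ECDF
tables for plotting, and `auroc()` computes separation from the rank-sum
identity.

## Targeted 3'UTR lengthening index

For one gene, the index is mean per-base coverage over the extension
segment (unique to the long isoform) divided by mean coverage over the
common segment. The mean, not the median, is used because sparse
extension coverage is informative rather than noise (the median of a
mostly-zero extension would discard the signal); the index is
scale-invariant and undefined (flagged) when the common segment has zero
coverage. Segment boundaries are user input — the package generalises
"read coverage across the 3'UTR" and does not claim particular
boundaries for any specific gene. Coverage comes from read records
(`coverage_track()`) or a bedGraph.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions used throughout the validation suite:

* 3 + 3 replicates, ~500 reads per gene per replicate (Poisson), as in a
  typical knockdown design at desk scale;
* gene classes lengthening 0.3 / shortening 0.2 / cryptic 0.2 / null 0.3;
* planted |Δusage| = 0.30 between the proximal-most and distal-most site
  of lengthening/shortening genes — comfortably above the 0.10 calling
  threshold, so direction-calling performance reflects the pipeline, not
  boundary luck;
* cryptic sites move from true usage 0.02 (control) to 0.25 (knockdown),
  alternating intronic (premature) and downstream-of-TES placement;
* cleavage jitter: discretised Gaussian, sd 2 nt — the few-nt
  heterogeneity scale at which sites hundreds of nt apart remain
  separable; the real libraries' heterogeneity is not claimed;
* internal priming: 10% of reads terminate immediately upstream of a
  planted 8-A sense-strand stretch in each gene's intron, ≥ 50 nt from
  any true site so filter evaluation is unambiguous;
* every true site gets a planted PAS hexamer 21 nt upstream and a
  controlled A-free 40-nt downstream block (U/GU-rich for the
  distal-most "strong" site of each gene, neutral for "weak" ones), so
  true-site reads cannot be lost to the mis-priming filter except by
  extreme jitter, and the strength scorer has planted labels to recover;
* accidental A runs ≥ 5 in the background sequence are broken outside
  planted intervals.

Genes sit in fixed-length slots (default 6000 nt), 25 per contig,
alternating strands; minus-strand genes are laid out in transcript-sense
coordinates and the slot is reverse-complemented wholesale, which makes
strand symmetry of the whole pipeline a structural property the tests
can check exactly. Truth (per-site usage, per-read origin, artifact
positions) is written to separate TSVs, never into the alignment files.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: sequencing error and base
quality, fragment-length and coverage biases, overlapping genes and
shared UTRs, multi-transcript annotation complexity, biological
replicate-to-replicate usage variability beyond multinomial sampling,
and genome-scale A-content composition. Results on synthetic data
validate the *logic* of the pipeline, not its field performance on any
particular library.

## Numerical choices and degenerate inputs

* Internal coordinates are 1-based closed (GRanges convention); BED is
  written 0-based half-open and GTF read 1-based inclusive.
* Modal-position ties break to the transcript 3' end; pair-selection
  ties break by pooled count then 5'-most position; both make outputs
  permutation-invariant.
* Zero-count gene-samples yield undefined (NaN) per-sample usage; genes
  with a zero condition total are excluded from testing.
* Expression fold change uses pseudocount 1 and flags |fc| ≥ 1.5.
* Seeds fully determine the simulation; the three generator stages use
  consecutive derived seeds so each stage is individually reproducible.

## Validation scales

The validation suite and `scripts/acceptance.R` run at sizes chosen so
the whole battery completes in well under a minute each on one CPU while
still being exhaustive where exhaustiveness is the point: the
mis-priming rule at all 200,000 positions of 50 random 2-kb sequences
(both strands); the exact test over all ~164,000 2×2 tables with margins
≤ 30 against direct enumeration (agreement to < 1e-12); the rank-sum
test for all group sizes up to 6 + 6 against permutation enumeration;
the replication filter over all 64 detection patterns of a 3+3 design;
and a 200-gene simulated study (~600,000 reads) for recovery metrics.

## Known limitations

* The exact test ignores replicate-level overdispersion (see above).
* The heuristic strength scorer is ordinal and uncalibrated by design.
* Gene models are single-isoform (union exons, one CDS, most-distal
  TES); real multi-isoform annotation can make "premature" vs
  "utr_internal" ambiguous for sites inside alternatively spliced
  regions.
* The simulator's artifact model (all internal priming at one planted
  stretch per gene) is deliberately simple; it measures filter
  correctness, not the field false-negative rate of the A-content rule.
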
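---
title: "Integrated inference of bacterial transcriptional regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated inference of bacterial transcriptional regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`trninfer` reconstructs a bacterial transcriptional regulatory network
(TRN): a directed graph of transcription factor (TF) to target-gene
interactions. Expression-only inference struggles with two well-known
failure modes — co-expressed but not co-regulated genes, and
post-transcriptionally regulated TFs whose mRNA says nothing about their
activity. The workflow implemented here therefore starts from *sequence*
evidence (phylogenetic footprinting across related genomes), refines it
with *expression* evidence (condition-specific biclusters), and assigns
regulators using four complementary properties of bacterial TFs, only one
of which depends on the TF's own expression profile.

The pipeline stages, each exposed as ordinary functions and orchestrated by
`infer_trn()`:

1. **Upstream intergenic regions (IGRs).** For every gene in every genome,
   the strand-aware upstream intergenic gap, kept when strictly longer than
   40 bp (`extract_upstream_igrs()`). A gap shared by a divergently
   transcribed pair is assigned to both genes. Coordinates are 1-based
   inclusive throughout.
2. **Footprinting groups.** Orthologous groups with at least one
   target-genome member and at least 4 IGR sequences
   (`assemble_footprinting_groups()`).
3. **De novo motif discovery** per group under a ZOOPS (zero-or-one
   occurrence per sequence) model against an order-3 Markov background
   trained on all IGRs (`discover_motifs_zoops()`), with up to 3 motifs per
   group at E-value 0.01.
4. **Genome-wide scanning** of each motif (`scan_for_hits()`): best hit per
   IGR per strand, log-odds against the order-0 stationary background, with
   an *exact* p-value from the dynamic-programming score distribution of a
   random word (`pssm_score_dist()`).
5. **Motif family clustering** (`cluster_motifs()`): single-linkage
   components over edges that satisfy both a 33% overlap of target-genome
   hit sets and a PSSM-similarity q-value below 0.01 (BH-adjusted
   column-shuffle p-values from `compare_pssms()`).
6. **Bicluster refinement** (`refine_coexpression()`): each motif family's
   target genes are refined against the row-standardized expression matrix
   into a gene subset and condition subset with significant co-expression
   (greedy alternating refinement; >= 3 genes, >= 30 conditions,
   permutation p <= 0.001).
7. **Four-criterion TF linking** (`score_tf_clusters()`): expression
   correlation, genomic proximity, DNA-binding-domain (DBD) motif
   similarity against a reference library, and phylogenetic correlation of
   motif and TF occurrence. Each criterion score is converted to an
   empirical p-value against 1000 permutation draws and combined as
   `R = -log10(p_corr * p_prox * p_dbd * p_pc)`; undefined criteria enter
   with p = 1. The rank-1 TF per cluster becomes its network regulator.
8. **Core network and operon extension** (`build_core_network()`,
   `operon_extend()`): edges from rank-1 TFs to bicluster members, extended
   transitively through predicted operons when the pairwise correlation
   over *all* conditions is at least 0.8.
9. **Expression-only consensus** (`clr_scores()`,
   `tree_importance_scores()`, `combine_rexp()`): a CLR-style
   mutual-information scorer and a random-forest importance scorer, each
   truncated to its top 50,000 edges and converted to empirical p-values
   against 10,000 scores from a within-row permuted matrix; combined as
   `R_exp = (1/3) * sum(-log10 p)` with missing approaches contributing 0
   (the divisor stays 3 even when fewer approaches are supplied, so a
   third, imported ranking — `import_ranked_list()` — can slot in).
10. **Merge** (`merge_networks()`): comparative-genomics predictions take
    precedence at TF granularity; consensus edges are kept only for TFs not
    already in the core, above a cutoff chosen by walking the ranked
    consensus in steps of 100 predictions and keeping the largest prefix
    with 95% gold-restricted precision (`threshold_by_precision()`;
    fallback cutoff 1.3 when no gold standard is supplied).

## Key tunable parameters

All defaults live in `infer_trn_control()`:

| parameter | default | meaning |
|---|---|---|
| `min_igr_len` | 40 bp | exclusive IGR length cutoff |
| `min_seqs` | 4 | IGR sequences per footprinting group |
| `bg_order` | 3 | Markov order of the discovery background |
| `evalue_max` | 0.01 | motif significance gate |
| `widths` | 10, 14 | discovery seed widths (trimmed cores >= 8) |
| `p_max_hits` | 1e-5 | exact scan p-value per retained hit |
| `min_overlap`, `q_max` | 0.33, 0.01 | motif clustering gates |
| `min_module`, `min_conditions`, `bicluster_p` | 3, 30, 0.001 | bicluster acceptance |
| `operon_max_gap`, `operon_r` | 50 bp, 0.8 | operon prediction and extension |
| `n_null` | 1000 | permutation draws per linking criterion |
| `n_perm_scores` | 10000 | score null draws per consensus approach |
| `precision_target` | 0.95 | consensus cutoff targeting |

At `p_max_hits = 1e-5` a genome of ~300 IGRs (~10^5 windows over both
strands) yields on the order of one chance hit per motif, which downstream
filters absorb (below). Motifs must carry roughly 17 bits to be scannable
at this threshold, which is why the pipeline searches at widths 10 and 14
and never trims below 8 columns; the generic `discover_motifs_zoops()`
default grid (8 and 12) suits standalone use on short planted motifs.

## Numerical and statistical choices

**Exact scan p-values.** The null score distribution of a width-w word is
computed by dynamic programming over score-rounded columns (granularity
1e-3) under the order-0 stationary background, even though discovery uses
the order-3 model — the exact distribution is only tractable for the
order-0 null. Zero-probability cells (pseudocount 0) are floored far below
the achievable range so the tail probabilities of feasible scores are
unaffected.

**Discovery significance is procedure-calibrated.** A motif found by
seeded, iterated site search is optimistically biased: sites were selected
*because* they agree. Closed-form combination of per-sequence hit tests
under-states this badly (we measured ~20% false motif calls on pure
background groups). The package instead (i) scores each contributing
sequence leave-one-out — the motif is rebuilt without that sequence's site
before re-scanning it; (ii) converts the best-hit score to a Gumbel tail
probability fitted to best hits on sequences sampled from the order-3
background (so repeat-like background structure is part of the null); and
(iii) standardizes the group statistic (sum of the three largest
per-sequence log evidences) against the same statistic produced by running
the *entire search* on background-model groups
(`discovery_calibration()`, shared across groups in a pipeline run).
Measured false-motif rate on background groups is ~2-5% at
`evalue_max = 0.01`, with ~50-80% per-group power on planted motifs at
the generator's mutation rates; because every regulon spans several
ortholog groups and scanning recovers members genome-wide, per-group power
well below 1 still yields near-complete regulon detection.

**Motif clustering identity.** Hits are identified by strand-agnostic site
centers matched within 5 bp: the same physical site is reported on either
strand depending on motif orientation, and registers jitter between motif
variants of different widths. A single shared site never counts as overlap
(chance co-hits would chain unrelated motifs through single coincidences).
The overlap coefficient divides by the smaller hit set, and the
PSSM-comparison q-values are BH-adjusted over the candidate pairs that pass
the overlap screen. The comparison statistic is the mean per-column Pearson
correlation over the best ungapped alignment, maximized over offsets and
orientations, with a minimum overlap of 6 columns: with near-one-hot
columns, 4-column overlaps reach a chance-perfect mean too easily under the
column-shuffle null.

**Bicluster refinement.** Starting from all conditions, the greedy
alternately (a) prunes the gene least correlated with the others when its
coherence falls below half the set's level and pruning improves the mean
pairwise |correlation|, and (b) removes the condition whose exclusion most
improves the score, restricted to conditions contributing at least half the
average per-condition variance — low-variance conditions carry weak but
genuine signal (small latent activity) and removing them is almost always a
chance-level "improvement" that would strip real support. Absolute
correlations are used throughout because repression anti-correlates;
rows are sign-aligned to the set centroid first. The permutation null
applies the *identical* refinement to equally sized random gene sets drawn
from a within-row permuted copy of the matrix: permutation removes genuine
co-regulation that contaminates random sets from the raw matrix, while
re-running the greedy keeps the null subject to the same selection
optimism. Condition subsets are arbitrary (not contiguous), and the
bicluster's shared condition subset stands in for per-gene condition
subsets in the correlation criterion.

**Permutation p-values** are `#{extreme}/n`, floored at `1/(n+1)` so that
a combined score never becomes infinite. Criteria that are undefined for a
pair — TF absent from the array, no cluster member on the TF's replicon, a
DBD family missing from the library, a presence vector without variance —
contribute p = 1 (neutral evidence). The null draws follow the stated
generation procedures: random TF against a random equally-sized gene set on
a random cluster's condition subset (correlation); random TF against a
random cluster (proximity, phylogenetic correlation); a single random
(cluster, library entry) comparison (DBD). With small TF universes the
floors of these empirical nulls limit how much any one criterion can
contribute (about `-log10(1/(n+1))`), which mostly matters when expression
carries no signal at all; the evaluation of the post-transcriptional
scenario below reflects that.

**Consensus nulls.** Built-in scorers are re-run on a within-row permuted
matrix (marginals preserved, TF-target dependence destroyed); imported
rankings take an explicit null score vector, by default sampled from the
empirical score distribution of random TF-target pairs.

**Evaluation.** The area under the precision-recall curve is integrated by
trapezoid over recall with a left anchor at (0, first precision).
Percentages in per-TF reports are rounded half-up to one decimal, a TF with
no predictions reports NA, a TF whose predictions are all wrong reports 0,
and the Average row is the mean over non-NA entries (zeros included) —
conventions verified against the bundled per-TF benchmark table
(`inst/extdata/ecoli_tf_benchmark.tsv`), whose six Average values are
reproduced exactly by `report_average()`.

## What the synthetic generator emulates

`simulate_trn_data()` produces a fully self-contained benchmark: related
genomes with shared gene order up to local shuffles, ortholog groups with
tunable loss, strong planted PSSMs (width 10-18) whose instances are
embedded in the upstream gaps of regulon members wherever the TF's ortholog
is present (point-mutated per genome), operon chains at small intergenic
gaps, TF genes placed adjacent to a regulon member half the time, a
reference motif library (noised planted PSSMs labelled with each TF's DBD
family plus 20 decoy families, emulating the scale of a curated library),
and an expression compendium in which regulon members track a latent TF
activity on an active condition subset. Post-transcriptionally regulated
TFs receive an expression profile unrelated to their activity — the case
the non-expression criteria exist to rescue.

The default scenario is 8 genomes, 300 ortholog groups, 12 TFs with
regulons of 5-15 genes, IGRs of 60-300 bp, mutation rate 0.05 per base per
genome, ortholog loss 0.1, 120 conditions, noise sd 0.4, 40% active
conditions, and a third of TFs post-transcriptional. The `easy` preset
(mutation 0.02, noise 0.2, all TFs transcriptional) is the reference
recovery benchmark; `post_transcriptional` makes every TF's expression
uninformative; `hard` raises mutation, noise, loss and the
post-transcriptional fraction.

What passing these benchmarks does *not* show about real data: the
generator plants one motif per TF with independent, near-one-hot columns
(no gapped or variable-spacer motifs — sigma-factor-like elements are out
of scope), expression noise is i.i.d. Gaussian with a single global
activity per TF (no combinatorial regulation, batch structure or
condition-specific artifacts), ortholog calls are error-free inputs, and
background IGRs are exactly the order-3 model the discovery background is
trained on. Real compendia violate all of these, and absolute
precision/recall on the synthetic presets should be read as upper bounds.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline on the
default-size scenarios (300 groups, 8 genomes, 12 TFs, 120 conditions),
which takes a few minutes each on one CPU; every stochastic step (sequence
simulation, discovery calibration, shuffle and permutation nulls, forests)
is driven by explicit seeds, so runs are reproducible end to end. With a
fixed seed the generator's FASTA output is byte-identical across runs.

## Known limitations

- Criterion p-values are empirical with 1000 draws; combined scores are
  capped near 12 and ties at the floor are broken by the DBD and
  correlation p-values, then TF id.
- With only a dozen candidate TFs, a spurious best-of-all-TFs correlation
  can reach the p-value floor; the integrated ranking then depends on the
  non-expression criteria whose own floors are set by the library and TF
  universe sizes. The rank-1 margin of the integrated linker over a
  correlation-only linker is therefore narrower here than it would be with
  hundreds of TFs.
- The ANOVA-style third consensus approach is import-only; the combiner
  keeps the fixed divisor of 3 regardless.
- Networks for the non-target genomes are not assembled (the per-genome
  PSSMs and hits are available in the fit object).
- Edge signs (activation/repression) are annotation from correlation signs,
  never used in scoring.
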
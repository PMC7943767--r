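---
title: "Detecting and dating whole-genome duplications from paralog divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating whole-genome duplications from paralog divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodup)
```

## The inference chain

Polyploidy events leave a characteristic footprint in a genome: a cohort of
paralog pairs that all diverged at the same moment. `paleodup` implements the
classic desk-scale chain used to find and date such events:

1. **Homology.** All-vs-all Smith–Waterman protein alignment (BLOSUM62,
   affine gaps open 11 / extend 1) feeds reciprocal-best-hit (RBH) calling:
   a pair is kept iff each gene is the other's unique top-scoring match.
   Reporting thresholds are score ≥ 50 and identity ≥ 0.3; score ties are
   broken by identity, then lexicographic id, deterministically.
2. **Divergence.** Each pair's proteins are globally aligned and
   back-translated onto their coding sequences; gapped, ambiguous and stop
   columns are dropped. Synonymous divergence is estimated with the
   Nei–Gojobori (1986) method: per-position synonymous site fractions
   (changes to stops count as nonsynonymous, so S + N = 3·codons exactly),
   pathway-averaged difference counts for multi-hit codons (stop-crossing
   pathways excluded), and a Jukes–Cantor correction
   ks = −3/4·log(1 − 4/3·pS), flagged saturated when pS ≥ 3/4. The 4dTv
   statistic — the transversion fraction at third positions of
   fourfold-degenerate codons whose first two bases match in both sequences —
   is a slower-saturating companion.
3. **Peaks and dating.** Gaussian mixtures (unequal variances, 1–4
   components, BIC model choice) are fitted to log-Ks (raw scale for 4dTv).
   The top-weight components are labelled α/β/γ by ascending mean — recent
   small-scale duplications, the WGD cohort, and older events. A Ks peak is
   dated with the molecular clock T = Ks/(2γ) with γ = 1.5×10⁻⁸ synonymous
   substitutions per site per year, the usual dicot rate.
4. **Collinearity.** Homolog pairs become anchors in gene-rank coordinates;
   per chromosome pair, dynamic programming repeatedly extracts the best
   strictly monotone chain (anchor count, then total gap, then a
   deterministic tie-break) with per-step gaps ≤ 25 ranks; chains shorter
   than 5 anchors are discarded. Restricting the divergence table to block
   anchors isolates the WGD cohort from tandem noise; block interval depth
   over a pre-WGD relative exposes the expected two-to-one mapping; pairs on
   the same chromosome within 10 gene positions are classified tandem.
5. **Clusters and enrichment.** Single-linkage components of the homolog
   graph form orthologous gene clusters (OGCs). Clusters are labelled by
   species-group composition (specific to a group: ≥ 2 of its species and
   none of the other; shared: ≥ 1 of each). For each term, enrichment of the
   foreground cluster set against a background set is a one-sided exact
   binomial tail P(X ≥ k_fg | n_fg, p_bg) with p_bg the background frequency,
   Benjamini–Hochberg adjusted; a term's repeated occurrences within one
   cluster count once.

## What the simulator emulates

`simulate_genomes()` evolves an ancestral set of random sense codons along a
species ladder. Substitution is K80 at the nucleotide level with
transition/transversion ratio κ (default 2) and rejection of proposals that
would create stop codons; per branch, the proposal intensity per site equals
the branch's nominal synonymous distance, so neutrally evolving fourfold
sites realise exactly the configured divergence. WGD duplicates every gene
onto a mirrored chromosome set (each copy kept with the retention
probability), recent tandem copies are inserted adjacent to their parents,
and inversions/translocations fragment collinearity. GO terms are drawn per
ancestral family from a power-law vocabulary (exponent 1.5), with planted
terms oversampled in families destined for a target species group. Every
duplicate and ortholog pair carries its origin and true synonymous
divergence; the planted anchor map and term set back precision/recall
scoring via `truth_report()`.

Defaults mirror a Cactaceae-like study design: one WGD at 25.7 MYA under the
dicot clock (Ks depth ≈ 0.77), tandem duplications at rate 0.1 per gene with
depth 0.05, 500 genes × 300 codons on 4 chromosomes, 2 inversions and 1
translocation.

What the simulator does **not** emulate — and hence what green tests do not
certify about real data: purifying selection (proteins here drift neutrally,
so homologs at a given Ks are far more diverged in amino acids than real
genes, making homology search *harder* than in practice), indels, gene
conversion, isoforms, codon-usage bias, base-composition heterogeneity, and
assembly artifacts.

## Numerical behaviour worth knowing

* **NG86 overestimates deep Ks under transition bias.** With κ = 2,
  synonymous changes at twofold-degenerate sites occur faster than NG86's
  equal-weight site counting assumes, and the Jukes–Cantor correction
  under-corrects K80 multiple hits. Measured on the simulator: a planted
  cohort at Ks 0.5 peaks near 0.53–0.56 (dates ≈ +11%), and at Ks 0.77 near
  0.86–0.90 (≈ +17%). This is a known property of the estimator, shared by
  real analyses that date WGDs with NG86-style Ks; the dating identity
  itself, T = Ks/2γ, is exact and linear.
* **Saturation.** Ks is undefined at pS ≥ 3/4 (flagged, excluded from
  fitting); fitted Ks values are capped at 5. Raw 4dTv is capped at 0.5 for
  peak fitting — its K80 asymptote — because spurious best-hit partners (for
  genes whose true partner was lost) scatter beyond it on few sites.
* **Identity floor.** With the default identity ≥ 0.3 filter, neutral
  homologs at pair Ks ≳ 0.8 start falling below the reporting threshold, so
  recall of very old duplicate pairs declines — visible in the acceptance
  report's `rbh_pair_recall` under the deep default conditions and the
  reason real studies see small, noisy γ peaks.
* **Exhaustive vs seeded search.** Up to 10⁶ pairs, hits are computed
  exhaustively with a compiled score-only Gotoh kernel (cross-checked
  against `Biostrings::pairwiseAlignment` in the tests). Beyond that, a
  shared-4-mer prefilter (≥ 5 shared words, plus each gene's top 3 partners
  by word count) bounds the work; like any word-seeded search it can miss
  pairs below ~40% identity.
* **Determinism.** Every stochastic step is seeded: the simulator from
  `sim_config(seed=)`, mixture initialisation from `detect_peaks(seed=)`
  (default 1729). RBH ties and chain ties break deterministically; two
  pipeline runs with one configuration produce byte-identical TSVs, which
  the manifest digests verify.

## Design choices that were genuinely open

* **Ks estimator.** NG86 + Jukes–Cantor was chosen over ML codon models
  because it is closed-form and hand-checkable against worked oracles; the
  model name is recorded in output metadata.
* **4dTv site definition.** A site counts only when both codons are in a
  fourfold family *and* their first two bases agree; raw (uncorrected) 4dTv
  is the default, with a K80-style transversion-distance correction
  (−½·log(1−2q)) behind a flag, since published 4dTv values are often
  ambiguous about correction.
* **Clustering.** Connected components (single linkage) rather than MCL:
  deterministic, testable against a union–find oracle, and externally
  produced cluster tables are accepted wherever fidelity to a specific tool
  matters.
* **Enrichment denominators.** `n_fg`/`n_bg` count annotated clusters only
  (an unannotatable cluster can never contribute a term and would dilute
  both frequencies); the alternative is a flag. Background zeros get add-one
  smoothing; terms in < 3 foreground clusters are skipped.
* **Tandem anchors.** Same-chromosome pairs within the 10-gene tandem window
  are excluded from intragenome anchors: tandem arrays otherwise chain into
  spurious near-diagonal "blocks", polluting the block-restricted
  divergence distribution.
* **Two-to-one depth.** Depth is counted by block rank-interval coverage (as
  the dot-plot reading of a duplicated region suggests). Blocks that chain
  across rearrangement boundaries inflate depth beyond 2 near the breaks,
  so the depth diagnostic is cleanest on comparisons where rearrangement is
  modest.

## Problem sizes used by the test suite

The suite validates every operation against independent oracles (hand
derivations, exhaustive enumerations, union–find, brute-force chain search)
and then runs the chain end-to-end on planted simulations: WGD recovery and
dating at 500 genes × 300 codons; tandem/WGD mode separation at 400 genes ×
200 codons; two-to-one depth at 300 genes × 200 codons across a 20-MY split;
enrichment error control over 50 annotation-level replicates of 250 + 750
clusters. These sizes give stable statistics (hundreds of pairs per mode)
while keeping a full run in minutes on one core.

## Limitations

Beyond the simulator's idealisations listed above: no E-value model for
hits (raw scores with fixed thresholds); no MCL or tree-aware orthology; no
GO-DAG term propagation; mixtures limited to four components, so more than
three superimposed duplication cohorts will be merged; and dating inherits
both the clock-rate assumption and the NG86 bias discussed earlier.
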
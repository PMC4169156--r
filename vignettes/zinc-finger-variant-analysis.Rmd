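---
title: "Methods: variant analysis of C2H2 zinc finger arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant analysis of C2H2 zinc finger arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfvar)
library(dplyr)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters, what the synthetic cohorts do and do
not emulate, and the design decisions taken where more than one
reasonable choice existed.

## The question

A C2H2 zinc finger contacts DNA through recognition-helix positions −1,
2, 3 and 6; positions C2 (β-turn), −2, 1 and 5 are similarly variable
across fingers but face away from the DNA. If missense variants at
contacting positions retarget transcription factors, selection should
leave detectable traces: depletion of *common* variants at contacting
positions, Hardy–Weinberg deviation of affected SNPs within populations,
and predicted binding-specificity shifts concentrated among rare
alleles. The pipeline measures all three on any proteome + variant +
genotype input set, and ships generators that plant each signal at a
known strength so the measurements themselves can be validated.

## Finger detection and the helix position map

Fingers are found with a pattern matcher for
`C-x(2,4)-C-x(11,14)-H-x(3,5)-H`. A profile HMM (Pfam PF00096) would
also work, but no downstream statistic uses HMM scores — only
coordinates and the conserved-residue anchors — so a transparent,
configurable pattern is preferred. Matching is left-to-right greedy and
non-overlapping; at a given start the shortest total span wins, with
ties broken toward the smallest gaps in order. This is deterministic and
matches the tandem-repeat structure of natural arrays. An exhaustive
enumeration oracle in the test suite confirms the scanner equals
"all placements + the same greedy rule" on random sequences.

The helix map anchors to the first conserved histidine: position 1 of
the recognition helix is `his1 − 6`, so −2…6 sit at offsets −8…−1
(position 4 is untracked and deliberately classed *unknown*). Anchoring
at His rather than at the second Cys keeps the map well defined when the
Cys-loop length varies. C2 is taken as the residue two after the first
cysteine, in the β-turn. The canonical Zif268 finger-2 helix RSDELTR
reproduces under this arithmetic, which is frozen in a test.

**Linkers.** "TGEKP-like" is operationalised as ≥ 3/5 identity to TGEKP
over the best 5-residue alignment, with linker length 4–8 (both
configurable). This admits the common natural variants (TGQKP, TGERP,
SGEKP) while excluding unrelated spacers. Arrays are maximal runs of
fingers in which *every* adjacent linker passes; runs of ≥ 3 are
reported. Requiring all linkers (rather than any) is the stricter
reading and is configurable.

## Variant classification

Coding effect uses the standard genetic code: equal amino acids →
silent; a stop gained or lost → other; otherwise missense. Analysis
retains missense variants at tracked positions only, and itemises counts
dropped by each rule so margins are conserved. "Common" means MAF ≥ 1%;
the threshold is inclusive (the ≥ form is the operational definition
used for the headline comparison) and configurable. Variants are
de-duplicated by (protein, residue, alternate amino acid).

Deleteriousness predictions are inputs, not re-implementations: SIFT
< 0.05, PolyPhen2-HDIV > 0.95, MutationTaster > 0.90, FATHMM < −1.5,
all strict inequalities, with a missing score never flagging its method
(matching the sparsity behaviour of aggregated annotation databases).

## Hardy–Weinberg deviation

Per (SNP, population) genotype tallies come from a biallelic GT-only
VCF plus a sample→population panel; missing genotypes are excluded from
tests but counted. Two tests are run:

- **Chi-square**: expected counts `n(p̂², 2p̂q̂, q̂²)` from the sample
  allele frequency, 1 df, no continuity correction (configurable choice;
  none is the default because the exact test is the primary inference).
- **Conditional exact test**: conditioning on the observed allele
  counts, every heterozygote count of matching parity is enumerated;
  probabilities follow the standard hypergeometric-type null, computed
  by a ratio recurrence anchored at the distribution's mode for
  numerical stability. The two-sided p-value sums outcomes with
  probability ≤ observed (ties included, 1e−7 relative tie tolerance —
  the convention of standard exact-HWE implementations).

The skip rule — no test when any genotype category has < 5 counts — is
applied before *both* tests by default (configurable to chi-square
only). The heterozygote-excess statistic `D = (het_obs − 2p̂q̂n)/2` is
always reported: positive D means heterozygote advantage, negative D
homozygote-favouring selection. Monomorphic SNPs get p = 1 and D = 0,
flagged rather than erroring. No multiple-testing correction is applied
by default (per-population raw p < α is the reported deviation
criterion); a Bonferroni option exists but is off.

A caution the test suite encodes: the exact and chi-square two-sided
p-values agree to ~0.02 only at very large samples (n ≈ 20,000); at
n = 500 the two conventions can differ by ~0.09 even with all categories
well filled. This is a property of the statistics, not an
implementation issue — the exact test matches a direct log-gamma
enumeration to 1e−12 for every configuration with n ≤ 50.

## Binding-specificity change

The summed Kullback–Leibler distance between the reference (R) and
variant (S) PFMs of the affected finger is
`Σ R ln(R/S) + Σ S ln(S/R)` over all cells, natural log, columns
compared in given order (no offset search — the matrices are
same-finger predictions of equal width). Observed PFMs contain zeros,
where the formula is undefined; a global pseudocount (default 1e−6) is
added to every cell and columns renormalised before the divergence. For
zero-free matrices, results at pseudocounts 1e−6 and 1e−9 differ by
< 1e−4, so the choice is immaterial away from the boundary. Pairs with
a missing PFM yield NA, mirroring predictor failures on real fingers.
Summed KL > 2.5 (strict) marks a dramatic specificity shift.

## Enrichment tests

The class-by-frequency and class-by-deviation comparisons use a
two-sided Fisher exact test as primary (robust for small cells) with the
Pearson chi-square reported alongside, since either test is defensible
for these tables. The odds ratio is
(contacting-common × non-contacting-rare) /
(contacting-rare × non-contacting-common), so depletion of common
variants at contacting positions gives OR < 1. Degenerate tables (an
empty margin) report p = 1 with a flag. The Fisher p-value is checked
in tests against fixed-margin hypergeometric enumeration — exhaustively
for all tables with total ≤ 12 and on thousands of random tables with
totals up to 200.

## What the simulator emulates — and what it does not

The generators are first-class, tested code; their defaults define the
study conditions used throughout the tests.

- **Proteome** (`gen_proteome`): 200 proteins, of which 60 carry a
  planted array of 4 canonical fingers joined by exact TGEKP linkers;
  non-structural residues are drawn from the 18 non-Cys/His amino acids
  so the planted coordinates are the unique pattern match, making exact
  recall a well-defined target. Decoys are residue-shuffled copies of
  planted sequences — same length and composition — which guards the
  scanner against composition-driven false positives.
- **Genotypes** (`gen_genotypes`): independent draws with
  `P(het) = 2pq(1−f)`, `P(hom) = p² + pqf` / `q² + pqf`. The inbreeding
  coefficient f is the deviation mechanism because it directly controls
  the sign of D (f > 0 → heterozygote deficit → D < 0), giving the
  qualitative analogue of homozygote-favouring selection. Defaults: 4
  populations × 100 individuals, f = 0.
- **Variant table** (`gen_variant_table`): 300 variants split
  35/35/10/10/10% into contacting / non-contacting / untracked
  (helix position 4, truth class unknown) / silent / other. MAFs mix
  rare Uniform(0.001, 0.01) and common Uniform(0.01, 0.5) draws 50/50,
  so the 1% threshold partitions non-trivially. A `common_or` argument
  plants a known common-variant depletion odds ratio for power studies.
- **PFM pairs** (`gen_pfm_pair`): Dirichlet reference columns; variant
  columns mix the reference with an independent random column at weight
  = divergence. Zero divergence gives identical matrices; mean summed
  KL increases monotonically in the weight.
- **Scores** (`gen_scores`): per-method Bernoulli deleterious calls at
  25% by default, scores drawn strictly on the corresponding side of
  each threshold, ~5% of benign cells set NA.

Each generator is a pure function of the configuration including its
seed; the written cohort (FASTA, VCF v4.2 with GT only, panel TSV,
variant/score/PFM TSVs, ground-truth JSON) is byte-identical across
runs, with populations encoded only in the panel, mirroring the
1000 Genomes layout.

Deliberately **not** simulated: linkage disequilibrium, admixture,
shared mutation processes (every SNP is independent), isoform structure,
splice/UTR annotation, and any expression (eQTL) data. Passing tests on
these cohorts therefore demonstrate correctness of the statistics and
plumbing under the stated generative model — not robustness to the
correlation structure of real cohorts.

## Problem sizes and runtime choices

The validation suite works at desk scale, chosen to keep each property
sharply testable: exhaustive exact-test verification for every genotype
configuration with n ≤ 50; type-I calibration over 1000 SNPs of 500
individuals; sign-recovery over 200 SNPs at f = 0.3 (≥ 90% rejections,
all with D < 0); depletion recovery over 100 cohorts of 1000 variants
at true OR 0.3; Fisher-oracle equivalence exhaustive to table total 12
and sampled to 200. The full pipeline default (200 proteins, 300
variants, 400 individuals) runs in seconds.

## Known limitations

- The scanner does not detect degenerate fingers lacking a canonical
  C2H2 signature, and reports no scores/E-values.
- Position "C2" has no universally fixed definition; the β-turn
  placement (first Cys + 2) is this package's choice.
- The exact test's p-values are discrete; comparisons against the
  chi-square p should respect the slow asymptotic agreement noted above.
- MAF computed from a cohort VCF uses genotyped individuals only; the
  simulator's variant-table MAF is the *nominal* generating frequency,
  so realised cohort frequencies differ by sampling noise.
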
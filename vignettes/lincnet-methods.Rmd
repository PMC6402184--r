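---
title: "Methods: statistics and sequence models behind lincnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics and sequence models behind lincnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincnet)
```

lincnet turns lncRNA, miRNA and mRNA count matrices plus transcript
sequences into an integrated ceRNA (competing endogenous RNA) analysis:
differential expression, novel-lncRNA filtering, a coexpression network,
cis/trans target prediction, consensus-voted miRNA binding, triad
assembly, and gene-set enrichment.  This vignette explains what each
stage computes, why the parameters are set where they are, which
numerical choices matter, and where the methods stop being trustworthy.

## 1. Differential expression: the Audic–Claverie count test

Sequencing studies with pooled libraries (all case samples merged into
one library, all controls into another) have no biological replication,
so variance-based tests do not apply.  The Audic–Claverie test asks: if
a feature produced `x` reads in a library of `N1` total reads, how
surprising is `y` reads in a library of `N2`?  Under independent Poisson
sampling with a flat prior on the rate, the conditional distribution of
`y` given `x` is negative binomial with size `x + 1` and probability
`N1 / (N1 + N2)`.  The two-sided p-value doubles the smaller tail
(capped at 1), with the observed count included in both tails:

```{r ac}
ac_pvalue(5, 5, 1e6, 1e6)       # identical counts: p = 1
ac_pvalue(0, 10, 1e6, 1e6)      # geometric tail: 2 * 2^-10
ac_pvalue(100, 220, 1e6, 1e6)   # a realistic 2.2-fold shift
```

Two numerical choices matter:

* **Tails are summed in log space** (log-pmf plus log-sum-exp), and the
  upper tail is truncated only far past the mode of the conditional
  distribution.  The naive `1 - sum(pmf)` form loses all precision once
  the tail drops to ~1e-15; the unit tests compare against
  `pnbinom(..., lower.tail = FALSE)` instead for the same reason.
* **The test is not exactly symmetric** under swapping
  `(x, N1) <-> (y, N2)`.  It cannot be: both tails include the observed
  point, and the identity `I_z(a, b) = 1 - I_(1-z)(b, a)` for the
  regularized incomplete beta function shows the two conditioning
  directions differ by exactly the observed point mass.  The difference
  is bounded by twice the larger of the two point masses — negligible
  for the large counts the test is meant for, visible for counts below
  ~20.  The test suite asserts the bound, not exact symmetry; the
  direction of every call does flip exactly under a label swap.

Fold changes are computed on RPKM with a pseudocount of 0.1 on both
sides, and p-values are Benjamini–Hochberg adjusted *within each feature
class* (lncRNA, miRNA, mRNA), because the three panels are separate
screens with separate thresholds: `q < 0.001` with `|log2fc| >= 1` for
lncRNA and mRNA, `q < 0.05` for the much smaller miRNA panel.

Calibration is checked, not assumed: under a null Poisson simulation
(5000 features, no planted effects) the fraction of features with
`p < 0.05` comes out at ~0.052, inside the accepted 0.03–0.07 band.

## 2. The novel-lncRNA filter cascade

Candidate transcripts pass five ordered gates: (1) length >= 200 nt,
(2) longest ORF < 300 nt, (3) hexamer coding-potential score < -1,
(4) no same-strand overlap with a known transcript, and (5) no protein
domain pattern in any reading frame.  Gates are evaluated in order and
failures are attributed to the first failing step, so a verdict table is
also an explanation.  The coding-potential score is a log-likelihood
ratio of in-frame hexamer usage under coding vs noncoding models; the
bundled toy model is trained on synthetic coding/noncoding sequences and
separates its two classes with margin at the -1 threshold.  The ORF
scanner is tested against a brute-force scan of every AUG and first
in-frame stop.

## 3. Coexpression network

Expression is `log2(RPKM + 0.1)`; edges are Pearson correlations with
`|r| >= 0.85` between lincRNAs and mRNAs.  The 0.85 threshold is a
*screen*, not an inference: at the simulated design (30 samples per
group, 60 total) the Fisher z standard error is about
`1 / sqrt(60 - 3) = 0.13`, so a planted latent correlation of 0.95
stays above the threshold with high probability while null pairs
(|r| typically < 0.4 at n = 60) essentially never cross it.  The
simulation confirms the arithmetic: the planted 20-member module is
recovered completely with a 0% background edge rate.

One generator subtlety is worth recording because it looks like an
analysis bug when first encountered: if library sizes are taken as the
column sums of a *small* simulated panel, any planted module dominates
the total and RPKM normalization couples every feature to the module
(a compositional artifact that cannot occur at transcriptome scale,
where one module is a negligible fraction of the library).  The
simulator therefore supports a fixed nominal library size (1e6) for
coexpression experiments.

## 4. Cis and trans targets

Cis targets are protein-coding genes whose annotated span comes within
10 kb of the lincRNA locus — an interval-overlap query with the window
added on both sides, tested against an all-pairs distance oracle.
Trans targets are called by complementarity: a Smith–Waterman-style
local alignment of the lincRNA against the reversed mRNA (so aligned
positions are antiparallel), scoring GC +3, AU +2, GU +1, mismatch -4,
gap -6, with a minimum score of 60.  At these values a score of 60
needs ~20 contiguous well-paired bases, which random 1-kb sequence
pairs essentially never reach.

## 5. miRNA binding and ceRNA triads

Binding edges are consensus votes over three independent predictors:

1. **Seed class** — canonical site types on miRNA positions 2–8
   (8mer, 7mer-m8, 7mer-A1, 6mer), Watson–Crick only (G:U wobble does
   not count).  The classifier is verified against a rule-based oracle
   on all 65,536 possible 8-nt windows.
2. **Duplex energy** — a nearest-neighbor dynamic program over the
   site region (stacking table for helix steps, +1.0 per G:U pair,
   +3.0 per internal loop, +3.5 per bulge, free ends), thresholded at
   -14 kcal/mol.  Verified against a quartic predecessor-pair DP and
   invariant under reverse-complementing both strands.
3. **AU context** — the A/U fraction of 30-nt flanks, >= 0.5.

lncRNA–miRNA edges need 2 of 3 votes, miRNA–mRNA edges all 3.  Triads
combine one DE lncRNA, one DE miRNA and one DE mRNA connected by
consensus edges; the *strict* mode additionally requires the ceRNA sign
pattern (lncRNA and mRNA move together, opposite to the miRNA).

```{r triads}
de <- data.frame(feature_id = c("lncA", "mirX", "m1", "m2", "m3"),
                 direction = c("up", "down", "up", "up", "down"))
lnc_e <- data.frame(mirna = "mirX", transcript = "lncA", consensus = TRUE)
mrna_e <- data.frame(mirna = "mirX", transcript = c("m1", "m2", "m3"),
                     consensus = TRUE)
assemble_triads(de, lnc_e, mrna_e, mode = "strict")[, 1:3]
```

The ceRNA simulator plants 8mer sites (with supplementary pairing and
AU flanks so all three predictors vote) and can additionally
*guarantee* that no unplanted site exists anywhere in the panel
(`exclude_chance_sites`): background positions that happen to spell a
seed match are resampled, flank bases are A↔U swapped (which breaks a
Watson–Crick match without changing the flank's AU content), and a draw
in which a chance site is welded inside a planted construct is rejected
and redrawn.  That makes the truth manifest exhaustive — with 5 planted
sites in a panel of 3 lncRNAs x 3 miRNAs x 4 mRNAs, the expected number
of chance 7mer+ sites is small but not negligible (a binomial
calculation gives roughly 0.4 per panel), so without exclusion a false
triad would appear in a sizeable fraction of seeds.

## 6. Enrichment and validation statistics

Over-representation uses the hypergeometric upper tail
`P(X >= k)` for `k` of `n` query genes landing in a `K`-member set
within an `N`-gene universe, BH-adjusted across sets and screened at
`p < 0.05`; it is tested against full subset enumeration for all
universes up to `N = 12`.  The validation helpers are the standard
qPCR and clinical statistics: `2^-ddCt` fold changes against the
control-group mean, Spearman correlation (rank-then-Pearson, so ties
are handled by midranks), and a Welch two-group test (optionally
pooled-variance).

## 7. Determinism and provenance

Every simulation consumes an isolated, offset-derived RNG stream and
restores the caller's `.Random.seed`, so fixtures are reproducible
regardless of what ran before them.  The pipeline writes a YAML run
manifest carrying a hash of the scientific configuration (the output
directory is deliberately excluded) and no timestamps; two runs of the
same configuration are byte-identical, file for file.

## Limitations

* The Audic–Claverie test models *technical* (Poisson) variation only.
  Pooling destroys biological replication; with dispersed counts the
  test is anticonservative, and its q-values should be read as a
  screen, not as error control over biology.
* Pearson correlation at `|r| >= 0.85` finds strong linear comovement;
  it says nothing about causation, and the threshold is far too strict
  to enumerate weaker regulatory relationships.
* The trans-pairing and duplex-energy scores are simplified models
  (no folding of either molecule, a reduced nearest-neighbor table,
  flat loop/bulge penalties); they rank candidates, they do not
  predict physical free energies.
* The coding-potential model bundled here is a toy trained on
  synthetic sequences; real use requires retraining on a genuine
  coding/noncoding corpus.
* All end-to-end guarantees (sensitivity, FDR, exhaustive site
  manifests) are statements about the *synthetic* generator with
  planted truth; on real data the same code runs, but the guarantees
  become assumptions to be checked.
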
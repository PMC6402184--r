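# lincnet

Integrated lncRNA–miRNA–mRNA expression and ceRNA network analysis.

lincnet takes count matrices and transcript sequences for the three RNA
classes and produces, stage by stage:

1. **Differential expression** — the Audic–Claverie exact count test on
   pooled per-group libraries, RPKM fold changes with a pseudocount, and
   Benjamini–Hochberg q-values per feature class (screens: |log2fc| ≥ 1
   with q < 0.001 for lncRNA/mRNA, q < 0.05 for miRNA).
2. **Novel lncRNA candidates** — a five-step filter cascade (length
   ≥ 200 nt, ORF < 300 nt, hexamer coding-potential score < −1, no
   known-transcript overlap, no domain pattern), with every rejection
   attributed to its step.
3. **Coexpression network** — lincRNA–mRNA Pearson correlation on
   log2 RPKM, edges at |r| ≥ 0.85.
4. **Targets** — cis (gene within 10 kb of the lincRNA locus) and trans
   (antiparallel base-pairing score ≥ 60).
5. **ceRNA triads** — miRNA binding by consensus vote over seed class,
   nearest-neighbor duplex energy and AU flank context (2-of-3 votes for
   lncRNA–miRNA, 3-of-3 for miRNA–mRNA), assembled into
   direction-consistent lncRNA–miRNA–mRNA triads.
6. **Enrichment** — hypergeometric over-representation against GMT gene
   sets.
7. **Validation statistics** — 2^−ΔΔCt qPCR fold changes, Spearman
   correlation, Welch tests.

Because real input data of this kind is rarely shareable, the package
ships a synthetic-data generator that plants every effect it later looks
for (DE features, coexpression modules, cis pairs, 8mer binding sites,
triads) and records them in a truth manifest, so the whole pipeline is
testable end to end.  See `vignette("lincnet-methods")` for the
statistics, the parameter rationale, and the limitations.

## Worked example

The bundled demo runs every stage on synthetic data with planted truth:

```r
library(lincnet)
res <- run_pipeline(pipeline_config(seed = 7, out_dir = "demo"))

res$de_recovery
#> $sensitivity
#> [1] 1
#>
#> $fdr
#> [1] 0
#>
#> $n_called
#> [1] 33
#>
#> $n_true
#> [1] 33

head(res$de[, c("feature_id", "class", "log2fc", "p", "q", "direction")], 4)
#>     feature_id class   log2fc             p             q direction
#> 220  mrna_0090  mRNA 1.944759 1.230229e-197 2.460458e-195        up
#> 170  mrna_0040  mRNA 1.932527 3.518174e-189 3.518174e-187        up
#> 262  mrna_0132  mRNA 1.850976 1.965756e-182 1.310504e-180        up
#> 156  mrna_0026  mRNA 1.815600 1.393638e-180 6.968192e-179        up

res$triads
#>     lncrna    mirna      mrna lnc_dir mir_dir mrna_dir
#> 1 lnc_0001 mir_0001 mrna_0001      up    down       up
#> 2 lnc_0001 mir_0001 mrna_0002      up    down       up
#> 3 lnc_0002 mir_0002 mrna_0003    down      up     down
```

All three triads are exactly the planted ones; the run directory
contains TSV/SIF/GTF/FASTA outputs for every stage plus a
`run_manifest.yaml` (config hash, seed, file list).  Reruns of the same
configuration are byte-identical.

The same analysis is available as thin stage-by-stage drivers:

```sh
Rscript analysis/00_run_all.R     # or run 01..08 individually
```

```text
simulated inputs written to results/data/
DE calls: 17 up, 16 down of 330 features
novel lncRNAs: 1 of 6 candidates
network: 20 edges between 1 lincRNAs and 20 mRNAs
targets: 2 links (gene_cis_01 cis+trans, gene_cis_02 cis)
strict ceRNA triads: 3
top set: cis_module (k=2/3, p=0.107)
fold change case vs control: 2.85-fold (Welch p = 0.00017); rho vs activity score = 0.92 (p = 1.9e-05)
```

## Reproduction

* **Unit and property tests** (testthat 3e; every statistical routine is
  checked against an independent oracle — negative-binomial tails,
  subset enumeration, quartic alignment DPs, brute-force scans):

  ```sh
  Rscript -e 'devtools::test()'
  ```

* **Acceptance report** — recomputes oracle agreement, null calibration,
  planted-truth recovery, cascade exactness and byte-level determinism
  for any seed, and writes them as JSON:

  ```sh
  Rscript scripts/acceptance.R --seed 1 --out acceptance.json
  ```

  At seed 1: oracle max |Δ| ≤ 2e-14 over 7803 Audic–Claverie tuples and
  0 mismatches over all 65,536 seed-site windows; null p < 0.05 rate
  0.052/5000; DE sensitivity 1.0 and FDR 0.0 over 200 planted features;
  full module, site and triad recovery with 0 false triads; pipeline
  byte-identical across reruns.
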
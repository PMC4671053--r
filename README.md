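# nucdyn

Nucleosome and chromatin-state dynamics from MNase ChIP-seq, built for
cellular reprogramming time courses: mouse embryonic fibroblasts (MEF) →
partially reprogrammed cells (pre-iPSC) → induced pluripotent stem cells
(iPSC). Given aligned single-end reads per histone mark (H3, H3K4me3,
H3K27me3, H3K9me3), a gene annotation, a CpG-island set and an
FPKM/q-value expression table, the package computes:

- **Dyad tags** — reads shifted 73 bp (half a nucleosome) 3′-ward, with a
  PCR-duplicate cap chosen as the smallest per-position multiplicity that
  still retains ≥ 99 % of the library;
- **Occupancy comparison** — 10-kb depth-normalised bins classified per
  pair of conditions into *gain* / *loss* (≥ 1.5-fold) / *no nucleosomes* /
  *unchanged*; 100-kb log₁₀-RPKM Pearson correlation for replicates;
  coverage rates of genic/intergenic regions (≥ 150 bp); detailed region
  read fractions (TSS ± 300/600, TTS ± 300, genic rest, intergenic);
- **Nucleosome calls** — Gaussian-kernel (σ = 20 bp) peak calling with a
  147-bp exclusion zone; per-nucleosome **fuzziness** = the standard
  (RMS) deviation of tag positions about the dyad; one-to-one matching of
  common nucleosomes between conditions (dyad distance < 73 bp) and a
  paired two-tailed t-test on their fuzziness;
- **TSS metaprofiles and heatmaps** — ± 2-kb RPKM profiles (10-bp bins,
  5-bin moving average) for the top-5 % expressed / silent / other genes;
  per-gene matrices over −500..+1500 bp with exportable row order; K-means
  clustering of −300..+600 profiles;
- **Chromatin domains** — H3K4me3/H3K27me3 islands from 1000-bp windows
  (≥ 6 reads, one-gap merging, ≥ 60 reads total), classified into
  *active* / *repressive* / *bivalent* (≥ 50 % overlap of the smaller
  island) with condition-to-condition transition matrices;
- **Promoter states** — TSS ± 500 bp promoters split into HCG/LCG by
  CpG-island overlap; four states (K4 / K27 / K4K27 / None) by the strict
  \>1-RPKM rule; state-transition matrices per CpG class with expression
  coupling;
- **Expression** — DE filter (fold ≥ 2 with pseudocount 1, q < 0.05, any
  pairwise comparison), six-cluster temporal K-means on z-scored
  log₂(FPKM + 1), condition correlation matrices.

A fully seeded synthetic generator (`sim_config()`, `simulate_genome()`,
`simulate_nucleosome_map()`, `simulate_reads()`, `simulate_expression()`)
plants ground truth at every level — dyads, dispersions, occupancy
multipliers, promoter mark classes, DE trajectories — so the entire
pipeline is testable offline. See the methods vignette
(`vignettes/nucleosome-dynamics.Rmd`) for the model, parameter defaults
and known limitations.

## Worked example

```r
library(nucdyn)
res <- demo_run(seed = 7)        # full synthetic three-condition pipeline
s <- res$summary

round(unlist(s$bin_fractions), 3)
#>          gain          loss none_detected     unchanged
#>          0.09          0.32          0.00          0.59
```

The demo plants the reprogramming pattern — the intermediate condition
loses intergenic occupancy (× 0.5) and gains genic occupancy (× 1.2) — and
the 10-kb classifier reports 32 % of bins as loss against 9 % gain,
the expected asymmetry for a globally more open intermediate state.

```r
f <- s$fuzziness$first_vs_second
sprintf("MEF %.1f bp vs pre-iPSC %.1f bp, paired p = %.2g",
        f$mean_a, f$mean_b, f$p_value)
#> "MEF 28.3 bp vs pre-iPSC 24.4 bp, paired p = 6.8e-305"
```

Planted tag dispersions are 31 bp (MEF), 26 bp (pre-iPSC) and 32 bp
(iPSC): common nucleosomes in the intermediate state are measurably
better phased (means are slightly deflated by the ± 73-bp tag-assignment
window; see the vignette). The expression stage recovers all 18 planted
DE genes in six balanced clusters:

```r
s$n_de
#> 18
table(res$clusters)
#> C1 C2 C3 C4 C5 C6
#>  3  3  3  3  3  3
```

and the HCG promoter-state transition matrix (MEF → iPSC) shows poised
K4K27 promoters resolving to K4:

```r
round(res$promoter_transitions$HCG, 2)
#>           K4 K27 K4K27 None
#>   K4    0.92   0  0.08    0
#>   K4K27 1.00   0  0.00    0
```

`demo_run(seed, dir = "out")` additionally writes bedGraph tracks, BED
nucleosome calls and domains, promoter/expression TSV tables and a
summary JSON.

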
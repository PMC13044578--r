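# darkog

Discovery and characterization of conserved **dark gene families** —
orthogroups (OGs) whose member proteins have no informative functional
annotation — from orthogroup membership tables, exhaustive homology-search
results, taxonomy lineages, a species tree, and expression evidence. The
package targets comparative genomics of non-model lineages (it was built
with the cnidarian/stony-coral dark proteome in mind), where a large part of
the gene inventory is function-unknown and often taxonomically restricted.

## What it computes

- **Dark/light classification.** A protein is *light* if at least one
  homology hit with *e* ≤ 10⁻⁵ carries a description that is not one of the
  functionally ambiguous phrases ("uncharacterized protein", "hypothetical
  protein", "predicted protein", "expressed protein", "unnamed protein
  product"); otherwise it is *dark*. An OG is dark iff **all** members are
  dark.
- **LCA lineage assignment.** Each OG is assigned the most specific rank on
  a configurable ladder (tax_id → … → superkingdom, with a custom
  Complex/Robust suborder) at which all member datasets share one
  non-missing taxon.
- **Conserved dark OG selection.** Dark OGs restricted to one of the nested
  groups Scleractinia ⊆ Hexacorallia ⊆ Cnidaria and present in ≥ 50% of that
  group's datasets.
- **Homology detection failure (HDF).** Best bitscores of an OG against
  each dataset are modeled as exponential decay with patristic distance,
  `B(d) = a·e^(−b·d)`. The probability that a true homolog at distance `d*`
  falls below the Karlin–Altschul-style detection floor
  `B_thr = log2(L_rep · L_db / E)` is `P(B < B_thr)` under a Gaussian
  predictive distribution (residual variance plus delta-method parameter
  uncertainty). Datasets outside the OG's LCA with `p > 0.95` support HDF,
  `p < 0.05` count against; an OG is HDF-supported when ≥ 50% of scored
  non-LCA datasets support it.
- **Expression bias.** Dark-versus-light proportion-bias statistics over
  bulk DE comparisons (|log2FC| > 0.5, padj < 0.05), Welch-test proteomics
  (|log2 FC| > 0.5, p < 0.05), and single-cell fold changes (FC > 2.0),
  with reciprocal-best-hit id mapping (> 60% coverage) across dataset
  versions.
- **Remote-homology network.** HMM–HMM hits filtered at probability ≥ 50%
  (a ≥ 90% preset is included) and query/subject coverage ≥ 60%, scored by
  `score / alignment length`, deduplicated to one edge per unordered OG
  pair, with connected-component and node-attribute statistics.
- **Synthetic corpus generator.** Every input above, generated with planted
  ground truth (darkness, origin clades, decay parameters, cell-type
  enrichment, hub-and-burst network) under a single seed, so the whole
  pipeline is testable at desk scale.

## Worked example

```r
library(darkog)

cfg   <- simConfig(seed = 7, nFamilies = 600)   # 40 datasets
paths <- simulateAll(cfg, tempfile("sim"))
report <- runPipeline(pipelineConfig(paths), tempfile("run"))
reportSummary(report)
#> Corpus: 7079 proteins (18.0% dark), 600 OGs (130 dark). Conserved dark
#> OGs: 40 (Scleractinia 29 / Hexacorallia 6 / Cnidaria 5). HDF: 40
#> assessed, 47.5% supported, 52.5% rejected. Network: 33 nodes, 30 edges,
#> 3 components (largest 11).
```

130/600 OGs are recovered dark (the generator plants darkness on 25% of
families; protein-level darkness is lower because dark families tend to be
smaller here). 40 dark OGs pass the ≥ 50% group-coverage rule; about half
are HDF-supported, matching the planted fast/slow regime mix of 0.5. The
network stage recovers the three planted hub-and-burst components of 11 OGs
exactly.

The decay model itself:

```r
d   <- c(0, 0.5, 1, 2, 4)
fit <- fitDecay(d, 200 * exp(-0.5 * d) + c(3, -2, 1, -1, 0.5))
fit
#> DecayFit: B(d) = 201.6 * exp(-0.5086 * d)  [residual sd 1.94, n = 5]
predictUndetected(fit, 3, repLength = 300, dbLength = 1e6)
#> [1] 0.006
```

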
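# traitatlas

Trait-based comparative genomics for bacterial genome collections.
`traitatlas` turns per-genome functional annotations into a binary
genome × trait atlas and clusters it in both directions:

* **GFCs (Genome Functional Clusters)** — genomes with similar trait
  repertoires, found by exemplar (affinity propagation) clustering of the
  genome × genome phi-correlation matrix;
* **LTCs (Linked Trait Clusters)** — traits that co-occur across genomes
  more than expected by chance, found the same way on the trait × trait
  phi matrix after zeroing negative correlations and keeping only pairs
  significant under BH-FDR < 0.05 (chi-square, df = 1, using the identity
  χ² = n·φ²).

Around that core it provides: KEGG-style module completeness
reconstruction from KO annotations (complete iff every reaction has an
annotated alternative, tolerating one missing reaction in modules with
≥ 3 reactions), B-vitamin acquisition strategies per genome
(consumer = transport only, independent = synthesis only, flexible =
both) over the 4³ = 64-cell three-vitamin configuration space,
taxonomic-coherence labels for GFCs (monophyletic / paraphyletic /
polyphyletic), LTC presence rules (strict > 50% of traits per genome,
> 50% of genomes per GFC) with core/common/ancillary categories,
interaction-trait enrichment and genome-size-expectation tests, 16S
amplicon → GFC mapping with a specificity index (mapped only when every
retained hit falls in one GFC), and a temporal-synchrony test of
same-GFC vs different-GFC OTU pairs. A seeded synthetic-data generator
plants recoverable cluster structure so the whole pipeline is testable
without any external downloads.

## Worked example

The `analysis/` scripts run the whole workflow on a generated dataset
(150 genomes in 5 planted blocks, 300 traits in 6 linkage blocks, 10%
KO-annotation dropout, 90% genus concordance):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_build_traits.R
Rscript analysis/03_cluster.R
Rscript analysis/04_interpret.R
Rscript analysis/05_env_mapping.R
```

Stage 3 prints, among other things:

```
GFC clustering: ap_result: 150 items in 5 clusters (net similarity 100.3428, converged in 126 iterations)
trait pairs retained after FDR: 12395 of 46665
LTC clustering: ap_result: 306 items in 7 clusters (net similarity 220.0997, converged in 129 iterations)
GFC recovery ARI vs planted blocks: 1.000
LTC recovery ARI vs planted blocks: 1.000
```

i.e. at these noise levels the exemplar clustering recovers the planted
genome blocks and trait linkage blocks exactly (adjusted Rand index 1.0);
the 7 LTCs are the 6 planted linkage blocks plus the appended vitamin
traits. Stage 4 then reports the within-LTC vs background correlation
contrast (mean within-LTC r 0.659 vs background 0.018 here), the vitamin
strategy configurations occupied (55 of 64 cells), the GFC enriched in
interaction traits (the planted one), and the q/down-sampling
sensitivity scan. Stage 5 maps all OTUs at specificity index 1 and
detects the planted +3 sd same-GFC synchrony shift (one-sided Welch
p ≈ 3e-180, Wilcoxon in agreement, randomization controls null).

Programmatic use mirrors the scripts:

```r
library(traitatlas)
spec <- synthetic_spec(seed = 2024)
d <- write_synthetic_inputs(spec, "inputs")
m <- run_all("inputs", "outputs")         # full pipeline, one call
report("outputs")                          # markdown summary from tables
```

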
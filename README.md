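# hicnets

Chromatin interaction modules from Hi-C contact maps.

Hi-C counts how often pairs of genomic loci touch in 3D. Clusters of loci
that interact far more than expected — multi-enhancer neighborhoods around
lineage-defining genes — act as coherent regulatory units, but Hi-C alone
does not annotate them. `hicnets` infers these units directly from a raw
sparse contact map, for epigenomics and regulatory-genomics work where
H3K27ac HiChIP or similar enrichment assays are unavailable.

## Method

For each chromosome and each 1D distance $d$ (bin width up to 2 Mb), the raw
contact counts are modeled as negative binomial,
$K \sim \mathrm{NB}(\mu_d, r_d)$ with $\mathrm{Var}\,K = \mu_d + \mu_d^2/r_d$,
fitted by maximum likelihood (Poisson fallback when equi-dispersed). A bin
pair is a significant contact when $P(K \le k) \ge 0.975$ under its stratum
model. Significant pixels whose surrounding $11 \times 11$ matrix window
averages fewer than 1 raw count are discarded as contact-desert noise.
Surviving contacts form an undirected graph over genomic bins, which label
propagation or Louvain clustering partitions into **chromatin interaction
modules** (≥ 4 bins), each scored by

- **connectivity** — induced edge count,
- **transitivity** — 3 · triangles / connected triplets,
- **eigenvector centrality** — max-normalized principal-eigenvector scores,
  whose argmax is the module's *central node*.

Super-enhancers are called from H3K27ac peak occupancy by ROSE-style
stitching (12.5 kb gap) and an elbow threshold on the normalized rank curve
(the point where the slope is nearest 1). Two conditions are compared by
restricting each side to its highly connected modules (its own elbow),
evaluating every module's span in the counterpart network, and labeling
modules with connectivity fold change > 1.3 as condition-specific.

See `vignettes/chromatin-interaction-modules.Rmd` for the model,
assumptions, and design choices.

## Worked example

On a ground-truthed synthetic map (10 Mb chromosome, 10 kb bins, three
planted 200 kb modules with five-fold contact enrichment):

```r
library(hicnets)

tr  <- synthetic_truth(seed = 1)           # generating truth, 3 planted modules
sim <- simulate_contact_map(tr)
res <- find_modules(sim$records, resolution = 10000,
                    include_zeros = TRUE, n_bins = 1000, method = "louvain")
res
#> hicnets result for chrS at 10000 bp
#>   fitted strata:        200
#>   significant contacts: 3696 ( 180 after desert filter )
#>   network:              65 nodes, 180 edges
#>   modules (>= 4 nodes): 3

head(as.data.frame(res$modules))
#>   module_id chrom span_start span_end n_nodes connectivity transitivity
#> 1 chrS_M001  chrS    1980000  2220000      22           61    0.3097345
#> 2 chrS_M002  chrS    4970000  5200000      21           63    0.3534031
#> 3 chrS_M003  chrS    8000000  8200000      20           55    0.3322148
#>   central_node_start central_node_score
#> 1            2020000                  1
#> 2            5050000                  1
#> 3            8090000                  1
```

The three detected modules coincide with the planted spans at 2.0–2.2,
5.0–5.2 and 8.0–8.2 Mb: of 3696 per-count significance calls, the desert
filter keeps the 180 that sit in dense neighborhoods, and clustering the
resulting 65-bin graph recovers each planted block as one module. Each
module's central node (eigenvector-centrality argmax, score 1 after
normalization) marks its most embedded bin. Super-enhancer calling on
simulated H3K27ac peaks works the same way:

```r
pk <- simulate_peaks(seed = 1)
se <- call_super_enhancers(stitch_peaks(pk$peaks))
sum(se$is_super)   # 31 stitched regions above the elbow occupancy of ~25
```

A command-line wrapper over the same functions is installed at
`system.file("cli", "hicnets", package = "hicnets")` with subcommands
`call`, `diff`, `se`, `simulate` and `plot`.

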
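# umgnet

Prioritization of rarely mutated "long tail" cancer genes by **rank
mobility under network propagation**.

Most genes in a tumor cohort carry too few somatic mutations for
frequency-based methods to say anything about them. `umgnet` scores genes
by how far they *climb* when quantized mutation scores are diffused over a
protein–protein interaction (PPI) network: a rarely mutated gene embedded
in a heavily mutated neighborhood accumulates propagated score and rises
in rank, while frequently mutated drivers, already at the top, cannot rise
at all. The package is aimed at computational cancer-genomics analysts who
have a cohort's variant calls, one or more weighted PPI networks, and
(optionally) expression and dependency-screen data.

## Method

For a filtered PPI network G = (V, E) with weighted adjacency W, the
column normalization W′ = W·D⁻¹ (D = diagonal of column sums) drives a
random walk with restart on the quantized gene × sample mutation matrix
S⁽⁰⁾:

    S⁽ᵗ⁺¹⁾ = α W′ S⁽ᵗ⁾ + (1 − α) S⁽⁰⁾,   α = 0.8 by default

which converges geometrically (spectral radius ≤ α < 1) to
S = (1 − α)(I − αW′)⁻¹ S⁽⁰⁾. Per gene, IS and FS are the mean seed and
final scores across samples, RIS and RFS their descending ranks, and
MS = RIS − RFS the mobility. A gene is an **upward-mobility gene (UMG)**
when

    MS ≥ β·|G|   and   RFS ≤ T          (β cohort-specific, T = 1000)

Per-network lists are intersected across PPI sources and optionally
filtered by dependency evidence (kept when the fraction of the cancer
type's cell lines with negative knockout effect, maximized over CRISPR and
RNAi, is ≥ p = 0.5). Rankings are validated by a one-sided Mann–Whitney
enrichment of reference cancer genes toward top ranks, selected genes are
compared with the background on a smoothed cell-line impact score
ψ = (Σbⱼ + b̄)/(k + 2), and each UMG is categorized (`drug_target`,
`weak_driver`, `both`, `low_evidence`) by its adjacency to
score/degree-stratified drivers in the composite network.

See `vignettes/upward-mobility-genes.Rmd` for the full model description,
parameter table and design rationale.

## Worked example

Everything below runs offline on the package's seeded synthetic-cohort
generator, which plants 10 driver hubs and 15 rarely mutated genes wired
into driver neighborhoods across two overlapping scale-free networks:

```r
library(umgnet)

spec   <- synthetic_cohort_spec(seed = 42)   # 2000 genes x 100 samples
cohort <- generate_cohort(spec)

report <- run_umg_pipeline(
  networks     = cohort$networks,
  variants     = cohort$variants,
  gene_lengths = cohort$gene_lengths,
  expression   = cohort$expression,
  dependency   = cohort$dependency,
  drivers      = cohort$drivers,
  cohort       = "SYNTH", beta = 0.25)

print(report)
#> umg_report: cohort SYNTH, beta = 0.25, T = 1000
#>   synth_net1: 1900 genes ranked, 381 selected
#>   synth_net2: 1900 genes ranked, 388 selected
#>   final: 26 genes after intersection + dependency filter

head(report$final, 3)
#>    gene mean_RFS        DM  kept no_data
#> 1 G0587     33.0 0.6666667  TRUE   FALSE
#> 2 G0046     52.0 0.2857143 FALSE   FALSE
#> 3 G1913     93.5 0.9047619  TRUE   FALSE

length(intersect(cohort$planted_umgs, report$final_genes))
#> [1] 15   # all 15 planted genes recovered
```

`report$final` lists the intersected genes ordered by mean
post-propagation rank, with the dependency fraction `DM` and the filter
verdict. The validation statistics come with the report:

```r
report$per_network$synth_net1$enrichment
#> one-sided rank-sum enrichment (normal_approx): U = 18900, p = 2.366e-08 (n = 10 vs 1890)
report$impact_comparison
#> one-sided rank-sum enrichment (normal_approx): U = 41468.5, p = 1.465e-10 (n = 26 vs 1864)
table(report$categories$label)
#>  drug_target low_evidence
#>           15           11
```

Planted drivers are strongly enriched toward the top final ranks
(p ≈ 2×10⁻⁸), the selected genes' dependency impact scores are shifted
right of the background (p ≈ 10⁻¹⁰), and the 15 planted genes — all
wired to high-score drivers — are categorized `drug_target`, while the 11
zero-mutation co-selected genes are flagged `low_evidence`.

File-based runs use the same machinery through a YAML config
(`run_umg_config("config.yaml")`) or the thin CLI at `inst/cli/umg.R`
(`umg.R run --config config.yaml`, `umg.R simulate --out dir/ --seed 1`);
`write_cohort()` emits a complete set of standard-format inputs (edge-list
TSVs, MAF-like variant TSV, expression TSV, dependency CSVs, gene-set
text files) to experiment with.

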
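# ClonalKit

Single-cell immune receptor repertoire analysis in R: from the contig
annotation tables produced by 10x Genomics Cell Ranger (or any AIRR
Rearrangement TSV) to paired-chain clonotype calls, clonal-architecture
statistics, diversity and overlap estimators, Jensen–Shannon clustering
of clone-size distributions, and joins onto per-cell expression
metadata.

## Who it is for

Anyone with single-cell V(D)J enrichment data — T-cell receptor or
immunoglobulin — who wants quantitative repertoire analysis that slots
into an existing single-cell expression workflow. ClonalKit consumes
plain tables (contig annotations in, barcode-keyed metadata in) and
emits plain tables, so it is agnostic to whichever expression toolkit
produced your clusters and embedding.

## What it computes

A cell's **clonotype** is an identifier string built from its paired
receptor chains, at four resolutions: gene usage (`CTgene`), CDR3
nucleotide (`CTnt`), CDR3 amino acid (`CTaa`), or gene + nucleotide
(`CTstrict`). Loci are joined by `_`, a missing chain is the literal
`NA`, and same-locus duplicates (dual-alpha T cells) are joined by `;`.

On the clone abundance vectors this induces, the package computes:

- unique-clonotype quantification, raw or scaled (100·unique/total);
- abundance and CDR3-length tables (combined lengths count sequence
  only, never the `NA` placeholder);
- clonal homeostasis: space occupied by proportion classes
  (rare → hyperexpanded);
- clonal proportion: cell counts held by clonotype rank ranges;
- diversity: Shannon H = −Σpᵢ ln pᵢ, inverse Simpson 1/Σpᵢ²,
  bias-corrected Chao1 S + F₁(F₁−1)/(2(F₂+1)), and ACE with the
  standard rare-class ceiling of 10;
- pairwise overlap: overlap coefficient |A∩B|/min(|A|,|B|) and the
  Morisita–Horn index 2Σxᵢyᵢ/((Σxᵢ²/X² + Σyᵢ²/Y²)·X·Y);
- clone-size distribution comparison: Jensen–Shannon divergence (base
  2) between log-binned clone-size spectra, with average-linkage
  clustering and Newick export.

A seeded synthetic generator (`simulateRepertoire()`) plants known clone
sizes, dual-alpha clones, chain dropout and multi-contig artifacts, and
is used throughout the tests for exact parameter recovery.

## Worked example

```r
library(ClonalKit)

sims <- lapply(1:2, function(i)
  simulateRepertoire(nCells = 300, seed = i, sampleName = paste0("s", i)))
rep <- combineReceptors(lapply(sims, `[[`, "contigs"),
                        samples = c("s1", "s2"), groups = c("P", "T"))
rep
#> RepertoireSet with 2 sample(s), 598 cells
#>   s1 (P): 299 cells
#>   s2 (T): 299 cells

clonalQuant(rep, scaled = TRUE)
#>   sample unique total    value
#> 1     s1    185   299 61.87291
#> 2     s2    152   299 50.83612

clonalDiversity(rep)
#>   sample cells richness  shannon inv_simpson    chao1      ace
#> 1     s1   299      185 4.880346    76.47648 626.4348 754.3802
#> 2     s2   299      152 4.536190    46.58729 333.1379 437.1292

round(clonalOverlap(rep, "morisita"), 4)
#>    s1 s2
#> s1  1  0
#> s2  0  1
```

Reading the output: sample s1 holds 185 distinct clonotypes among 299
cells (61.9 % of library size), with Shannon entropy 4.88 nats and an
effective clone number (inverse Simpson) of 76.5; Chao1/ACE estimate
several hundred clonotypes remain unseen, as expected for a
singleton-rich power-law repertoire. The two independently simulated
samples share no clonotypes, so their Morisita–Horn overlap is 0.

Joining onto expression metadata:

```r
meta <- simulateCellMeta(rep[["s1"]]$barcode, nClusters = 4, seed = 1)
joined <- joinExpression(meta, rep)          # left join by barcode
table(joined$freq_bin)                       # Single/Small/... classes
perCluster <- splitByMetadata(joined, "cluster")
clonalDiversity(lapply(perCluster, metaCountVector))
```

A thin command-line wrapper with subcommands `simulate`, `combine`,
`metrics`, `diversity`, `overlap`, `join` and `run` lives at
`inst/scripts/clonalkit`; `runPipeline()` drives the same chain from a
single YAML config and writes every table plus a run manifest.

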
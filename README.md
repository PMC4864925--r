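# ptmsel

Selection and driver analysis of cancer somatic missense mutations in
lysine acetylation and ubiquitination sites.

Post-translational modifications (PTMs) of lysine — acetylation and
ubiquitination — regulate protein degradation, chromatin state and
signalling. A missense single-nucleotide variant (SNV) that substitutes
a modified lysine, or a residue in its flanking sequence, can rewire
these regulatory circuits. `ptmsel` implements an end-to-end analysis
of this mutation class for computational cancer biologists: it maps PTM
sites onto a proteome, asks whether site regions are under positive
selection in a tumour cohort, scores individual genes as candidate
drivers, lifts the signal to pathways, and searches a protein
interaction network for modules whose mutations correlate with patient
survival. A seeded synthetic-data generator with planted ground truth
makes the whole pipeline testable end to end without any external
downloads.

## The statistics at the core

**Site regions and mutation classes.** A PTM site is a modified lysine
K at position *p*; its region is the closed interval
[*p* − 7, *p* + 7], clipped to the protein, with overlapping regions
merged. A mutation at offset 0 from the nearest central lysine is
*direct*, at offset 1–2 *proximal*, at 3–7 *distal*, otherwise
unrelated. Sites arriving as 15-mer sequence contexts are mapped by
exact substring match (every occurrence counts; partial matches are
discarded).

**Bootstrap selection tests.** For each PTM type, restricted to
proteins carrying that modification, the per-residue mutation rate
inside merged regions is compared with the rate outside:
FC = (m_in / L_in) / (m_out / L_out). The null redistributes each
protein's mutations uniformly over its own residues, preserving
per-protein totals, and the one-sided empirical p value uses the
add-one rule p = (1 + b) / (1 + B) over B shuffles (default 100,000).
The same machinery contrasts modified versus non-modified lysines,
domain versus non-domain sequence, and the conservation of PTM versus
non-PTM mutations within disorder strata.

**Per-gene driver test.** For each gene with at least one site and one
mutation, per-residue counts are regressed on the disorder track
(Poisson, log link; uniform-rate fallback for degenerate designs). The
expected active-site count E sums the fitted means over region
residues, the observed count O is compared through the exact Poisson
upper tail P(X ≥ O | E), and genes are ranked after
Benjamini–Hochberg adjustment (FDR < 0.05). A
mutation-frequency-binned permutation test (100 bins, up to 10⁷
permutations) measures overlap of the detected genes with a known gene
list.

**Pathways.** Gene sets (GMT; 3–1000 modified members, at least two
separately mutated proteins) are tested with a Poisson exact test:
λ = background regional rate × the set's summed region length.
Significant sets are exported as an enrichment map (overlap
coefficient ≥ 0.5).

**Survival modules.** Within each cancer type, a greedy
HyperModules-style search grows connected modules from mutated network
genes, at each step adding the neighbour that most improves the
two-group log-rank p value of mutation carriers versus non-carriers.
Family-wise control uses 100 network-shuffling permutations: gene
labels are permuted on the nodes, the full search is rerun, and a
module is kept when its log-rank p beats the permutation minima with
empirical p < 0.05.

## Worked example

```r
library(ptmsel)

cfg <- simConfig(seed = 7, nProteins = 60, nSamples = 300, burdenMean = 25)
b <- simulateBundle(cfg)
b$dataset
#> PTMDataset
#>   proteins    : 60 (total 27995 residues)
#>   PTM sites   : 436 (117 acetylation, 366 ubiquitination, 47 shared)
#>   mutations   : 11055 in 298 samples
#>   domains     : 54; network edges: 101; survival records: 300
#>   gene sets   : 50; predictor calls: 11055

ann <- classifyMutations(b$dataset)
table(ann$category)
#>   direct   distal     none proximal
#>      190     1725     8324      816

bootstrapRegionEnrichment(b$dataset, "acetylation", nShuffles = 10000)
#> EnrichmentResult: region_enrichment [acetylation / all]
#>   observed 754, expected 672.3, FC = 1.126
#>   empirical p = 0.0008999 (10000 shuffles, one-sided)

dr <- scanDriverGenes(b$dataset)
head(dr[, c("gene", "n_mutations", "O", "E", "p", "fdr")], 3)
#>    gene n_mutations   O         E            p          fdr
#> 1 P0009         608 281 142.00834 5.702395e-25 3.364413e-23
#> 2 P0043         369 153  73.59326 4.391680e-16 1.295546e-14
#> 3 P0011         204  69  28.11102 5.637607e-11 1.108729e-09

b$truth$driver_genes
#> "P0009" "P0011" "P0043" "P0052" "P0059"
```

The acetylation regions of this cohort are mutated 1.13-fold above the
resampling expectation (754 observed versus 672 expected SNVs), and the
three most significant genes in the driver scan are all planted
drivers, each with an observed active-site count about twice its null
expectation.

The same stages run from the shell over a bundle directory:

```sh
Rscript scripts/ptmsel-pipeline.R simulate --out bundle --seed 7
Rscript scripts/ptmsel-pipeline.R all --in bundle --out results --seed 7
```

which writes `regions.tsv`, `annotations.tsv`, `selection_stats.tsv`,
`drivers.tsv`, `hotspots.tsv`, `pathways.tsv`, `em_nodes.tsv`,
`em_edges.tsv`, `modules.tsv` and a JSON run manifest.

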
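# divset

Diverse-set selection for SNP-genotyped germplasm collections.

Genebank collections of selfing crops are large and redundant: the same
line deposited under several names, near-isogenic derivatives, duplicated
landraces. Researchers who can grow only a limited number of accessions
need a *diverse set* (DS) — a subset that retains as much of the
collection's allelic diversity as possible while excluding genetically
identical material. divset implements the stratified selection workflow
used for such collections, end to end:

1. **Distance** — pairwise allele-sharing (identity-by-state) distances
   $d_{ij} = \sum_l g_{ij,l} / N_{ij}$, where per locus $g$ is 0 for
   identical homozygotes, 1 for opposite homozygotes, 0.5 for het vs hom,
   1 for het vs het (configurable to 0), and loci missing in either
   accession are excluded from both the sum and the compared-locus count
   $N_{ij}$.
2. **Redundancy** — single-linkage groups of accessions above a similarity
   threshold (default >99.9%), flagging duplicates and near-duplicates.
3. **Clustering** — k-means-style iterative reassignment on genetic
   similarity (each accession represented by its similarity-matrix row),
   with seeded farthest-point initialization and a post-pass that
   co-labels zero-distance accessions.
4. **Selection** — one accession per cluster, honouring user preference,
   exclusions and seed availability; maturity-group (MG) windows pool a
   target MG with its adjacent MGs; a spreadsheet-style selector table can
   be exported for manual picking.
5. **Evaluation** — percentage of panel SNPs that remain polymorphic in a
   subset, replicate DS-vs-random-set comparisons with Welch t-tests,
   pairwise-distance histograms, SNP-subset consistency checks and
   retention-plateau detection.
6. **Simulation** — a Balding–Nichols generator of structured inbred
   collections (skewed subpopulations, duplicate groups, residual
   heterozygosity, missing calls, MG labels) so every stage is testable
   without external data.

Genotypes are read and written in the PLINK text (PED/MAP) and PLINK 1
binary (BED/BIM/FAM, SNP-major) dialects; metadata, cluster tables,
distance matrices and reports are plain CSV.

## Worked example

```r
library(divset)

sim <- simulate_collection(n_accessions = 200, n_snps = 2000, seed = 42)
D   <- pairwise_distance(sim$genotypes)
D
#> ibs_dist: 200 accessions, 19900 pairs (het/het rule = 1)
#>   distance range [0.0000, 0.3699], mean 0.3194; zero-distance pairs: 94

redundancy_groups(D, threshold = 0.999)
#> redundancy_groups: 13 groups at similarity > 0.999
#>   accessions in groups: 47; 100% identical to another: 44
#>   group sizes: 9, 9, 6, 3, 3, 3, 2, 2, 2, 2

A  <- kmeans_cluster(D, k = 25, seed = 1)
ds <- build_diverse_set(A, meta = sim$meta, seed = 1)
ds
#> diverse_set: 25 picks from k = 25 clusters (seed 1)
#>   modes: random=25; exhausted clusters: 0

polymorphic_retention(sim$genotypes, ds$picks$accession_id)
#> retention_report: 25 accessions retain 1812 / 2000 SNPs (90.60%)

compare_ds_rs(sim$genotypes, sizes = c(15, 25), replicates = 10, seed = 1)
#> comparison_report: 10 replicates per arm (seed 1)
#>   size   15: DS 86.83% (sd 0.35)  RS 83.73% (sd 1.24)  p = 1.5e-05 **
#>   size   25: DS 90.72% (sd 0.28)  RS 88.81% (sd 1.30)  p = 0.00113 **
```

Reading the output: 47 of the 200 simulated accessions fall in >99.9%
similarity groups (the simulator planted ~25%, plus their group heads). A
25-accession diverse set retains 90.6% of the 2,000-SNP panel; at equal
sizes, diverse sets beat purely random sets by 2–3 percentage points with
far lower replicate spread, significant at the 1% level (`**`).

The same pipeline runs from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "divset.R", package = "divset"))')
Rscript "$CLI" simulate --out sim --n-accessions 200 --n-snps 2000 --seed 42
Rscript "$CLI" cluster  --bfile sim/sim --k 25 --meta sim/sim_meta.csv --out clusters
Rscript "$CLI" select   --bfile sim/sim --k 25 --meta sim/sim_meta.csv --out ds
Rscript "$CLI" evaluate --bfile sim/sim --sizes 15,25 --out eval
```

Every subcommand writes a JSON manifest of its parameters and seeds next
to its outputs; identical arguments and seed give byte-identical CSVs.

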
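# ahepipe

An R implementation of the bioinformatic workflow behind **anchored hybrid
enrichment (AHE) phylogenomics** — the target-capture approach that
hybridizes tiled 120 bp probes to conserved exonic "anchor" regions and
sequences the captured fragments, recovering both the anchors and their
variable flanks across many species at once. The package is aimed at
phylogeneticists who want a tested, scriptable version of every step
between raw paired FASTQ reads and a RAxML-ready supermatrix, plus a
ground-truthed simulator to validate the whole chain.

## What it does

| stage | functions | core rule |
|---|---|---|
| probe/target design | `select_targets()`, `find_exon_boundaries()`, `mask_high_copy()`, `tile_probes()` | ≥6 taxa, ≥150 bp, no exon boundary, no indels, a 120 bp window with >50% pairwise identity; 15-mer (±1 bp) high-copy masking; 120 bp probes at 1.72× tiling |
| read merging | `merge_pair()`, `merge_pairs()` | lowest binomial tail probability over all overlap degrees, *P*(X ≥ m \| o, 0.25) < 10⁻¹⁰ to merge; quality sum on match, difference on mismatch |
| assembly | `reference_library()`, `spaced_kmer_match()`, `map_read()`, `assemble_individual()` | spaced 20-mer seeds (≥17/20), ≥55 matches per 100 aligned bases, exact 60-mer de-novo extension to a fixed point |
| consensus | `refine_offsets()`, `call_consensus()` | Binomial(n, 0.1) error model at α = 0.05, IUPAC ambiguities, lowercase soft-mask below 5× coverage |
| orthology | `filter_low_coverage()`, `kmer_distance()`, `cluster_orthologs()` | <10-read clusters removed; shared-20-mer Jaccard distance (consecutive + every-third-base spaced); ≤1 sequence per individual per cluster; ≥50% species occupancy |
| trimming | `run_aligner()`, `trim_alignment()` | MAFFT `--genafpair --maxiterate 1000`; conserved = modal char >40%; 20 bp windows with <10 stable sites masked; columns with <12 unmasked bases removed |
| supermatrix | `concatenate_loci()`, `count_informative()`, `nj_tree()` | partitioned concatenation, parsimony-informative site counts, neighbor-joining sanity tree |

The merging criterion: for overlap degree *o* with *m* matching bases the
pipeline evaluates the one-sided binomial tail
*P*(X ≥ m | o, p₀ = 1/4), picks the degree minimizing it, and merges only
below 10⁻¹⁰. The consensus rule: a column's majority base is called
outright when its minority count is explainable as sequencing error under
Binomial(n, 0.1) at α = 0.05, otherwise the IUPAC code over the
individually significant bases is emitted.

A first-class simulator (`sim_config()`, `simulate_ahe()`) generates a
species tree, anchor/flank-structured loci (slow conserved core, fast
flanks), 150–350 bp fragments sequenced as PE150 pairs with Phred
qualities, low-level contaminants and optional planted paralogs — with
full provenance, so recovery can be audited against the planted truth.

## Worked example

```r
library(ahepipe)

cfg <- sim_config(seed = 7, n_taxa = 5, n_loci = 4)
print(cfg)
#> AHE simulation config: 5 taxa, 4 loci of 500 bp, 20x depth, PE150 reads, seed 7

sim <- simulate_ahe(cfg)
print(sim$reads)
#> AHE read set: 5 individuals, 855 read pairs ( 9 contaminant )

pipe <- ahe_pipeline(sim = sim)
print(pipe)
#> AHE pipeline run: 5 individuals, 23 consensus sequences, 4 trimmed loci
#> Supermatrix: 5 taxa x 1819 sites over 4 loci; 269 informative sites; 0.0% missing

str(evaluate_pipeline(pipe))
#> List of 7
#>  $ recovered_frac             : num 1
#>  $ n_recovered                : int 20
#>  $ n_expected                 : int 20
#>  $ mean_identity              : num 1
#>  $ contaminant_clusters_before: int 0
#>  $ contaminant_clusters_after : int 0
#>  $ rf_distance                : num 0
```

All 20 locus × taxon haplotypes are recovered at 100% identity on
well-covered (uppercase) sites, every contaminant read fails to assemble
into a surviving cluster, and the neighbor-joining tree built from the
1,819-site supermatrix matches the generating species tree exactly
(Robinson–Foulds distance 0). `write_supermatrix()` emits relaxed PHYLIP,
FASTA, the `DNA, locus = a-b` partition file and a stats TSV for
downstream maximum-likelihood analysis.

A thin command-line front end mirrors the R API
(`inst/cli/ahe.R`: `sim`, `merge`, `assemble`, `orthology`, `trim`,
`matrix`, `run`), e.g.

```sh
Rscript $(Rscript -e 'cat(system.file("cli/ahe.R", package="ahepipe"))') \
    run --config sim.yaml --out run_out/
```

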
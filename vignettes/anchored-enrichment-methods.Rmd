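---
title: "Methods: the anchored-enrichment pipeline and its simulator"
author: "ahepipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the anchored-enrichment pipeline and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What this package computes

Anchored hybrid enrichment (AHE) targets conserved exonic "anchor" regions
with tiled 120 bp probes; the captured fragments also carry the faster-
evolving flanking sequence that holds most of the phylogenetic signal at
shallow timescales. `ahepipe` implements the complete bioinformatic path
from raw paired reads to a partitioned supermatrix:

1. **Probe/target design** from multi-species locus alignments
   (`select_targets()`, `find_exon_boundaries()`, `mask_high_copy()`,
   `tile_probes()`).
2. **Statistical read merging** of overlapping PE150 pairs
   (`merge_pair()`, `merge_pairs()`).
3. **Hybrid assembly** — divergent-reference mapping by spaced 20-mers plus
   de-novo extension by exact 60-mers (`assemble_individual()`), offset
   refinement (`refine_offsets()`) and binomial consensus calling
   (`call_consensus()`).
4. **Contamination filtering and orthology**
   (`filter_low_coverage()`, `kmer_distance()`, `cluster_orthologs()`).
5. **Alignment and trimming** (`run_aligner()`, `trim_alignment()`).
6. **Supermatrix construction** with partition table, occupancy and
   informativeness statistics and an NJ sanity tree
   (`concatenate_loci()`, `count_informative()`, `nj_tree()`).

A ground-truthed simulator (`sim_config()`, `simulate_ahe()`) generates
AHE-like experiments so every stage can be validated against a planted
truth without any external data.

## The statistical models

### Overlap merging

For a candidate overlap of degree $o$ with $m$ matching bases, the pipeline
computes the one-sided binomial tail
$P(X \ge m \mid o, p_0)$ with $p_0 = 1/4$ (uniform-base null). Every degree
$1 \dots \min(|r_1|, |r_2|)$ is evaluated, the degree with the smallest
tail probability wins (ties go to the longer overlap — the physically
larger explanation), and the pair is merged only when that probability is
below $10^{-10}$. In the overlap, agreeing bases keep their base with
quality $\min(93, q_1 + q_2)$; disagreeing bases take the higher-quality
base with quality $|q_1 - q_2|$, and an `N` never wins a disagreement. The
quality algebra and the uniform null are the conventional choices; both are
configurable (`p_null`, `qual_cap`). No minimum absolute overlap is imposed
beyond the probability criterion itself. Only the "innie" geometry
(fragment at least one read long) is searched; the simulator never produces
fragments shorter than a read.

### Mapping and assembly

The reference library holds, per locus, the majority-rule consensus of the
design alignment restricted to the probe (anchor) region, and spaced
20-mers — 20 sampled positions every third base (58 bp span) — anchored at
design-alignment columns with modal-base frequency of at least 90%. The
every-third-base pattern is the same spacing the orthology distance uses;
anchoring at conserved columns keeps seeds findable in divergent
individuals. A read obtains a preliminary hit when at least 17 of the 20
sampled positions match (`spaced_kmer_match()`), and is accepted for a
locus when the best gap-free placement against the reference achieves at
least 55 matches within 100 consecutive aligned bases (`map_read()`; at
60% identity an ortholog still passes comfortably while random sequence,
expected 25 matches, essentially never does). Reads are tried in both
orientations; capture is strand-agnostic.

Placed reads contribute their exact 60-mers to a hash; an unplaced read
joins a locus by sharing a single exact 60-mer with it, which is how
contigs extend into the flanks beyond the probe region. Passes over the
three read files (merged, unmerged mate 1/2) repeat until a full pass adds
nothing; the placed-read set grows monotonically, so the iteration reaches
a fixed point (a cap of 50 passes guards pathological inputs).

60-mers are then clustered: pairs of 60-mers at adjacent read positions
that co-occur in at least two reads are unioned, and each read joins the
component holding the majority of its 60-mers (ties to the larger
component). Counting only adjacent pairs is a connectivity-preserving
restriction of the full co-occurrence relation: at 20x coverage every
adjacent pair of true k-mers recurs in ~15 reads, while k-mers containing
a sequencing error are singletons under either rule, so the resulting
partition is the same at a fraction of the cost. A single-copy locus
yields one cluster; a duplicated locus at 10% divergence yields two,
because the copies share essentially no 60-mers. (A rare identical 60-mer
shared between copies can bridge them into one cluster — an inherent
property of the published co-occurrence rule, not of this implementation.)

Offset refinement tries, for every read, shifts within ±3 and a single gap
insertion at each read position, accepting changes that improve the read's
agreement with the majority profile of the other reads and never letting
the cluster's total column agreement (the sum over columns of the majority
count) decrease. Displacements beyond ±3 are treated as assembly errors;
the bounded search keeps refinement linear in the number of reads.

### Consensus calling

Per column with coverage $n$ and majority count $m$: the majority base is
called when $n = m$ or when the minority count can be explained as
sequencing error under $\mathrm{Binomial}(n, 0.1)$ at $\alpha = 0.05$,
i.e. $P(X \ge n - m) \ge 0.05$; otherwise the IUPAC code over the majority
base and every minor base whose own count is individually significant
($P(X \ge k) < 0.05$) is called. Bases at columns with coverage below 5
are soft-masked to lowercase. Counts are unweighted, as the binomial model
implies; merged-read qualities do not enter the call. An empty interior
column (possible only through gap placement) is written as masked `n`,
keeping the lowercase-iff-low-coverage invariant exact.

### Orthology

Consensus sequences from clusters with fewer than 10 reads are removed as
possible low-level contaminants; survivors are grouped by locus into
homolog sets. The distance between two homologs is one minus the Jaccard
similarity of their combined k-mer sets — all consecutive 20-mers plus all
spaced (every third base) 20-mers, case-folded so soft-masked bases
participate: masking encodes coverage, not sequence doubt severe enough to
exclude. The union denominator makes the similarity symmetric and bounded.
Pairs are ranked by distance (ties in lexicographic member-id order, so the
output is invariant to input order) and agglomerated; a merge whose union
would contain two sequences from one individual is skipped outright, never
deferred, and pairs sharing no k-mer at all (distance 1) never join.
Clusters covering fewer than 50% of the study's species are dropped; the
occupancy filter runs after agglomeration terminates and counts distinct
species, not sequences.

### Alignment trimming

Each ortholog set is aligned with MAFFT (`--genafpair --maxiterate 1000`);
when no aligner executable is available a bundled center-star progressive
aligner (global pairwise alignments against the longest member, merged on
the star center) serves for tests and tiny inputs. Trimming then proceeds
in three steps: (i) a column is *conserved* when its most common non-gap
character occurs in strictly more than 40% of the sequences; (ii) for each
row, a site is *stable* when its column is conserved and the row matches
the modal character (an IUPAC ambiguity matches when the modal base is
among its members — heterozygous-looking but correct sites should not be
masked), and every window of 20 consecutive ungapped row positions with
fewer than 10 stable sites is masked to `?` (a sequence's 20 bp is
sequence length, not alignment length); (iii) columns with fewer than 12
characters outside `{?, -}` are removed. Gaps count neither toward modal
frequencies nor as unmasked: they are absence of data.

A single pass of these steps is not idempotent: masking lowers modal
counts, which can flip conserved flags and trigger more masking on a
second application. `trim_alignment()` therefore iterates the three steps
to a fixed point (masking and removal are monotone, so the iteration
terminates), making the full procedure idempotent by construction while
each individual step remains exactly the published single-pass rule. The
column-removal threshold of 12 presumes a study of a few dozen taxa;
`ahe_pipeline()` clamps it to the simulated species count so desk-scale
runs with 8 taxa are not trimmed to nothing.

### Supermatrix and NJ tree

Trimmed loci are concatenated over the union of taxa, absent loci padded
with `?`; the partition table is written in the RAxML dialect
(`DNA, locus = a-b`, 1-based inclusive) for downstream maximum-likelihood
analysis, which this package deliberately leaves to the dedicated tools. A
site is parsimony-informative when at least two A/C/G/T states each occur
in at least two taxa (ambiguities count as missing). The sanity tree is
neighbor joining on p-distances with pairwise deletion, negative branch
lengths clamped to zero; soft-mask case is uppercased on FASTA/PHYLIP
export with a sidecar BED, since phylogenetics formats carry no case
semantics.

## The simulator: what it emulates, and what it does not

`sim_config()` describes the experiment; the defaults are the study
conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `n_taxa` | 8 | sampled species/individuals |
| `n_loci` | 30 | capture targets |
| `anchor_len`, `flank_len` | 200, 150 bp | conserved core, two flanks |
| `anchor_rate_scale`, `flank_rate_scale` | 0.3, 1.5 | relative rates |
| `tree_height` | 0.15 subs/site | root-to-tip divergence |
| `coverage_mean` | 20x | mean per-base depth per locus |
| `fragment_len_range` | 150-350 bp | sonication emulation |
| `read_len` | 150 bp | PE150 sequencing |
| `base_error_rate` | 0.003 | per-base error |
| `contam_fraction` | 0.01 | contaminant read pairs |

The species tree is a coalescent topology rescaled to `tree_height`, with
branch lengths floored at 5% of the height: topology recovery is only a
meaningful benchmark when internal branches carry signal (roughly
≥0.01 substitutions/site at these sequence lengths). Loci evolve under
HKY85 (Jukes-Cantor is the κ = 1, equal-frequency special case and the
default) with the region-specific rate multipliers producing the
anchor/flank conservation contrast that the whole capture design rests on.
Fragment lengths are uniform on 150–350 bp, positions uniform within a
locus, and fragments never span loci — enrichment concentrates reads on
targets. Correct bases get Phred 40; error bases get a quality drawn
uniformly from 2–20, which makes quality-aware merging decisions
observable. Contaminants are fragments of an unrelated uniform-random
sequence, guaranteeing negligible k-mer sharing with targets. Duplications
(`dup_loci`) plant a paralog: a copy of one taxon's haplotype mutated at
`dup_divergence` (10%) per site, sequenced alongside the original.
`coverage_mean` is a target *depth*; the per-locus fragment count is drawn
as Poisson with mean `coverage_mean · L / E[footprint]`, where the
footprint is the distinct bases a pair covers.

Deliberately not modelled: indels during evolution, PCR duplicates,
adapter read-through, and quality-by-cycle profiles. Passing tests
therefore demonstrate the statistical machinery on data whose noise is
i.i.d. substitution error; real libraries add artefacts (chimeras, index
hopping, heterozygosity) that this simulator does not probe.

## Numerical and design choices

* Pairwise identity excludes columns where either row of the pair is
  gapped — gap columns carry no substitution signal; the identity window
  screen uses the mean over pairs (minimum available via `stat = "min"`).
* Exon-boundary 40-mer matches are resolved to the leftmost genome site;
  masked positions split a target and the length filter is re-applied to
  the pieces (`split_masked_targets()`).
* Probe starts are integer-floored from the uniform step
  `probe_len / density`, first probe at the region start, last probe
  right-anchored at the region end, so realized per-base coverage
  converges to the configured 1.72x for long regions (within 5% beyond
  ~1.2 kb).
* Ties everywhere break deterministically: smallest mapping offset,
  longest overlap, lexicographic pair order in orthology, first-listed
  base in majority votes.
* Problem sizes in the shipped tests — 8 taxa x 30 loci at 20x for the
  end-to-end run, 20 replicate seeds for paralog safety, 100-1000 random
  cases for the oracle equivalences — were chosen so the full suite
  documents the study conditions while remaining comfortable to run on a
  laptop.

## Known limitations

* The de-novo extension requires an exact 60-mer; at very low coverage or
  very high error rates flank recovery breaks before reference mapping
  does.
* The center-star fallback aligner is adequate for near-identical
  sequences only; any serious run should have MAFFT on the PATH.
* Orthology is k-mer based; it separates paralogs via the per-individual
  constraint but performs no tree-based reconciliation and no paralog
  rescue.
* Maximum-likelihood inference, model selection and bootstrapping are out
  of scope: the package emits RAxML-ready inputs and only an NJ sanity
  topology.
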
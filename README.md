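# otukit

De novo OTU clustering and amplicon read preprocessing for marker-gene
(16S rRNA / ITS) community surveys, with a ground-truth read simulator
and truth-based evaluation metrics.

## Who this is for

Microbial ecologists and bioinformaticians who need a self-contained,
deterministic implementation of the classic 454/Illumina amplicon
workflow — raw FASTQ to OTU table — and a way to *measure* how well a
clustering run recovers a known community, without downloading reference
databases or external binaries.

## The algorithm

Reads are quality-trimmed (sliding window of 10% of the read length,
truncating at the first window whose mean Phred drops below Q20),
primer-trimmed (semi-global alignment, IUPAC-aware), stripped of
terminal/contiguous `N`s and length-filtered. Dereplicated sequences
(exact-prefix fast mode, or full mode = clustering at 100% identity)
are orderd by abundance, optionally purged of two-parent chimeras, and
clustered greedily:

* the most abundant unassigned sequence seeds a cluster;
* remaining sequences are ranked by k-mer similarity
  `sum_tau min(n_i, n_j) / (min(l_i, l_j) - k + 1)` (k = 8);
* each candidate is accepted when its **gap-ignoring pairwise identity**
  — matches / (matches + mismatches) over the gapless columns of a
  unit-cost Needleman–Wunsch alignment — reaches the threshold
  `s_thr` (default 0.97); accepts reset a reject counter, misses
  increment it, and the scan stops once it exceeds `m` (default 32).

Ignoring gap columns makes homopolymer indel errors (the signature 454
artifact) and 5'-anchored length differences free, so clusters form
around biological templates rather than read-length strata. The engine
is Rcpp-backed and bit-reproducible; at `m = Inf` it is provably
identical (and tested) against a brute-force greedy scan.

The simulator generates power-law communities (`p_i ∝ i^-alpha`) from a
synthetic reference pool, with exact chimera fractions (default 20%,
90% bimeras / 10% trimeras), 454-like quality decay, homopolymer indel
errors and per-read truth labels, so every claim the package makes can
be checked against a known answer.

## Worked example

```r
library(otukit)

# simulate one amplicon sample with known composition
refs <- make_reference_pool(60, seed = 42)
community <- sample_community(n_otus = 30, alpha = 1, refs, seed = 42)
sim <- generate_sample(community, n_reads = 2000, chimera_frac = 0.20,
                       sample_id = "S1", seed = 43)

# quality filtering, dereplication, chimera filter, clustering
pp <- preprocess(sim$records)
attr(pp$stats, "pass_fraction")
#> [1] 0.9995
dereps <- dereplicate(pp$kept, "full")
dereps <- flag_chimeras(dereps, detect_chimeras(dereps))
clusters <- cluster_denovo(dereps, cluster_params(identity_threshold = 0.97))
clusters
#> otu_clusters: 116 OTUs, 1911 reads, threshold 0.97

# compare against the simulator's ground truth
map <- map_otus(clusters, sim$truth)
count_redundant(map)            # artifactual splits of one true taxon
#> [1] 1
count_chimeric_otus(map)        # OTUs seeded by a labelled chimera
#> [1] 88
round(chimeric_read_fraction(clusters, sim$truth), 3)
#> [1] 0.166
round(top20_rss(clusters, sim$truth, map), 5)
#> [1] 0.00775

# per-sample diversity from the OTU table
tab <- build_otu_table(clusters)
round(diversity_index(tab$counts["S1", ], "shannon"), 3)
#> [1] 3.097
round(chao1(tab$counts["S1", ]), 1)
#> [1] 397.2
```

Reading the numbers: 99.95% of reads survive filtering; the 30-source
community is recovered with a single redundant split and a top-20
abundance RSS of 0.008; 16.6% of clustered reads are surviving labelled
chimeras (mostly reads whose chimeric junction lies beyond the read end
— content-identical to a parent and undetectable in principle), and the
simplified detector leaves 88 small chimera-seeded OTUs, which the
truth-mapping correctly separates from biological ones. The methods
vignette (`vignettes/otu-clustering-methods.Rmd`) discusses what these
metrics do and do not establish.

## Command line

An executable wrapper is installed with the package:

```sh
otukit=$(Rscript -e 'cat(system.file("exec","otukit",package="otukit"))')
Rscript $otukit preproc --input reads.fastq --qual 20 --minlen 200 \
        --output kept.fastq --stats stats.tsv
Rscript $otukit otu-denovo --input kept.fastq --threshold 0.97 \
        --reject 32 --derep full --out-dir out/
Rscript $otukit stats --otutable out/otutable.tsv \
        --indices shannon,simpson,invsimpson,chao1 --out diversity.tsv
Rscript $otukit evaluate --membership out/membership.tsv \
        --truth sim/truth.tsv --out metrics.tsv
```

Also available: `otu-ref` (best-hit reference assignment), `chimera`
(standalone calls), `simulate` (the 10 × 5000-read benchmark-style
preset), `align` (debug pairwise alignment).

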
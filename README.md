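# replitime

Replication-timing analysis for sorted S-phase fraction enrichment arrays:
from per-probe log2(BrdU-IP/input) ratios measured in early, mid and late
S-phase fractions on a tiling-probe grid, to smoothed replication profiles,
timing-class segments, initiation/termination zones, a replicon and
replication-domain map, and the probe-, replicon- and gene-level statistics
that relate replication time to GC content, gene and transposable-element
coverage, histone modifications (H3K4me1/2, H3K9me2, H3K56ac), DNA cytosine
methylation and gene expression.

The package is aimed at genomicists analysing Repli-chip-style data in
compact genomes, where replicons are on the order of 100 kb and euchromatin
replicates in the first half of S phase.  Because such legacy array data
are often unavailable, the package includes a first-class synthetic
chromosome simulator with full ground truth, so every stage of the pipeline
is validated by parameter recovery.

## The method in brief

Each probe carries per-fraction enrichment ratios.  The pipeline:

1. quantile-normalizes replicate arrays within each fraction and averages
   them (`smoothProfiles`), then loess-smooths each fraction profile in a
   fixed 150-kb genomic window (locally weighted quadratic, tricube
   weights);
2. calls per-fraction **enriched segments** — maximal runs of probes with
   smoothed ratio > 0 spanning at least 10 kb (`callSegments`) — and
   reconciles the three fractions into eight **timing classes**
   `E, EM, M, ML, L, EL, EML, I` by 3-bit membership (`reconcileSegments`);
3. detects **initiation and termination zones** as local extrema of
   50-kb-window profiles (maxima in early/mid are initiation, minima
   termination; roles flip in the late profile), widens each extremum to a
   10-kb zone and merges overlaps (`findExtrema`, `makeZones`);
4. selects **replicon boundaries** from the termination zones by a
   three-tier precedence (late zones corroborated in early *and* mid;
   remaining late-fraction zones; remaining early/mid minima in
   early/mid-enriched territory), assembles **replicons** between
   boundaries with plurality-class labels, and merges adjacent like-classed
   replicons into **replication domains** (`selectBoundaries`,
   `buildReplicons`, `clusterDomains`);
5. computes the statistics: one-sample t and exact doubled-tail binomial
   tests of features per timing class within a region
   (`probeClassTests`), Welch comparisons between replicon classes
   (`repliconCompare`), symmetric five-bin within-replicon feature
   profiles with Clopper-Pearson intervals (`binProfile`), and the
   per-gene epigenetic-pattern/timing/expression tables
   (`patternActivityTable`, `timingEnrichmentTable`, `activityByTiming`).

`runPipeline()` drives the whole chain from files on disk (probe TSV,
BED/GFF3 annotation, mark and expression TSVs) and writes BED/TSV results
plus a deterministic run manifest.

## Worked example

Simulate a 3-Mb chromosome with default study conditions and map its
replicons:

```r
library(replitime)
cfg <- simConfig(chromLength = 3e6, seed = 1)
sim <- simulateChromosome(cfg)
sim$truth
#> GroundTruth: 29 origins (18 active), 17 boundaries, 3000 probes, chrom 3000000 bp

prof  <- smoothProfiles(sim$repliSet)                   # 150-kb profiles
profZ <- smoothProfiles(sim$repliSet, window = 50000)   # zone detection
profileCorrelation(prof, c("early", "mid"))   #  0.48
profileCorrelation(prof, c("early", "late"))  # -0.84

fr <- setNames(nm = c("early", "mid", "late"))
segs <- lapply(fr, function(f) callSegments(prof, f))
seg <- reconcileSegments(segs$early, segs$mid, segs$late, probes(sim$repliSet))
table(S4Vectors::mcols(seg)$cls)
#>   E  EM   M  ML   L  EL EML   I
#>   4   8   8  13  10   0   0   0

zones <- lapply(fr, function(f) assignZoneTiming(makeZones(profZ, f), seg))
term <- lapply(zones, function(z) z[S4Vectors::mcols(z)$kind == "termination"])
init <- lapply(zones, function(z) z[S4Vectors::mcols(z)$kind == "initiation"])
bd <- selectBoundaries(term$early, term$mid, term$late, seg, initZones = init)
reps <- buildReplicons(bd, probes(sim$repliSet), seg)
doms <- clusterDomains(reps)
```

This run yields 19 boundaries defining 20 replicons (median 142 kb)
organised into 10 replication domains, and 15 of the 17 true boundaries
are recovered within 20 kb — matched boundaries land with sub-kilobase
precision; the misses are boundaries whose peak in the true
replication-time curve has near-zero prominence (an origin almost
overtaken by its neighbour's fork), which no smoothed-extremum method can
retain.  The origin-distance gradients built into the simulated chromatin
marks (H3K56ac declining away from origins, H3K9me2/5mC elevated in
late-firing territory) are recovered by `binProfile()` and
`repliconCompare()`, and gene activity is higher in early-replicating
classes, mirroring the biology the simulator encodes.

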
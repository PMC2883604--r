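---
title: "Mapping replication timing, replicons and chromatin features with replitime"
author: "replitime authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping replication timing, replicons and chromatin features with replitime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(replitime)
  library(GenomicRanges)
  library(S4Vectors)
})
```

## The measurement and the model

Replication-timing profiling by sorted-fraction BrdU immunoprecipitation
("Repli-chip") labels newly synthesised DNA, sorts nuclei into early, mid
and late S-phase gates, and hybridises the BrdU-enriched DNA of each gate
against total input DNA on a tiling array.  For every ~1-kb probe this
yields, per fraction and replicate, a log2(BrdU-IP/input) ratio: positive
where the locus tends to replicate during that gate, negative where it does
not.  Downstream of normalization, the analysis chain implemented here is:

1. **Profiles** — replicate averaging and loess smoothing of each
   fraction's ratios in a fixed genomic window.
2. **Segmentation** — per-fraction enriched segments (smoothed ratio > 0
   sustained over at least 10 kb), reconciled across fractions into eight
   timing classes: `E, EM, M, ML, L, EL, EML, I`.
3. **Zones** — local extrema of the smoothed profiles.  In the early and
   mid profiles, maxima are initiation zones and minima termination zones;
   the late profile flips the roles.  Each extremum becomes a 10-kb zone;
   overlapping zones merge.
4. **Replicon map** — replicon boundaries are chosen from the termination
   zones by precedence (below); replicons are the intervals between
   boundaries, classified by the plurality timing class of their probes,
   and adjacent like-classed replicons merge into replication domains.
5. **Feature statistics** — probe-level one-sample tests of GC, gene/TE
   coverage and binary chromatin marks per timing class within a region;
   Welch comparisons between replicon classes; symmetric five-bin
   within-replicon profiles of binary features with exact binomial
   confidence intervals.
6. **Gene analysis** — per-gene mark patterns (the fixed 16-pattern
   activity-ranked map), gene timing classes, and the association of both
   with expression (exact binomial and hypergeometric tests).

## Boundary precedence

Replicon boundaries are taken from termination zones in three tiers:

1. late-fraction termination zones corroborated by a termination zone in
   *both* the early and the mid profile within 20 kb (boundary at the
   center of the merged union);
2. remaining termination zones of late-fraction provenance;
3. remaining early/mid termination zones (profile minima) whose timing
   class carries early and/or mid enrichment.

Two supporting rules are applied.  First, a termination candidate is
vetoed when both other fractions identify an initiation zone at its
position: a site that two profiles call an origin region is not accepted
as a fork-convergence site on the word of the third.  Without this veto,
deep-early origin cores — where the mid profile genuinely dips — would be
split in half, inverting the within-replicon bin geometry.  Second,
boundaries closer than 20 kb are merged to their midpoint.

## The synthetic-chromosome generator

No public accession exists for the original array data, so validation is
by parameter recovery on simulated chromosomes whose generative model
follows the biphasic, stochastically firing origin picture the real data
support:

* origins placed by a gamma renewal process (shape 4, mean spacing
  107 kb — the replicon scale of the real chromosome);
* each origin assigned to an early or a late firing family (probability
  0.5), with a mean firing time uniform in `[0, 0.40]` (early) or
  `[0.55, 0.90]` (late) S-phase units;
* per-cell firing-time jitter, Normal with SD 0.20 S-units.  This value
  encodes the stochastic-activation picture: origin order within the first
  half of S phase varies from cell to cell (a ±2 SD spread covers roughly
  half of S phase).  A much smaller jitter would give every origin an
  essentially fixed firing time — a strict temporal program — which makes
  the three fraction profiles saturate into disjoint blocks and is not the
  regime the method was designed for;
* expected replication time
  `t(x) = min over origins o of clip(f_o + |x - o| / v, 0, 1)` with fork
  speed `v = 300` kb per S-phase unit.  Origins overtaken by a
  neighbour's fork are passively replicated and leave no boundary;
* closed-form labeling probabilities per sorting window (thirds of
  `[0, 1]` by default) from the Normal CDF of the claiming origin's jitter,
  with clipped mass assigned to the outer windows so the three
  probabilities sum to one;
* per-replicate ratios `1.5 * log2((p + 1e-6) / (1/3))` plus
  Normal(0, 0.3) array noise.  The `1e-6` floor keeps log ratios finite
  where a window's probability vanishes;
* chromatin-mark probabilities linear in the scaled origin distance `d`
  (H3K56ac declining away from origins; H3K9me2 and 5mC elevated in
  late-family replicons), genes placed with intensity rising toward
  termination zones of early replicons, TEs enriched in late replicons,
  and presence calls logistic in overlapping-probe H3K56ac/H3K9me2 with an
  overall activity rate near 60%.

The generator does **not** emulate FACS gate overlap or sorter
cross-contamination, immunoprecipitation efficiency, dye bias, probe
sequence effects (GC is drawn, not computed), or replicate correlation
structure.  The most consequential omission is gate overlap: in real
sorted fractions the early and mid gates capture overlapping cell
populations, which pushes the early-mid profile correlation toward the
very high values seen on real arrays and produces broad `EM` classes.
With mathematically disjoint sorting windows, a probe can carry
substantial labeling probability in two windows only when its expected
replication time falls within about one jitter SD of the window break, so
`EM`-classed territory is a band around origins whose firing time
straddles the break, not the bulk of euchromatin.  Passing recovery tests
therefore demonstrate correctness of the machinery on data with the
designed structure — they do not certify performance on real arrays.

## Scoring recovery

A run is scored on two quantities, computed by `scripts/acceptance.R` and
the end-to-end tests:

* **boundary recovery** — the fraction of true boundaries (local maxima of
  `t(x)`) with a called boundary within 20 kb.  Matched boundaries are
  located with sub-kilobase precision.  A small tail of true boundaries is
  intrinsically invisible: when a neighbour fires much earlier than an
  origin, the boundary collapses to within a few kb of the overtaken
  origin and its peak in `t(x)` has a prominence below ~0.05 S-units over
  a handful of probes, which no smoothed-extremum criterion can retain.
  This is why noise-free recovery plateaus below 100%.
* **family-class consistency** — `familyConsistentClasses()` maps the
  early family to `{E, EM, M}` and the late family to `{L, ML}`, and a
  replicon counts as consistent when its called plurality class is in its
  originating family's set.  Early-family origins with mean firing times
  near the top of the early window genuinely replicate their distal
  territory after the mid/late break; such replicons are called `ML` and
  score as inconsistent even though the call reflects the signal, which
  caps consistency below 100% by construction.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `window` | 150000 | bp | loess window for replication profiles, correlations and deciles |
| `zoneWindow` | 50000 | bp | loess window for extremum detection |
| `minLen` | 10000 | bp | minimum span of an enriched segment |
| `zoneWidth` | 10000 | bp | width of initiation/termination zones |
| `tol` | 20000 | bp | zone matching tolerance (Tier 1, reproducibility) |
| `minSep` | 20000 | bp | minimum boundary separation before midpoint merging |
| `nMin` | 20 | probes | smallest class reported in probe-level tests |
| `quartile` | 0.75 | — | AT-rich / gene-rich threshold (array-wide) |

Two windows are deliberate.  The 150-kb window is the classical choice for
chromosome-scale replication profiles and is used everywhere a profile is
reported or correlated.  For **extremum detection** it is mathematically
too wide at the ~107-kb replicon scale: a local quadratic fit over a
±75-kb span cannot represent two peaks one replicon apart, so ripples with
that period are annihilated and boundary recovery collapses to ~50% even
on noise-free data (verified directly: the raw noise-free profile contains
every boundary, the 150-kb smooth retains a fraction of them).  Zones are
therefore detected on a 50-kb-window profile — fine enough to resolve
structure at half the replicon scale while still averaging ~50 probes —
and both windows are exposed in the configuration.

## Numerical and statistical conventions

* Loess fits are degree-2 with tricube weights on `|x - x0| / (window/2)`,
  the classical loess defaults; windows with fewer than 8 probes fall back
  to the tricube-weighted mean.  The abscissa is scaled to the half-window
  inside the normal equations to keep them well-conditioned at genomic
  magnitudes.
* Quantile normalization (limma, ties averaged) is applied within each
  S-phase fraction across its replicate arrays, never between fractions:
  the three fractions are separate experiments and their ratio
  distributions are genuinely different.
* Probes with no replicate value in a fraction are filled by linear
  interpolation in genomic coordinate and flagged; more than 5% missing
  aborts.
* Plurality votes (zone class, replicon class, gene class) break ties by
  the fixed order `E, EM, M, ML, L, EL, EML, I`.
* Plateaus in extremum detection collapse to their midpoint probe, taking
  the left probe of even-length plateaus.
* Two-sided exact binomial p-values double the smaller tail and cap at 1
  (this differs from the likelihood-ordering rule of `binom.test`);
  binomial CIs are Clopper-Pearson; replicon comparisons use Welch's
  unequal-variance t-test (fractional degrees of freedom); pattern-class
  enrichment uses one-sided hypergeometric tests in both directions with
  the direction of the smaller p reported.  Significance codes are
  `* p<0.05, ** p<0.01, *** p<0.001` on raw p-values; a
  Benjamini-Hochberg column is provided for reference but does not drive
  the codes.
* Within-replicon bins pool probes across replicons by default (weighting
  long replicons more); per-replicon averaging is available
  (`mode = "perReplicon"`).
* Replicon ends: chromosome ends close the first and last replicon by
  default (`ends = "chromosome"`); `ends = "boundary"` restricts replicons
  to inter-boundary intervals.
* Gene mark calls are any-positive over overlapping probes by default
  (probe calls are themselves enrichment calls); a majority rule is
  available.  Genes with no overlapping probe or missing expression are
  excluded and counted.

## A worked run

```{r run, eval = FALSE}
cfg <- simConfig(chromLength = 3e6, seed = 1)
sim <- simulateChromosome(cfg)
ann <- simulateMarksGenes(cfg, sim$truth, sim$repliSet)

prof <- smoothProfiles(sim$repliSet)                   # 150-kb profiles
profZ <- smoothProfiles(sim$repliSet, window = 50000)  # zone detection
segs <- lapply(setNames(nm = c("early", "mid", "late")),
               function(f) callSegments(prof, f))
seg <- reconcileSegments(segs$early, segs$mid, segs$late,
                         probes(sim$repliSet))
zones <- lapply(setNames(nm = c("early", "mid", "late")), function(f)
  assignZoneTiming(makeZones(profZ, f), seg))
term <- lapply(zones, function(z) z[mcols(z)$kind == "termination"])
init <- lapply(zones, function(z) z[mcols(z)$kind == "initiation"])
bd <- selectBoundaries(term$early, term$mid, term$late, seg,
                       initZones = init)
reps <- buildReplicons(bd, probes(sim$repliSet), seg)
doms <- clusterDomains(reps)
```

Equivalently, `runPipeline(pipelineConfig(...), outdir)` executes the same
chain from files on disk and writes BED/TSV tables plus a manifest whose
bytes depend only on the inputs and configuration.

## Known limitations

* Per-chromosome processing only; no multi-chromosome joint modelling.
* The thresholding segmentation rule is the only one offered (no HMM or
  changepoint alternative), matching the method being reimplemented.
* Zones narrower than the probe spacing cannot be resolved; boundary
  candidates closer than `minSep` merge.
* Under the disjoint-window generative model, the mid profile dips both at
  deep-early origin cores and in deep-late territory, which caps the
  attainable early-mid profile correlation well below what overlapping
  FACS gates produce on real arrays.
* The statistics assume probes are exchangeable within classes; spatial
  autocorrelation from smoothing is not propagated into the tests, exactly
  as in the original analysis style this package mirrors.
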
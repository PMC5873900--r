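# peakclasses

Two-class characterization of a multi-subunit chromatin remodeler's
binding sites from ChIP-seq peak calls.

## The problem

A chromatin remodeling complex like human INO80-C consists of a catalytic
ATPase (INO80) scaffolding accessory subunits (RUVBL1, RUVBL2, MCRS1,
YY1).  Mapping each subunit separately by ChIP-seq reveals that the
ATPase's peaks split into two classes with opposite chromatin biology:

* **Canonical** sites — the ATPase peak is co-occupied by at least one
  accessory subunit peak; these sit in accessible, active chromatin
  (H3K27ac) near highly expressed genes.
* **Non-canonical (NC)** sites — the ATPase peak overlaps *no* accessory
  peak; these carry a repressive signature (H3K27me3, EZH2, inaccessible
  chromatin) and sit near lowly expressed genes.

`peakclasses` is for genomicists who have per-subunit peak calls
(narrowPeak/BED), optional signal tracks, a chromatin-state segmentation
and a gene expression table, and want this classification plus the
standard downstream characterization as one reproducible, tested
pipeline.

## The method

For ATPase peak set $A$ and accessory peak sets $S_1,\dots,S_k$ (each
blacklist-filtered, then recursively merged so that no two peaks within
500 bp of each other remain separate):

$$
\mathrm{NC} = \{a \in A : \forall i,\ \forall s \in S_i,\ |a \cap s| = 0\},
\qquad
\mathrm{Canonical} = A \setminus \mathrm{NC}
$$

with overlap counted as ≥ 1 shared base under 0-based half-open
coordinates.  Each class is then characterized by:

* **chromatin state** — per peak, the segmentation label with maximal
  base overlap (dominant state); reported as per-class fractions, raw or
  grouped into active/weak/repressive;
* **signal landscape** — 10 bp-binned coverage (fragments extended to
  150 bp from their 5′ ends), reference-point matrices around peak
  midpoints/summits, scaled metagene matrices over gene bodies, and
  column-mean metaplot profiles;
* **nearby gene expression** — each gene assigned to the class of its
  nearest peak by TSS-to-midpoint distance (ties/ambiguous genes
  excluded), classes compared by median/quartile abundance and the
  Wilcoxon rank-sum statistic.

A seeded generator (`simulate_study`) emits a complete miniature study —
genome, subunit narrowPeak files with planted canonical/NC structure and
realistic jitter/dropout noise, blacklist with decoy peaks, segmentation,
concordant fragment tracks, genes and class-conditional expression — so
the whole pipeline is validated end-to-end against known truth without
any downloads.

## Worked example

```r
library(peakclasses)

# a complete synthetic study: 200 canonical + 55 NC planted sites on
# 2 x 1 Mb, with boundary jitter (sd 50 bp) and 20% accessory dropout
sim <- simulate_study(sim_config(seed = 42), "demo")

# classify and characterize everything the study provides
cfg <- run_config_from_sim(sim, "demo/out")
report <- run_all(cfg)
print(report)
```

which prints (messages abridged):

```
filter_blacklist [atpase]: removed 10 of 265 peak(s)
...
classify_peaks: 200 canonical, 55 non-canonical (21.6% NC)
<run_report> peakclasses 0.1.0
  classes: 200 canonical, 55 non-canonical (21.6% NC)
  expression: median TPM 19.14 (canonical) vs 1.18 (NC), z = 10.66
```

Reading the numbers: the 10 decoy peaks planted inside blacklist regions
are removed from every subunit file; classification recovers exactly the
planted 55/255 = 21.6 % NC fraction despite jitter and dropout (any
single surviving accessory suffices under the any-overlap rule); and
genes nearest to NC peaks are expressed an order of magnitude lower than
genes nearest to canonical peaks, with a strongly positive standardized
rank-sum statistic.  `demo/out/` additionally contains `canonical.bed`,
`noncanonical.bed`, per-track class metaplot profiles, state-fraction
tables (the grouped table is `{canonical: active 1.0, NC: repressive
1.0}` on this synthetic landscape), the per-gene assignment and
`report.json` with every count above.

A thin CLI wraps the same functions:

```sh
exec/peakclasses simulate --seed 42 --out demo/
exec/peakclasses run-all --sim demo/ --out demo/out/
exec/peakclasses classify --atpase INO80.narrowPeak \
    --accessory RUVBL1=ruvbl1.narrowPeak --accessory YY1=yy1.narrowPeak \
    --chrom-sizes hg.chrom.sizes --blacklist blacklist.bed --out run1/
```

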
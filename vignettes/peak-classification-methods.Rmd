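---
title: "Methods: co-occupancy classification and chromatin characterization of remodeler binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occupancy classification and chromatin characterization of remodeler binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakclasses)
```

## The problem

Multi-subunit chromatin remodeling complexes such as INO80-C are scaffolded
by a catalytic ATPase (INO80) carrying accessory subunits (here RUVBL1,
RUVBL2, MCRS1 and YY1) that direct targeting and remodeling.  When each
subunit is mapped independently by ChIP-seq, the ATPase's binding sites
split into two biologically distinct classes:

* **Canonical** sites, where the ATPase peak is co-occupied — shares at
  least one base — with a peak of at least one mapped accessory subunit.
* **Non-canonical (NC)** sites, where the ATPase peak overlaps no peak of
  any accessory subunit.

The package implements this classification and the downstream
characterization used to show the two classes are real: chromatin-state
composition, signal metaplots (accessibility and histone-mark tracks), and
the expression of nearby genes.  Because the procedure is a chain of
deterministic interval operations, its correctness can be established
exhaustively on synthetic data with planted structure, which is what the
test suite does.

## Peak post-processing

Peak calls (narrowPeak/BED) are processed per subunit before
classification:

1. **Blacklist filtering.** Any peak sharing ≥ 1 base with a blacklist
   region is removed.  Overlap is computed under 0-based half-open
   semantics; `[100,200)` and `[199,250)` overlap, `[100,200)` and
   `[200,250)` do not.
2. **Recursive merging** (`recursive_merge`, default `max_gap = 500`).
   Two peaks on one chromosome are merged into their union when they
   overlap or their gap (`next.start − prev.end`) is at most `max_gap`
   bp; the rule is applied to a fixpoint, so chains of nearby peaks
   collapse even when the chain's endpoints are far apart.  "Within
   500 bp" is read **inclusively**: a gap of exactly 500 merges, 501 does
   not.  The threshold is a parameter.  Merged peaks keep the maximum
   member score (strongest evidence); names and summits are dropped,
   since a merged region has no single summit.  Merging is applied within
   each subunit's peak set only, never across subunits — classification
   must compare independently processed sets, and cross-set merging would
   leak co-occupancy information into peak geometry.

Classification itself (`classify_peaks`) labels each processed ATPase peak
canonical if it overlaps any accessory peak (any-base rule, no
minimum-fraction requirement; a `min_overlap` option exists but defaults
to 1 bp) and non-canonical otherwise.  The two classes always partition
the ATPase set, and adding an accessory set can only move peaks from
non-canonical to canonical — both properties are tested.

## Signal tracks and matrices

Coverage tracks are built from sequenced-fragment intervals on a fixed
10 bp grid: each fragment is extended to 150 bp (the approximate
nucleosome footprint) from its 5′ end in strand direction, and a bin's
value is the number of extended fragments overlapping it.  bedGraph text
tracks are also read, resampled onto the grid by length-weighted mean.

Two matrix layouts feed the metaplots and heatmap-style summaries:

* **Reference-point** (`reference_point_matrix`): one row per peak,
  anchored at the interval midpoint (default) or recorded summit with
  midpoint fallback; column *j* samples the bin covering
  `anchor − flank + j·binsize`.  Positions running off a chromosome
  contribute 0 and are counted in the matrix metadata, keeping rows
  rectangular.
* **Scaled-region metagene** (`scaled_region_matrix`): per gene, an
  unscaled upstream flank (default 1.5 kb), the gene body rescaled to
  `body_bins` bins (default 100; each bin is the length-weighted mean of
  the track over its real-valued fraction of the body), and an unscaled
  downstream flank (default 1 kb).  Minus-strand rows are flipped so
  every row reads TSS → TES.  A gene shorter than one bin gets a constant
  body equal to its whole-body mean and is flagged.

The default body resolution of 100 bins and the 1.5 kb metaplot flank are
conventional display choices; both are parameters.  No library-size
normalization is applied — the class comparisons are within-track, and a
scale factor can be applied externally when comparing real samples.

Every matrix computation is verified in the tests against an independent
per-base implementation (expand the track to one value per base, then
sample/integrate positions directly), including strand flips and edge
padding.

## Chromatin-state composition

A ChromHMM-style segmentation (labeled, non-overlapping BED intervals) is
intersected with each peak class.  Each peak receives its **dominant
state**: the label with the maximum overlapping base count.  Exact ties
are broken by the earlier label in the segmentation's declared label
order — a documented, deterministic rule; peaks with zero segmented
overlap are labeled `unsegmented`.  Whether published analyses counted
multi-state peaks fractionally or by a single assignment is generally not
stated; dominant-state assignment is the default here because it gives
one label per peak and makes the class fractions directly interpretable
as "fraction of peaks in state X".  Per-class fractions are reported per
state and, optionally, per state group through a user-supplied
state → group map (the synthetic segmentation ships a three-group
active / weak / repressive map).

## Nearest-peak gene assignment and expression

Genes are assigned to a peak class by linear distance from the gene TSS to
peak midpoints (distance 0 when the TSS lies inside a peak); the TSS is
the standard gene anchor for regulatory assignment, and a whole-gene-body
distance mode is deliberately left out of scope of the default path.  A
gene is labeled by the class of its nearest peak when that distance is at
most `max_distance` (default 1 Mb — effectively unbounded on the
synthetic genome, a real bound for genome-scale use).  Genes whose
nearest canonical and nearest non-canonical distances differ by at most
`ambiguity_window` (default 0: exact ties only) are labeled `AMBIGUOUS`
and excluded from the comparison, operationalizing the exclusion of genes
tied to both classes.  The comparison reports per-class n, median and
quartile abundances plus the two-sample Wilcoxon rank-sum statistic and
its tie-corrected normal standardization — reported descriptively, as the
class contrast is a distributional observation, not a hypothesis test
headline.

## The synthetic study generator

`simulate_study` writes a complete miniature study whose defaults are the
conditions the pipeline is validated under:

* genome: 2 chromosomes × 1 Mb;
* 200 canonical + 55 non-canonical sites (21.6 % NC, mirroring the ~4:1
  class ratio such classifications report), placed on a jittered grid
  with ≥ 3 kb spacing so post-processing cannot merge neighboring planted
  sites;
* site widths log-normal with median 300 bp (sdlog 0.3), a typical
  point-source ChIP-seq peak scale;
* per-subunit boundary jitter (Normal, sd 50 bp) and per-accessory site
  dropout (probability 0.2), modeling antibody-efficiency variation —
  the main realistic failure mode of co-occupancy classification;
* a blacklist of 10 inter-site regions, each seeded with one decoy peak
  per subunit so the filtering stage always has work to do;
* a segmentation placing each canonical site inside an active-state
  segment (states `Tss`/`Enh`) and each NC site inside a repressive one
  (`ReprPC`/`Het`), with `Quies` (weak) elsewhere; segments extend
  ±2.5 kb around the site so jittered peaks stay inside;
* three fragment tracks: ATPase-like signal at all sites, H3K27ac-like at
  canonical sites only, H3K27me3-like at NC sites only.  Fragment counts
  per site are Poisson (mean 100) with positions Normal(center,
  width/4), plus uniform background at 1e-4 fragments/bp — enough to
  produce peaked metaplots without modeling read-level artifacts;
* one gene per site with its TSS 300–800 bp from the site center, and
  log-normal expression with meanlog 3 (canonical-linked) vs 0.5
  (NC-linked), sdlog 1 — a strong but overlapping effect, so the
  recovered direction is a statistical, not mechanical, outcome.

Generation is a pure function of the config: the same seed gives
byte-identical directory trees, and the global RNG stream is restored
afterwards.

**What the simulation does not emulate:** read-level sampling noise,
mappability and GC artifacts, alt contigs, peak-caller behavior
(peaks are planted, not called), co-occupancy that varies by genomic
context, overlapping genes, and the long-tailed size distribution of real
ChromHMM segments.  Passing tests therefore demonstrate the correctness
of the interval algebra, the signal accounting and the recovery of
planted class structure under boundary noise and dropout — not robustness
to upstream data-generation artifacts, which enter before this pipeline's
inputs exist.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; the only conversion is to
  the 1-based closed convention of the IRanges machinery inside internal
  helpers.
* Sorting is total and deterministic: assembly chromosome order, then
  start, then end.
* narrowPeak summit `-1` maps to an absent summit; operations needing an
  anchor fall back to the interval midpoint `floor((start+end)/2)`.
* Empty blacklists and empty accessory overlaps are legal; an empty
  accessory *panel* is an error (classification undefined), as are empty
  region sets for matrix construction.
* Strict chromosome checking by default; `strict = FALSE` drops
  out-of-assembly records with a reported count (real ENCODE files carry
  alt contigs).
* The genomic-distribution summary assigns each peak midpoint to exactly
  one of promoter / gene body / distal with promoter priority and a
  strand-aware ±1 kb promoter window by default; published figures of
  this kind rarely enumerate their window, so it is a parameter.

## Problem sizes in the test suite

The oracle-equivalence tests run on 10 kb toy genomes with up to ~50
intervals per set, 1000 random instances per operation; recovery tests
run the full default study (2 Mb, 255 sites, 255 genes, 3 tracks) across
20 seeds.  These sizes give exhaustive per-base cross-checks and stable
recovery statistics while keeping the default `R CMD check`-style run in
minutes on one CPU.

## Known limitations

* Classification is binary per accessory evidence; it does not model
  partial complexes or quantify co-occupancy strength.
* Dominant-state assignment discards secondary states of wide peaks (a
  fractional mode is a natural extension).
* Gene assignment uses linear TSS distance; enhancer–promoter looping is
  out of scope.
* The NC fraction depends on which accessories were mapped: missing
  accessory data inflates it, which is exactly the dropout behavior the
  simulator stresses.
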
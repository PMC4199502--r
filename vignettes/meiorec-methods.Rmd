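---
title: "Calling and classifying meiotic recombination events from tetrad genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and classifying meiotic recombination events from tetrad genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiorec)
```

## The measurement problem

In a hybrid yeast cross the four spores of a single meiosis can be genotyped
at tens of thousands of biallelic SNPs, so every marker reports how the four
chromatids segregated: 2:2 is Mendelian, 3:1 (or 1:3) marks a
gene-conversion tract on one chromatid, 4:0 a conversion of both chromatids
of one homolog. Crossovers (COs) appear as reciprocal, persistent switches
of parental origin in two spores; noncrossovers (NCOs) as conversion tracts
without an arm exchange. The composition of these signatures — simple
versus tandem-discontinuous tracts, events confined to two chromatids
versus engaging three or four — discriminates between repair pathways:
synthesis-dependent strand annealing, biased versus unbiased resolution of
double Holliday junctions (dHJ), multiple strand invasion, and short-patch
mismatch repair.

`meiorec` implements the full chain from per-spore genotype calls to
pathway-level statistics: segregation profiling, tract and breakpoint
calling, proximity grouping into events, the E1–E7 event taxonomy,
discontinuity metrics, two null models (random NCO placement, the 1:2:1
chromatid ratio), the accompanying test battery, and a synthetic meiosis
generator with ground truth.

## Event calling

**Segregation classes.** Each marker is classified purely from its four
calls (`S22`, `S31`, `S13`, `S40`, `S04`, or `INCOMPLETE` when any call is
missing).

**Tracts.** A tract is a maximal run of same-direction non-2:2 markers with
a fixed converted-chromatid set. `INCOMPLETE` markers *bridge* a run but
never start or end one; missing data therefore cannot fabricate
discontinuities, which matter because tandem discontinuity is itself a
phenotype of interest. A run splits where the converted chromatid set or
the direction changes. Converted chromatids are identified against the
spore phases at the nearest fully typed 2:2 marker outside the run.

**Span conventions.** Marker data bound a tract only to within the flanking
inter-marker intervals, so three spans are reported: minimal (first to last
converted marker), maximal (out to the nearest non-converted markers) and
the midpoint convention (midpoints of the two flanking intervals). All
length statistics use the midpoint span: its boundary error is symmetric
around the true boundary, so tract-length medians are estimated without
systematic offset, while min and max spans are retained for sensitivity
checks.

**Crossovers.** Phase blocks are read over the fully typed 2:2 markers
only. This masks conversion tracts by construction (their markers are
non-2:2), so a tract can never be miscalled as two crossovers, and the
procedure is idempotent. A configuration change in which exactly two spores
swap parental origin yields a breakpoint bounded by the last old-phase and
first new-phase marker; any other change (e.g. four spores at once) is
flagged as a complex region and reported, never silently dropped. A
support threshold for short phase blocks is available
(`min_phase_markers`), with default 1: at ~200 bp marker resolution,
single-marker events are real observations.

Note that when several junctions interleave on one chromosome, the two
spores that visibly swap at a junction need not be the two chromatids that
physically exchanged — e.g. the proximal junction of a three-strand double
crossover surfaces as a switch between two centromere-sisters. The caller
reports what is observable; the taxonomy operates downstream of it.

**Sisterhood.** Centromeres segregate with their chromatid, so the two
spores sharing the parental allele at the fully typed 2:2 marker nearest
the centromere are sisters for that chromosome. Without a centromere
coordinate (or without any such marker) sisterhood is undefined and the
E5B2/E5B3 distinction is disabled for that chromosome.

## Grouping and the E1–E7 taxonomy

Tracts and breakpoints within 5 kb of each other (nearest-edge distance
between footprints; overlap counts as 0; the boundary is inclusive, and
both the distance convention and the cutoff are configurable) are merged
into one event by transitive closure. At a 0 kb cutoff only
overlapping/abutting members merge and the event count is maximal; it is
non-increasing in the cutoff.

Events are labelled by member composition and the number of chromatids in
the union of member chromatid sets:

| label | definition |
|---|---|
| E1 | one 3:1 tract, one chromatid, no breakpoint |
| E2 | one breakpoint, conversion (if any) contiguous with its interval |
| E3 | one breakpoint plus ≥ 1 conversion on a crossover chromatid separated by 2:2 markers |
| E4 | ≥ 2 tandem tracts on one chromatid, no breakpoint |
| E5 | ≥ 2 units on exactly two chromatids (subtyped below) |
| E6 / E7 | members engaging three / four chromatids |

Anything outside the table is labelled `unclassified` with a full dump,
never silently binned. A 4:0 tract occupies two chromatids (needed for
chromatid counting) and, alone, is an E5B2-type signature (both converted
chromatids are sisters).

**E5 subtypes.** E5A is the signature of unbiased dHJ resolution. Two
observational forms are recognised, because marker resolution dictates two
appearances of the same molecular event. When the segment between the two
junctions carries informative markers, the two complementary conversions
restore 2:2 with swapped phase and the event is seen as an *apparent double
crossover*: exactly two reciprocal breakpoints between the same two
non-sister chromatids. When the overlap carries no informative marker, the
event is seen as two overlapping, opposite-direction NCO tracts on
non-sister chromatids. Both forms classify as E5A (the
opposite-direction requirement is configurable). E5B1 is two non-sister
NCOs without overlap, E5B2 NCOs confined to a sister pair, and E5B3
everything else on two chromatids (triple crossovers, CO–NCO mixtures,
or any E5 whose chromosome lacks defined sisterhood).

**Discontinuity components.** For tandem events the package reports the
whole-event length (footprint span), individual tract lengths (midpoint
spans) and the 2:2 gap lengths between consecutive same-chromatid tracts.
These three components separate the multiple-invasion phenotype (long
events, wild-type-sized tracts) from the short-patch-repair phenotype
(wild-type-sized events, short tracts and gaps).

## Null models

**Random NCO placement.** Per tetrad, the observed NCO events are replaced
by the same number of NCOs placed uniformly per bp (chromosome chosen
proportional to length), each on a uniformly chosen chromatid, keeping the
observed footprint-length multiset (permuted without replacement; a
point-NCO variant exists) while crossover-containing events stay fixed.
Adjacent-event distances are recomputed per replicate in four categories
(NCO–NCO and CO–NCO, same versus different chromatid; "same" means the
chromatid sets intersect). Uniform placement is deliberately the minimal
null: no DSB hotspots and no interference, so a rejection is evidence of
*spatial structure*, not a fitted model of it.

Two significance summaries are provided. The Wilcoxon rank-sum test of
observed against pooled simulated distances matches the test family used
for the length comparisons; the permutation form ranks the observed
category median among the replicate medians. Only the permutation form is
exactly calibrated, because spacings within one genome are mutually
dependent — and even it requires the observed layout to follow the null
sampling scheme exactly: when observed events come through the caller,
footprint discretisation and cutoff-merging of overlapping tracts make the
test conservative by a few percent (measured ~2–3% rejection at nominal
5%). The package's calibration check therefore draws observed layouts from
the null model itself, which is the appropriate type-I-error measurement
for a Monte-Carlo test, while the power check runs fully end-to-end on
clustered (mms4-like) cohorts. Replicate counts: an empirical two-sided p
from R replicates can only reject at 5% if `min(p_lo, p_hi) ≤ 0.025`, i.e.
R = 199 is the smallest count at which the 5% level is achievable; with
R = 99 the nearest achievable level is 4%.

**1:2:1 chromatid ratio.** Two independent crossovers without chromatid
interference choose chromatids uniformly (16 equally likely pairings),
giving exactly 4:8:4 events on two, three and four chromatids. The package
provides the enumeration, a Monte-Carlo sampler with binomial intervals,
and a chi-square goodness-of-fit for an observed triple — the yardstick for
deciding whether closely spaced apparent double crossovers are independent
events or one event.

**Double-NCO configurations.** For two independent DSBs within 5 kb, each
repaired as an NCO on a uniform chromatid, the package computes the
expected proportions of (A) overlapping non-sister, (B) non-overlapping
non-sister and (C) sister-chromatid configurations. Same-chromatid
pairings (4/16) would not be seen as a double NCO and are discarded;
conditional on distinct chromatids, sister pairs are 1/3. An excess of
configuration A over this generative null is the quantitative argument
that overlapping NCO pairs derive from unbiased resolution of a single
intermediate rather than from two DSBs.

## The synthetic generator

The generator is the package's stand-in for sequenced tetrads and defines
the conditions under which the pipeline is validated. Defaults, with the
reasoning:

* genome: the 16 S. cerevisiae chromosome lengths with approximate
  centromere midpoints (a 2-chromosome `test_genome()` keeps unit tests
  fast); ~60,000 markers, near-uniform spacing with ±25% jitter — the
  density of a typical hybrid cross (~200 bp resolution).
* counts per meiosis: Poisson, mean 90 CO-destined DSBs (the standard
  genome-wide crossover count for such hybrids) and mean 39 NCOs
  (wild type); 52 in mms4 mode, where multi-tract chains bring the
  tract-level count near the ~100-per-tetrad scale seen before grouping.
* tract lengths: gamma parameterised by median (simple NCO 1.8 kb,
  CO-associated conversion 2.0 kb, shape 2). Only medians and quartiles
  are reported for real data; a gamma gives positively skewed, strictly
  positive lengths of the observed shape.
* mms4 mode: a DSB becomes a chain of `min(2 + Geom(0.5), 11)` tracts with
  gamma gaps (median 1.0 kb). The observed range of tract counts is 2–11;
  a uniform count on 2–11 is incompatible with the ~5.4 kb median event
  span that accompanies it (it would predict ~20 kb), so the count
  distribution is the skewed family that reproduces both the range and the
  span median, with wild-type-sized member tracts.
* msh2 mode: 10% of NCOs are repaired as converted patches (median 0.5 kb)
  separated by restored gaps (median 0.3 kb) inside an envelope drawn from
  the normal NCO length distribution, ending on a patch at both ends.
* sgs1 mode: 15% of CO-destined intermediates resolve without bias (the
  E5A pair: a shared converted core on one chromatid of each homolog with
  short private extensions), 10% engage a third chromatid, and 15% of NCOs
  come from a short 0–500 bp subpopulation.
* missing calls: 0.5% of calls, injected last; intersister repair
  (genotype-invisible) can be generated to verify the pipeline's blindness
  to it.

Crossovers exchange the arm distal to the centromere and junctions are
composed distal-to-proximal, which is the strand-tracing order; conversion
tracts ride the exchanged strands, so a crossover-associated tract
surfaces on a spore of the observable exchange pair. Ground truth records
every DSB with intended tract intervals and an observability flag: a tract
spanning no marker, or a breakpoint with no residual two-spore difference
between its flanking clean 2:2 markers (close same-pair double crossovers
cancel; a chromosome-end conversion can consume a flank), is flagged
undetectable but still emitted.

**What the generator does not emulate.** DSB hotspots and crossover
interference (positions are uniform per bp), genotyping error beyond
missing calls, aneuploidy, segmental variation between the parents, and
marker-free genome regions longer than the jittered grid produces. Passing
recovery tests therefore demonstrates correctness of the calling and
classification logic under realistic densities — not robustness to every
artefact of real sequencing data.

**Ascertainment, quantified by the truth records.** Detection conditions
induce biases that the tests account for explicitly: a 0.3 kb gap is only
seen if a marker falls inside it, so *detected* discontinuous patchy
events have longer envelopes than patchy events at large (the package's
msh2 comparison therefore measures truth-matched whole-event spans, giving
the patchy and simple populations the same ascertainment); an NCO within
5 kb of a crossover is absorbed into that event and no longer counted as a
standalone NCO event (~5–10% at wild-type densities), so NCO recovery is
measured by truth matching rather than by event counts; and measured gap
lengths are upward-biased relative to the generative gap median for the
same reason short gaps go unseen.

## Problem sizes

The shipped test-and-verification suite runs, per check: the exhaustive
classifier sweep (~40,000 configurations of ≤ 3 members over 4 chromatids);
100 random layouts of up to 200 tracts against the transitive-closure
oracle; 10,000 Monte-Carlo double crossovers against 1:2:1; 100 wild-type
full-genome tetrads for parameter recovery; 50-tetrad mms4 and msh2
cohorts for the discontinuity contrast; 500 calibration runs and a
5-tetrad clustered cohort for the spacing test; and 50 random fixtures
plus 1000 resampled nulls for the statistics battery. The
`scripts/acceptance.R` report uses 40 wild-type and 25 tetrads per mutant
mode. These sizes were chosen so each check's sampling error is well
inside the asserted tolerance.

## Known limitations

* Sisterhood inference fails only when conversion spans the
  centromere-proximal markers; affected chromosomes fall back to E5B3 with
  a flag rather than guessing.
* The E2/E3 contiguity rule uses midpoint footprints; at very sparse
  marker spacing a contiguous conversion can be misread as separated (and
  vice versa) within one inter-marker interval.
* Complex regions (non-reciprocal multi-spore phase changes) are reported
  but not decomposed; the paper-level analyses treat them as unresolvable
  at marker resolution.
* The Wilcoxon form of the spacing test inherits the dependence-induced
  conservatism discussed above; use the permutation form when calibrated
  error rates matter.
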
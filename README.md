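# meiorec

Genome-wide analysis of meiotic recombination from four-spore tetrad SNP
genotypes, for researchers mapping crossovers (COs) and noncrossovers
(NCOs) in hybrid yeast crosses (or any system where the four products of
one meiosis are genotyped at dense biallelic markers).

In such data every marker reports the segregation of the four chromatids:
2:2 is Mendelian; 3:1/1:3 marks a gene-conversion tract on one chromatid;
4:0/0:4 a two-chromatid conversion. A crossover is a reciprocal, persistent
phase switch between two spores; a noncrossover is a conversion tract
without an arm exchange. `meiorec` turns per-spore parental-origin calls
into:

* **tracts and breakpoints** — maximal same-direction non-2:2 runs (missing
  calls bridge, never split) and reciprocal two-spore phase switches read
  over fully typed 2:2 markers (so conversion tracts are masked by
  construction); tract lengths are reported under min / midpoint / max span
  conventions, with statistics on the midpoint span;
* **events** — tracts and breakpoints within 5 kb (nearest-edge, inclusive,
  configurable) merged by transitive closure;
* **the E1–E7 taxonomy** — simple NCO (E1), simple CO (E2), CO with
  discontinuous conversion (E3), discontinuous NCO (E4), two-chromatid
  multi-unit events (E5, subtyped E5A / E5B1 / E5B2 / E5B3 using inferred
  sister-chromatid pairing), and three- / four-chromatid events (E6 / E7).
  E5A — the signature of unbiased double-Holliday-junction resolution — is
  recognised both as an apparent double crossover (two reciprocal
  breakpoints between one non-sister pair) and as overlapping
  opposite-direction NCO tracts;
* **discontinuity components** — whole-event length, member tract lengths
  and 2:2 gap lengths, the quantities that separate multiple-invasion from
  short-patch-repair phenotypes;
* **null models** — random NCO placement over the fixed CO map with
  Wilcoxon or permutation significance, the exact 1:2:1 (4:8:4) chromatid
  ratio for apparent double crossovers with Monte-Carlo and chi-square
  goodness-of-fit, and the configuration null for close NCO pairs;
* **the test battery** — Welch t, Wilcoxon rank-sum, Kolmogorov–Smirnov and
  the z-test of proportions, two-sided and uncorrected;
* **a synthetic meiosis generator** — wild-type and mutant-like modes
  (`mms4` tandem multi-invasion chains, `sgs1` unbiased-resolution and
  multichromatid signatures plus short NCOs, `msh2` short-patch repair)
  over an S. cerevisiae-scaled 16-chromosome genome with ~60,000 jittered
  markers, emitting ground truth with observability flags for recovery
  testing.

## Worked example

```r
library(meiorec)

p   <- sim_params(genome = test_genome(), n_markers = 4000,
                  co_mean = 6, nco_mean = 5)
sim <- simulate_meiosis(p, seed = 1)
sim$tetrad
#> tetrad_genotypes 'tetrad1': 4 spores x 4000 markers (86 missing calls)

ev <- call_recombination(sim$tetrad)
ev
#> recomb_events (tetrad 'tetrad1')
#>   10 events from 10 tracts and 7 breakpoints (cutoff 5000 bp)
#> class
#> E1 E2
#>  3  7

summary(ev)[, c("total", "n_co_events", "n_nco_events", "minority_prop",
                "median_simple_nco", "median_gc_co")]
#>   total n_co_events n_nco_events minority_prop median_simple_nco median_gc_co
#> 1    10           7            3             0            2393.5         2591
```

Ten events were called: seven simple crossovers (E2) and three simple
noncrossovers (E1); no minority (E4–E7) events, as expected at this low
event density. The medians are midpoint-convention spans in bp — with only
3 and 7 tracts they sit above the generating 1.8 / 2.0 kb medians purely by
sampling noise (cohort-scale runs recover them; see below).

The chromatid-interference null:

```r
chromatid_ratio_null(10000, seed = 1)$proportions
#>     2     3     4
#> 0.251 0.500 0.249
```

matching the exact 4:8:4 enumeration (`chromatid_ratio_enumeration()`),
i.e. the 1:2:1 expectation for apparent double crossovers on two, three
and four chromatids when crossovers do not interfere at the chromatid
level.

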
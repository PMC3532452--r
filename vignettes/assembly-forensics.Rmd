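---
title: "Reference-free assembly forensics with Feature Response Curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free assembly forensics with Feature Response Curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frcurve)
```

## The problem

A de novo assembly can look excellent by contiguity statistics (NG50, contig
count) while being riddled with mis-joins, collapsed repeats, inversions and
chimeric sequence. When no finished reference exists, the only independent
witnesses of assembly correctness are the sequencing reads themselves:
if the assembly is right, read pairs aligned back to it should land at the
expected distance, in the expected relative orientation, on the same contig,
at an even depth. `frcurve` turns violations of these expectations into
typed, located *features* ("suspicious regions") and summarises the
contiguity-correctness trade-off as a Feature Response Curve (FRCurve).

Two library types carry complementary signal. A paired-end (PE) library
(innie orientation, inserts of a few hundred bp) localises small-scale
problems: coverage anomalies and local mis-joins. A mate-pair (MP) library
(outie orientation, inserts of several kb) sees long-range structure:
scaffolding errors, large indels, inversions. Accordingly, 9 feature types
are computed from PE alignments (`LOW_COV_PE`, `HIGH_COV_PE`,
`LOW_NORM_COV_PE`, `HIGH_NORM_COV_PE`, `COMPR_PE`, `STRECH_PE`,
`HIGH_SINGLE_PE`, `HIGH_SPAN_PE`, `HIGH_OUTIE_PE`) and 5 from MP alignments
(`COMPR_MP`, `STRECH_MP`, `HIGH_SINGLE_MP`, `HIGH_SPAN_MP`, `HIGH_OUTIE_MP`).

## The evidence model

Every mapped read with an expected mate is assigned exactly one class:

* **PROPER** — mate on the same contig, pair in the library orientation,
  fragment length within $\mu \pm k\sigma$ (default $k = 3$);
* **OUTIE** — mis-oriented, or at an aberrant distance;
* **SINGLETON** — mate unmapped;
* **SPANNING** — mate on a different contig.

From these, each contig accumulates per-position tracks: vertical read
coverage $C(p)$, proper-pair coverage, spanning (horizontal) coverage
$S(p)$ — the number of whole fragments covering $p$ — and per-class anomaly
counts. Fragment length is defined as the outermost-coordinate span of the
two mates (standard TLEN semantics), counted once per pair from its
leftmost mate.

### The CE statistic

Compression/expansion events are detected with a z-like score. For the $n$
proper fragments spanning a locus, with local mean length $m$,

$$Z = \frac{m - \mu}{\sigma / \sqrt{n}},$$

where $\mu, \sigma$ are the library's insert mean and standard deviation
(refined from the observed proper fragments at run time). Strongly negative
$Z$ means the assembly is locally *shorter* than the sequenced genome
(a collapse), strongly positive $Z$ means it is locally *longer* (a stretch
or insertion).

One numerical subtlety matters in the detector. Fragments are sampled by
the condition "span the window midpoint", which is a length-biased draw:
the chance of spanning a point is proportional to fragment length, so the
null mean of the sample is the size-biased mean
$\mu^* = \mu + \sigma^2/\mu$, not $\mu$. The shift looks tiny (30 bp for a
3000 ± 300 bp MP library) but enters $Z$ multiplied by $\sqrt{n}$; with
hundreds of spanning fragments per window it would push the null by one to
two standard deviations and flood the output with spurious stretch calls.
`detect_ce_features()` therefore centres windows at $\mu^*$
(`size_bias_correction = TRUE`), while `ce_statistic()` itself keeps the
plain definition, which is what a user applies to an explicit fragment
sample. Note a consequence of classification-before-CE: an indel larger
than $k\sigma$ of a library's insert makes the spanning pairs OUTIE
("too distant"), removing them from the CE sample — very large events are
therefore seen by `HIGH_OUTIE_*`, coverage features and `LOW_COV`, not by
CE, whereas events within $k\sigma$ are CE territory.

### Windows and region granularity

Windowed statistics (CE and anomaly fractions) use sliding windows of
1000 bp at a 200 bp step (both configurable). A flagged window contributes
its central step-wide tile (200 bp) to the feature region, not the whole
window: overlapping windows tile the contig at step resolution, so a real
multi-window signal still produces one contiguous region, while a single
noise window marks only 200 bp. Under the default $|Z| > 3$ thresholds the
expected per-window null flag rate is $2\Phi(-3) \approx 0.27\%$ per
library, and the tile attribution keeps the expected spuriously flagged
fraction of a clean assembly well under 1%. Because adjacent windows share
most of their spanning fragments, CE noise is correlated: when a spurious
excursion does occur it tends to flag a few consecutive windows at once, so
the clean-run flagged fraction is lumpy around its (small) expectation from
seed to seed.

Windows with no spanning fragments yield the no-data sentinel (`NA`), never
$Z = 0$: absence of evidence is not evidence of perfect insert sizes, and
such windows are skipped (they can still trigger coverage features).

### Thresholds

All detector constants live in `thresholds()` and are deliberate tool
parameters, not biological constants:

| parameter | default | meaning |
|---|---|---|
| `cov_low_frac` | 1/3 | low coverage below this fraction of the library mean |
| `cov_high_frac` | 3 | high coverage above this multiple of the mean |
| `ce_low`, `ce_high` | −3, +3 | CE flags outside this Z interval |
| `anomaly_frac` | 0.4 | window mean anomaly-read fraction to flag |
| `min_region` | 200 bp | merged regions shorter than this are dropped |
| `merge_gap` | 200 bp | same-type regions closer than this merge |

Coverage thresholds are multiplicative on the library's own mean, which
makes them robust to the (typically large) coverage difference between PE
and MP libraries. Degenerate inputs are defined away: a refined insert sd
of 0 (identical fragments) is floored at 1 bp; an empty alignment is an
error, not a silent zero.

## The Feature Response Curve

Contigs are sorted by length, longest first (ties broken lexicographically
by contig id so that output is deterministic). For a feature threshold
$\tau$, the longest prefix of contigs whose cumulative feature count is at
most $\tau$ is selected, and the curve point is the approximate genome
coverage $\min(1, \text{selected length} / G)$ with $G$ the user-supplied
genome size — the only reference-free reading of "genome coverage". The
comparison is *inclusive* ($\le \tau$): $\tau = 0$ then reads naturally as
"coverage achievable with zero-feature contigs", and the curve reaches its
plateau $\min(1, \Sigma L / G)$ exactly at $\tau$ equal to the total
feature count. A feature, for counting purposes, is one merged region, not
one base. Per-type curves restrict the count to a single feature type;
since a per-type count can never exceed the total, each per-type curve
dominates the global curve pointwise. Chaff contigs (< 200 bp) are *not*
excluded from the curve by default; `assembly_summary()` reports them
separately as a percentage of $G$.

## Validation against a truth set

`sensitivity_specificity()` scores calls per *position*, over all assembled
bases: TP are truth positions covered by at least one feature, FP flagged
positions outside truth, and so on; the four counts always sum to the
assembly length. A `slack` parameter dilates truth intervals before
counting, because breakpoint evidence from read pairs physically flanks a
junction rather than covering it: an inversion breakpoint is revealed by
mis-oriented pairs whose reads sit up to one fragment length away. In the
bundled benchmark the slack is one MP insert mean (3000 bp), the resolution
of the longest-range instrument, while the simulator's truth ledger marks
junction-type events with a flank of one PE insert mean (300 bp), the
resolution of the tighter instrument. Undefined ratios (empty truth, or
features covering everything) are reported as `NA` rather than a
misleading 0 or 1.

## The synthetic benchmark

The generator exists so that every detector can be tested hermetically,
with known ground truth and no downloads:

1. `generate_reference()` — i.i.d. bases at a chosen GC, with optional
   planted exact repeat families;
2. `apply_misassembly_events()` — typed corruptions (inversion, relocation,
   tandem-repeat collapse, expansion, chimeric insertion, deletion,
   fragmentation) producing contigs, a truth ledger and a liftover map;
3. `simulate_pairs()` — Gaussian fragments (truncated at twice the read
   length), uniform starts, innie PE / outie MP orientation, optional
   uniform substitution errors;
4. `liftover_alignments()` — reads are placed at their *true* assembly
   coordinates through the liftover map; reads in deleted sequence become
   unmapped, reads inside inversions flip strand, reads from a collapsed
   repeat copy pile onto the kept copy, and reads overhanging a breakpoint
   by more than 20 bp (configurable) are unmapped while smaller overhangs
   are soft-clipped.

Replacing a real aligner with exact liftover is a deliberate design choice:
tests become exact and deterministic, and every mis-placed read is
attributable to the simulated event rather than to aligner heuristics. The
price is realism: no mapping ambiguity in repeats, no aligner-specific
proper-pair flags, no quality scores, no PCR duplicates, no indel errors.
Passing the bundled benchmark therefore demonstrates that the detectors
respond correctly to the geometry of each event class under clean mapping;
it does not certify behaviour under heavy multi-mapping, which is a known
limitation of alignment-based forensics in repeat-rich genomes (a MAPQ
floor is exposed for exactly that case).

The standard study conditions are a 100 kb genome, PE at 80× (300 ± 30 bp,
100 bp reads) and MP at 20× (3000 ± 300 bp), with two ≥ 2 kb inversions, a
2 kb relocation, a contig fragmentation, a 500 bp tandem-repeat collapse
and a 1 kb chimeric insertion (`benchmark_events()`). These sizes keep a
full end-to-end run in a few seconds while leaving each event several
fragment lengths of clean flanking sequence. Substitution errors are left
at 0 in the standard configuration: liftover placement is exact regardless
of base errors, so they would add runtime without changing any coordinate.
Expected detector responses, asserted by the test suite:

| event | primary evidence |
|---|---|
| inversion | `HIGH_OUTIE_*` over the body and breakpoints |
| relocation | `HIGH_OUTIE_*` (distance) at all three junctions |
| repeat collapse | `COMPR_MP` at the junction (PE pairs invert and become OUTIE) |
| chimeric insertion | `LOW_COV_PE` over the unsequenced body, `STRECH_*` flanks |
| fragmentation | `HIGH_SPAN_*` toward both new contig ends |
| deletion | singletons from removed sequence, `COMPR_*` at the junction |

Contig ends deserve a note: spanning coverage necessarily decays within one
insert length of an end, and the spanning-fragment sample there is
conditioned on fitting inside the contig, which biases local fragment means
slightly downward. The event-free false-positive control therefore excludes
positions within one MP insert mean of a contig end; real scaffold-end
artefacts look the same in real data.

## Determinism and seeds

Every stochastic stage takes an explicit seed; `run_benchmark()` derives
per-stage seeds from one master seed, and two runs with the same seed
produce byte-identical FASTA, GFF3, curve and report files. GFF3 output is
1-based inclusive (internal coordinates are 0-based half-open throughout);
the conversion is exercised by round-trip tests on random intervals.

## Worked example

```{r example, eval = FALSE}
library(frcurve)
bench <- run_benchmark(seed = 1)
bench
#> <frc_benchmark> synthetic benchmark (seed 1 )
#>   events: 9 truth intervals; slack 3000 bp
#>   sensitivity: 0.754  specificity: 0.988  flagged(non-edge): 0.0132
#> <frc_eval> reference-free assembly evaluation
#>   contigs: 2  NG50: 50500 bp  chaff: 0.00%  (G = 100000 bp)
#>   features: 21 regions over 8 types
plot(bench)
```

For user data the entry point is `frc_evaluate()` on an assembly FASTA plus
coordinate-sorted BAM files (SAM is accepted for small inputs), or the
bundled command line script `inst/cli/frc.R` with subcommands `evaluate`,
`simulate`, `frc` and `validate`.

## Known limitations

* Multi-mapping reads: with the default MAPQ floor of 0 a random placement
  among repeat copies dilutes, and can hide, repeat-related features.
* Features are interval evidence, not breakpoint calls: region boundaries
  are window-quantised (step resolution) and flank junctions by up to one
  insert length.
* CE detection is blind to indels larger than $k\sigma$ of the library
  insert (the informative pairs leave the PROPER class); those events are
  instead caught by `HIGH_OUTIE_*`/`LOW_COV_PE`.
* The simulator does not model aligner behaviour, base qualities, PCR
  duplicates or structural error co-occurrence; conclusions about real
  data should be validated on real alignments.
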
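---
title: "lampcall: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lampcall: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lampcall)
```

## The measurement problem

A LAMP reaction amplifies a short genomic target with six design sequences
(F3, F2, F1, B1, B2, B3) and strand-displacing polymerase; the product is a
ladder of concatemers — tandem, alternating-orientation copies of the core
unit — plus, when the assay misbehaves, spurious concatenates of primer
sequence with no target at all. Sequenced on a nanopore device, a single
read may hold several independent observations of the hotspot base, or
none, and a conventional mapper's primary-alignment view of such a read
discards most of that structure. `lampcall` treats the read as a string in
a concatemer grammar: find candidate target copies, validate their flanks,
extract each copy, and vote.

## Pipeline model

**Seeding.** Every query (the target seed plus each design sequence, both
strands) is aligned to the read with affine-gap local alignment. Hits
require identity ≥ `min_identity` (default **0.70**, the conventional
seeding threshold for error-prone long reads) *and* query coverage ≥
`min_query_cov` (default **0.80**). Identity counts gap columns in the
denominator — the stricter convention; without the coverage floor,
micro-alignments of a few bases can clear a pure identity filter, which is
also why the floor exists at all (the shortest design sequences are
~16 bp). Multiple copies are found by best-hit-then-mask iteration; masked
spans are replaced by a sentinel that cannot be realigned through.

**Scoring.** Match +2, mismatch −4, gap open −4, gap extend −2 (a gap of
length $L$ costs $4 + 2L$). These are the long-read mapper defaults in the
surrounding ecosystem; nothing downstream is sensitive to the absolute
scale, only to the mismatch/gap trade-off. The aligner is compiled (Rcpp),
exact (full DP, no heuristics), and is checked in the test-suite against
an independent brute-force R implementation.

**Target seed.** The seed is `target_ref[target_span]`; by default the
span is the region strictly between the F1 and B1 sites extended by 5 bp
each side. The hotspot must lie inside it. A short seed maximizes the
chance that every concatemer unit contains a complete copy; the ±5 bp
extension anchors the seed's ends inside flanking design sites so that an
exact unit produces a seed hit at identity 1. The span is overridable in
the assay file for assays whose hotspot sits elsewhere between the inner
sites.

**Chaining.** A concatemer adjacency grammar is generated from the unit
structure (forward unit `F2 F1 TARGET B1 B2` in reference orientation, its
reverse complement, inverted-repeat junctions `B2+B2−` / `F2−F2+`, loop
tokens inside junctions, outer primers only at read ends) and closed under
reverse-complement symmetry of the whole read. From each target hit,
extension proceeds to the nearest neighbouring hit on each side, subject
to a gap tolerance of ≤ 25 bp of unexplained sequence and an overlap
tolerance of ≤ 5 bp (local alignments of abutting sites can overlap
slightly; the seed itself overlaps F1/B1 by construction). Extension stops
at the first grammar violation, at another target hit, or at the read end
— greedy bidirectional extension per target, not global chaining, which
matches the per-copy semantics needed here. Flanking hits between two
target copies may be shared by both sub-reads; the target hits themselves
are never shared.

**Consensus calling.** Each extracted (target-forward) sub-read is aligned
to the amplicon reference and accepted when identity ≥ 0.70 over ≥ 50
columns — thresholds chosen to mirror the seeding threshold and exclude
micro-alignments; both configurable. The hotspot call is *allele-aware*:
the sub-read is re-scored against the wildtype reference and against each
declared mutant haplotype, and a strictly better-scoring allele wins.
Without this, a mutant-carrying sub-read pays a guaranteed mismatch at the
hotspot, so a sequencing error near the locus makes the aligner route
around it (placing a gap over the hotspot) more often for mutant than for
wildtype reads — classic reference bias, which measurably deflates VAF in
simulation. When the allele scores tie (base is neither allele, deleted,
or uncovered) the call is read off both edit paths and kept only if they
agree; disagreement (e.g. an inserted base mimicking one allele) is
ambiguous evidence and becomes NOCALL rather than being resolved toward
the reference. Deletions spanning the hotspot are reported as DEL: they
count toward the pileup but not toward SNV support. One read contributes
one consensus call — plurality over its sub-read calls, ties broken
uniformly at random from the session RNG (the pipeline seed is recorded in
the run report) — because sub-reads of one molecule are copies, not
independent observations. Votes are unweighted; base qualities are not
used (the simulator emits flat qualities, and weighting is an open
extension).

**Classification.** Precedence: `SHORT → ONT → TARGET → FRAGMENT →
SPURIOUS → BACKGROUND → UNKNOWN`. Length (< 60 bp) and adapter checks are
cheap and unambiguous, so they run first; TARGET must outrank SPURIOUS
because genuine target reads also contain many design hits. Decisions the
heuristics needed but the field leaves unstated, with defaults:

| parameter | default | meaning |
|---|---|---|
| `short_len` | 60 bp | below this, SHORT |
| `ont_min_identity`, `ont_min_cov` | 0.80, 0.50 | adapter match identity; fraction of the read an adapter hit must cover (adapters come from configuration, never hard-coded) |
| `fragment_min_columns` | 60 | whole-read-to-amplicon alignment columns before a target-less read counts as FRAGMENT (below this, one stray design hit would qualify) |
| `spurious_min_hits` | 3 | design hits ("many seeds") required for SPURIOUS |
| `bg_min_identity`, `bg_min_cov` | 0.80, 0.60 | background-genome match identity and read coverage |

The background test uses the package's own aligner with exact k-mer
seeding (13-mers sampled across the read, offset-clustered, windowed
alignment) rather than an external mapper with a MAPQ filter: grading and
tests must run self-contained, and MAPQ is mapper-specific. The same
seed-and-extend primary alignment backs `classify_amplicon`, the
alignment-position classifier used for plain PCR amplicon runs and as the
comparison baseline for the concatemer-advantage check. When no background
genome is supplied the BACKGROUND test is skipped and such reads degrade
to UNKNOWN.

## Diagnostics

Support is mutant + wildtype consensus calls; other bases, DEL and NOCALL
are tallied but never counted as support. VAF = n_mut / support with a
two-sided population-proportion interval: Wald by default (the
conventional textbook interval), Wilson available because Wald degenerates
at k ≈ 0 — relevant for negative controls, where residual VAFs sit well
under 1%. Timeline positions come from the FASTQ `start_time=` field
(ISO-8601 MinKNOW convention or plain seconds), reported relative to the
earliest read of the run; `time_to_support(timeline, 250)` is the
headline time-to-result statistic, 250× being the conventional support
target for confidently separating a ≥ 10% tissue VAF from a ~1% sequencer
error floor. `detection_power(depth, vaf, error, threshold)` makes that
trade-off exact with binomial tails; the default decision threshold of
0.05 is the midpoint between the error floor and the minimal VAF of
interest on the log scale, and is overridable.

## Sequencer performance model

Useful calls arrive at rate
$\textit{active pores} \times \textit{participation}(t) \times
\textit{rate per pore} \times (1-\textit{barcode loss}) \times
\textit{target fraction} \times \textit{call yield}$,
with participation ramping linearly from `ramp_start` × steady (default
0.3) to steady over `ramp_duration` (default 120 s), reflecting the low
pore participation typical of a flow cell's first minutes. The ramp
integral is inverted in closed form. `optimal_amplification` interpolates
a characterization sweep (amount vs target fraction) linearly, adds
amplification time and fixed overhead, and minimizes total time on a dense
grid — the full curve is returned, not just the argmin, because the
asymmetry matters: on an increasing-concave fraction curve,
over-amplifying costs less than under-amplifying, so a protocol should sit
at or slightly past the optimum. This transparent rate-product form is a
deliberate reconstruction: every factor is observable and configurable,
and it is validated against simulation rather than against any published
fitted parameters.

## The simulator's stated world

`simulate_run` draws reads from a class mixture (defaults: 45% target,
10% fragment, 15% spurious, 15% background, 5% each adapter/short/random),
with:

* concatemer unit counts `1 + Geom(p = 0.45)` truncated at 8 (mean ≈ 2.2
  units) — the true unit-length distribution of LAMP product is not
  quantified beyond gel ladders, so this is a documented stand-in;
* per-base substitution/insertion/deletion rates 3%/2%/2%, an R9.4.1-like
  aggregate of 7%;
* target reads mutant with probability `true_vaf` (default 0.554, a
  realistic heterozygous-tumour operating point);
* Poisson arrivals (default 10 reads/s) encoded as ISO-8601 `start_time=`;
* spurious reads as random-order, random-orientation concatenations of
  3–8 design sequences; background reads as 100–1000 bp slices of a
  bundled synthetic 100 kb contig; adapter reads from a synthetic 70-mer;
* optionally, `chimera_frac` of target reads made *imbalanced*: a long
  background section joined to a short single-unit target section — the
  read shape that defeats primary-alignment classification and motivates
  concatemer awareness.

The bundled example assay lays real-style primer sequences end-to-end with
a synthetic 31 bp spacer; the amplicon is therefore synthetic (zero
spacing between design sites), which is cosmetically unlike a real
amplicon but structurally identical for everything downstream. The
hotspot's synthetic context has non-degenerate neighbours (`G·A·G`):
placing the variant inside a homopolymer makes single-deletion gap
placement genuinely ambiguous at the locus — a real failure mode that
assay designers avoid and that the simulator therefore avoids too.

What the simulator does **not** emulate: signal-level error structure
(homopolymer-length errors, strand-specific bias, quality correlation),
cauliflower-branched concatemer topology, chimeric ligation artefacts
other than the stated two-part chimeras, or barcode cross-talk. A green
end-to-end test therefore establishes algorithmic correctness on the
stated structural model of LAMP product, not basecaller realism.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; only VCF output is
  1-based.
* Plurality ties consume one RNG draw; batch mode sorts reads by start
  time before processing, so a follow-mode run over the same files in the
  same order reproduces the batch report exactly (verified in tests; at
  zero error there are no ties at all).
* Empty pileups, empty FASTQ inputs and zero-support runs produce NOCALL
  reports, never errors; malformed or truncated FASTQ records are skipped
  with counted warnings.
* `sample()`-style range draws in the simulator use a length-safe helper
  (R's `sample(n, 1)` scalar expansion is a classic off-by-a-mile trap).
* Loop primers are seeded by default (`include_loops = TRUE`) but carry no
  special weight; assays without them simply have no loop tokens in the
  grammar. Whether the original heuristics seed loop primers is unknown;
  this is our explicit choice.

## Known limitations

* Per-query best-hit-then-mask seeding is exhaustive DP per read; adequate
  to a few kb and a handful of queries, not for genome-scale seeding.
* The identity filter alone cannot distinguish a true design-sequence hit
  from a paralogous micro-hit on random sequence for the shortest queries;
  the coverage floor mitigates but does not abolish this (the test-suite
  bounds the spurious-hit rate on random DNA rather than asserting zero).
* BACKGROUND classification is a coverage/identity criterion, not a
  mapper's MAPQ; reads from repetitive genomic regions would be accepted
  more liberally than a MAPQ ≥ 20 filter would allow.
* The sequencer model treats pores as exchangeable and the target fraction
  as time-invariant within a run; flow-cell degradation across re-uses is
  out of scope.
* Single-hotspot diagnostics only: no multi-locus joint calling, no
  quality-weighted votes, no methylation awareness.
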
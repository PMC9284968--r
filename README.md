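# lampcall

Concatemer-aware analysis of LAMP amplicons sequenced on nanopore devices,
for ultra-rapid (intraoperative-scale) hotspot variant diagnostics.

## The problem

Loop-mediated isothermal amplification (LAMP) amplifies a target in
minutes, but its product is concatemeric: each sequenced molecule carries
multiple tandem, alternating-orientation copies of the amplified unit,
interleaved with primer-derived sequence. Standard read mappers pick one
"primary" alignment per read, so a read whose longest section does not
cover the locus of interest is thrown away even when a shorter section
carries a perfectly good copy of the hotspot — and LAMP assays also
mis-prime, producing spurious primer concatenates that look like signal
unless decomposed. `lampcall` recovers that information and turns a
basecalled FASTQ stream into a hotspot diagnosis in near real time.

## What it does

For a LAMP assay defined by its design sequences (F3, F2, F1, B1, B2, B3,
optional loop primers), an amplicon reference, and a hotspot position:

1. **Seed** — locally align the target seed and every design sequence to
   each read, both strands (affine Smith–Waterman, match +2 / mismatch −4 /
   gap open −4 / extend −2); spans with identity ≥ 70% covering ≥ 80% of
   the query are hits.
2. **Chain** — from each target hit, walk left and right through
   neighbouring hits, validating the expected design-sequence order with a
   concatemer adjacency grammar, to cut out one sub-read per target copy.
3. **Call** — align each extracted sub-read back to the amplicon reference
   and read the hotspot allele off the edit path, allele-aware (the
   sub-read is re-scored against each allele haplotype to avoid reference
   bias); the per-read pileup of sub-read calls is resolved by plurality,
   ties broken at random under a recorded seed.
4. **Classify** — every read gets exactly one class:
   `SHORT → ONT → TARGET → FRAGMENT → SPURIOUS → BACKGROUND → UNKNOWN`.
5. **Report** — mutant allele fraction VAF = n_mut / (n_mut + n_wt) with a
   population-proportion confidence interval (Wald, Wilson optional),
   support-over-time from the FASTQ `start_time=` metadata, and
   time-to-N× support.

Two companion models make the protocol tunable end to end: exact binomial
sensitivity/specificity for a depth/VAF/error operating point
(`detection_power`; at 250× support, a 10% VAF against a 1% error floor
gives ≥ 99% of each), and a sequencer-performance model
(`sequencer_model`, `sequencing_time`, `optimal_amplification`) that picks
the amplification time minimizing total time-to-result from a
characterization sweep. A labelled read simulator (`simulate_run`)
generates every class of read under an ONT-like error model so the whole
pipeline is testable at desk scale with no external data.

## Worked example

```r
library(lampcall)
assay <- example_assay()          # bundled synthetic K27M-style assay
assay
#> LAMP assay 'h3f3a_k27m_synthetic': 149 bp reference, hotspot 76 (A>T), seed 41 bp
#>   F3  GTTTGGTAGTTGCATATGGTG
#>   ...

cfg <- simulation_config(assay, n_reads = 500, true_vaf = 0.554, rng_seed = 42)
fq  <- tempfile(fileext = ".fastq")
sim <- simulate_run(cfg, fastq = fq)   # FASTQ with start_time= metadata

report <- run_pipeline(assay, fq, background_fasta = cfg$background,
                       ont_sequences = cfg$adapter,
                       config = lamp_config(support_target = 150), seed = 1)
report$class_counts
#>     TARGET   FRAGMENT   SPURIOUS BACKGROUND        ONT      SHORT    UNKNOWN
#>        227         51         78         76         24         19         25
```

which prints, for this seed:

```
VAF 53.33% (95% CI 46.81-59.85%), support 225x
time to 150x support: 34.2 s of sequencing
```

The library was simulated at a true VAF of 55.4% with 7% aggregate
per-base error; the reported VAF sits inside its own confidence interval
of the truth, and the class counts recover the simulated mixture. The
support timeline (`report$timeline`) is what a real-time run would show
accumulating.

### Command line

```sh
lampcall simulate --assay assay.txt --n 2000 --vaf 0.554 --fastq sim.fastq
lampcall classify --assay assay.txt --fastq sim.fastq --out results/
lampcall watch    --assay assay.txt --fastq incoming_dir/ --out results/
lampcall model    --curve sweep.tsv --pores 1200 --rate 0.05 --out model/
lampcall amplicon --fastq sim.fastq --reference genome.fa \
                  --amplicon 10000-10149 --hotspot 10076
```

(the `lampcall` script is installed under the package's `exec/`
directory; equivalently `Rscript -e 'lampcall::lamp_cli()' --args ...`).

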
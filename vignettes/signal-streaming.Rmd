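---
title: "Signal-file streaming and basecall dispatch: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-file streaming and basecall dispatch: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slow5pipe)
```

## What this package models

Nanopore basecalling workflows have two performance-relevant layers that are
independent of the neural network doing the calling: **how raw-signal
records are fetched from disk**, and **how reads are marshalled between the
file reader and the basecaller**. `slow5pipe` implements both layers
concretely enough to be measured: a flat, appendable record format with
sequential streaming and indexed random access; and an in-process
server/client dispatch loop with a bounded queue. A deterministic mock
basecaller and a matched signal simulator close the loop, so the package's
claims are testable as parameter-recovery experiments rather than
assertions about hardware.

## The data model

A file is a `run_header` followed by `signal_read` records.

* `run_header`: number of read groups (sets of reads sharing acquisition
  metadata), one ordered attribute map per group, an auxiliary-field schema
  (`name`, one of `int`/`double`/`string`) shared by all records, and two
  codec choices for the binary dialect.
* `signal_read`: an identifier; the calibration quartet `digitisation`
  (ADC quantisation levels), `offset` (ADC offset), `range` (pA span) and
  `sampling_rate` (Hz); the 16-bit integer sample vector; and aux values
  conforming to the schema. Picoamp conversion is
  `pA = (raw + offset) * range / digitisation`, which is affine in the raw
  samples — a property the tests exercise directly.

Constructors enforce the invariants (positive calibration scalars, 16-bit
sample range, identifier shape, schema conformance), and the binary
deserializer re-checks them when parsing, so a file cannot smuggle an
invalid object into memory.

## The two dialects

The ASCII dialect is a `#`-prefixed header followed by one TSV row per read
with the signal as comma-separated integers: greppable and diffable, used
for inspection and tests. The binary dialect frames each record as
`[length][payload]` after a magic/versioned header; payloads are compressed
whole (`zlib` by default, `zstd` or `none` selectable) and the signal inside
is delta–zigzag–varint coded by default. Zigzag interleaving
(0, −1, 1, −2 → 0, 1, 2, 3) makes the small deltas typical of pore signal
one-byte varints. Both writers are byte-deterministic for identical inputs —
no timestamps, stable attribute order — so reproducibility can be asserted
with file digests.

Design choices worth recording:

* **Random access is defined for the binary dialect only.** The index maps
  `read_id` to `(byte offset, record length)` and is persisted as a text
  side-car (`<file>.idx`) carrying a fingerprint (data-file size plus
  leading bytes); a mismatch — e.g. after an append — makes the loader
  refuse the index rather than silently serve stale offsets. ASCII files
  are sequential-only.
* **Appends never rewrite existing bytes**, and duplicate read ids are a
  hard error at write and append time, because index keys must be unique.
* **Truncation is detected positionally**: a short length prefix or payload
  reports the last good offset, so a damaged file can be triaged.

## Sequential streaming and why it is fast

`stream_batches()` consumes the file in a single forward pass, reading
large blocks (1 MiB) and slicing records out in memory; `slow5_batchsize`
records at a time are handed to up to `slow5_threads` forked workers for
decompression and parsing. Two contracts are testable and tested:

* **Thread invisibility** — the flattened output is identical for every
  (batch size, worker count) combination; parallelism is observable only as
  speed.
* **Single pass** — instrumented counters show at most the file size in
  bytes read and zero seeks, whereas random access performs exactly one
  seek per record.

Record parsing itself is compiled (C++), as in the C libraries this layer
is modelled on; at tens of thousands of records per second the parse loop,
not the arithmetic, is the hot path.

## The dispatch pipeline

`run_pipeline()` implements the five-step wrapper workflow: start server,
connect client, stream batches, submit, collect and write. The server is
realized in-process with an explicit bounded queue rather than a TCP
service — the transport is incidental to the algorithmic contract, and an
in-process queue makes the capacity invariant (`pending + in_flight <=
max_queued_reads`) directly instrumentable; the returned summary reports
the peak observed load. Submission happens in chunks of `guppy_batchsize`
(which must not exceed the queue capacity) and blocks while the queue is
full, which in-process means dispatching queued work until there is room.
`procs` collection workers split each dispatched batch; results keep
submission order, and `sorted = TRUE` canonicalizes output by read id since
an asynchronous server makes no ordering promise in general.

A backend is any pure function from a list of reads to one result per
read. Purity is what makes two runs comparable; the bundled mock backend is
deterministic by construction.

## The mock model and simulator

The simulator and mock basecaller share a `mock_model`: per-base current
levels (defaults A=80, C=100, G=120, T=140 pA), fixed dwell `D` (10
samples/base), Gaussian noise (sd 2 pA), calibration constants
(digitisation 8192, range 1402.882 pA, offset 10, sampling 4 kHz — plausible
nanopore-era values fixed for reproducibility), and a seed. Sequences are
uniform over A/C/G/T; each base emits `D` noisy samples at its level,
inverted to raw ADC units, rounded and clipped.

The mock basecaller takes the median of each dwell window and picks the
nearest level; ties break to the lexicographically smaller base. Per-base
quality is `min(40, max(2, round(margin)))` with `margin` the pA gap between
the two nearest levels — so the default 20 pA level spacing yields q≈20
calls. The read-level mean qscore is the phred of the mean per-base error
probability (the production-basecaller convention; it is monotone in the
read's expected error rate, unlike the arithmetic mean of q).

With sd 2 pA noise, the median of 10 samples has standard deviation about
`2 * 1.253 / sqrt(10) ≈ 0.79` pA; a miscall needs the median to stray more
than 10 pA, a ~13-sigma event, so per-base error is far below 1e-3 and the
observed identity on 50,000 simulated bases is expected (and observed) to
be 100% at the default settings, and exactly 100% analytically at zero
noise. This is deliberately simpler than a real pore — no k-mer context, no
dwell-time variation, no adapter/stall artefacts, no homopolymer
compression — so passing recovery tests demonstrates that the plumbing is
lossless and the dispatch correct, *not* that the mock generalizes to real
signal.

## Output formats and splitting

FASTQ is the standard 4-line record with phred+33 qualities; unaligned SAM
uses flag 4 with `RNAME`/`POS`/`CIGAR` unset and carries the mean qscore
twice: `qs:i` (rounded half-up) and `mq:f` (full precision), so a split can
be reproduced from either representation. Qualities outside the encodable
0–93 range are clamped with a logged count. The pass boundary is inclusive
(`mean qscore >= threshold` passes), matching the common q≥7 convention.
The standalone splitter routes records byte-identically; for SAM it trusts
the stored tag by default (recomputation is a flag), and always recomputes
when no tag is present.

## FAST5 interop

Only the multi-read HDF5 layout is read (one `read_<id>` group holding
`Raw/Signal` plus calibration attributes on `channel_id`); the single-read
legacy layout is out of scope. A read missing its signal or a calibration
attribute yields a per-read error while the rest of the file is still
served — degraded containers are common enough that all-or-nothing parsing
would be hostile. Conversion to BLOW5 assigns one read group per input file
and is byte-deterministic; header attributes not representable in the aux
schema are dropped, the tested contract being the lossless core (signal +
calibration). HDF5 access goes through the Bioconductor `rhdf5` bindings.

## Benchmarks: asserting mechanism, not wall clock

Published speed-ups for sequential signal access are hardware- and
filesystem-dependent; a test suite cannot assert them. What it can assert
is the mechanism: both access modes decode identical record multisets, the
random path performs exactly `n` seeks while the sequential path performs
none, and — direction only, on the host running the tests — sequential
throughput is at least random throughput. Timed comparisons warm both code
paths first so R's first-call byte-compilation does not skew them. Cache
clearing (which needs root) is replaced by instrumented logical I/O
counters, which are cache-independent. `bench_parallel()` runs `k`
identical jobs on `k` independent file copies (avoiding shared-cache
artefacts) and reports the contention ratio `job_time(k)/job_time(1)`;
ratios are reported, never asserted.

## Problem sizes and numerical choices

The shipped checks use 1,000 reads for round-trip fidelity across all
twelve dialect/codec combinations, 10,000 reads for exhaustive
index-vs-sequential agreement, 50,000 reads for the access-pattern
benchmark, and 100 reads × 500 bases for pipeline recovery — sizes at which
every property is exercised at full fidelity while a complete run stays in
the minutes range on one CPU. Half-up rounding is used for the integer SAM
qscore tag (so splitting reproduces identically from either tag); base R
`round()` is used for mock quality margins, where half-integer margins have
measure zero under continuous noise. Ties in level assignment are broken
lexicographically to keep the mock a pure function.

## Known limitations

* The ASCII dialect has no random-access index.
* The mock basecaller is a windowed nearest-level classifier; it is not a
  model of real pore chemistry and its qualities are geometric margins, not
  calibrated error probabilities.
* FAST5 writing exists only to build test fixtures (uncompressed,
  multi-read layout); VBZ-compressed third-party FAST5 is not supported.
* The in-process server measures queue discipline, not network transport
  effects.
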
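---
title: "Promoter-level pre-processing: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-level pre-processing: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maraprep)
```

Motif activity response analysis (MARA) models a promoter-by-sample matrix
of expression or chromatin signal in terms of predicted regulatory sites.
`maraprep` produces that matrix locally from raw data, so that only a
few-MB summary file travels to the analysis server. This vignette explains
the models behind each pipeline, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where the problem was genuinely open.

## Coordinate and annotation conventions

All coordinates are 0-based half-open, the BED convention; this removes
every ±1 ambiguity, and "overlap" always means a shared ≥ 1 bp interval.
A promoter's anchor is `floor((start + end) / 2)` of its annotation
interval — the center on which ChIP-seq windows are placed. Annotation is
user-supplied (promoter BED, one-exon-per-row transcript TSV, and a
transcript→promoter association TSV): server-internal promoterome tables
are not redistributable, so the package defines open formats and ships a
generator for synthetic ones. Within a transcript, abutting exons are
merged and overlapping exons rejected, because overlap would double-count
the transcript length used for RPKM. A transcript may associate with only
one promoter; with no principled weighting scheme available for
multi-promoter transcripts, ambiguity is treated as an annotation error
rather than silently resolved.

## Alignment ingestion

BED and BAM inputs reduce to the same sorted interval representation.
From BAM, unmapped, secondary and supplementary records are excluded —
and excluded from `total_reads`, which is the normalization denominator,
so its definition must be exact — while duplicates are kept and paired
mates count as two independent reads (the tool cannot know the library's
duplication or pairing semantics, so it applies the least surprising
deterministic rule and documents it). Each record contributes its
reference-consumed span (CIGAR-aware), so a spliced read is represented
by its full genomic extent. "Indexing" is an in-memory per-chromosome
slice table over the sorted reads; no on-disk index is produced because
nothing downstream needs one. Chromosome names are compared as exact
strings in C-locale order; a warning fires when annotation and alignment
chromosome sets are disjoint, the classic silent-zero-counts failure.

## ChIP-seq: promoter-window counting

For window width $w$ (default 2000 bp, must be even) and anchor $a$, the
window is $[\max(0, a - w/2),\; a + w/2)$. A read increments every window
it overlaps by at least 1 bp — the most inclusive deterministic reading;
midpoint and 5′-end modes are available (`mode = "midpoint"`,
`"five_prime"`) for users who prefer point assignment, but any-overlap is
the tested default. Strand is ignored: ChIP fragments are strand-symmetric
around binding sites. Counts become
$\log_2(n \cdot 10^6 / N + c)$ — counts-per-million with pseudocount
$c = 0.5$. CPM is the minimal depth normalization and makes the
scale-invariance property (doubling counts and library leaves output
unchanged) exactly testable; the pseudocount fixes the zero-count value at
$\log_2 c$ and keeps reruns byte-identical.

## RNA-seq: exon-overlap assignment and promoter pooling

Inputs are already genome-aligned, so "mapping to the transcript set"
means exon-overlap assignment, not re-alignment. A read compatible with
$k \ge 1$ transcripts (≥ 1 bp exon overlap, same chromosome) contributes
$1/k$ to each: deterministic and mass-conserving — the summed fractional
counts equal the number of assigned reads to within accumulated floating
error, a property the tests assert at $10^{-9}$. No EM rescue is
attempted; with promoters, not isoforms, as the output unit, the 1/k
split is almost always within-promoter and EM would add nondeterminism
for little gain. Strandedness is configurable
(`stranded = none|forward|reverse`) and off by default, since the tool
cannot know the library protocol.

Transcript counts are normalized as RPKM
($n_t \cdot 10^9 / (L_t N)$; TPM available via `norm = "tpm"`) and
*summed* over each promoter's transcripts: a promoter's value represents
total transcription initiation at that site, so summation, not averaging,
is the physically meaningful pooling (averaging would halve the signal of
a promoter that happens to have two annotated isoforms). The reported
value is $\log_2(E_p + c)$, $c = 0.5$.

## Microarray: the normal+exponential chain

Input is an open tab-delimited probe-intensity table; proprietary binary
scanner formats and chip-definition files are out of scope. Per sample,
intensities follow $X = S + B$ with signal $S \sim \mathrm{Exp}(\theta)$
and background $B \sim N(\mu, \sigma^2)$.

*Estimation.* $\hat\mu$ is the mode of a kernel-smoothed density,
located in two passes: a first pass over all intensities, then a second
over the sub-mode portion only. The second pass matters because the
default bandwidth scales with the overall standard deviation, which the
long signal tail inflates; a single pass oversmooths the background peak
and drags the mode tens of units into the signal. $\hat\sigma$ is the RMS
deviation of intensities below $\hat\mu$ (the left flank is essentially
pure background), and $\hat\theta$ the mean excess above $\hat\mu$. On
generator output (20% pure-background probes, $\mu = 100$, $\sigma = 15$,
$\theta = 200$, 50,000 probes) all three recover within 10%. Constant
input is an estimation error, not a silent zero.

*Correction.* Each intensity is replaced by the posterior mean
$E[S \mid X = x] = a + \sigma\,\varphi(a/\sigma)/\Phi(a/\sigma)$ with
$a = x - \mu - \sigma^2/\theta$. The Gaussian ratio is evaluated as
$\exp(\log\varphi - \log\Phi)$, which is stable far below the background
mean where $\Phi$ underflows; the tests pin the result to numerical
quadrature of the posterior at $10^{-6}$ relative error, and it is
strictly increasing and strictly positive by construction.

*Non-specific binding.* After correction, a per-sample floor — the 5%
quantile of the corrected intensities — is subtracted, clamped below at
$\varepsilon = 1$ so the later $\log_2$ is defined and non-negative. This
quantile floor is a deliberately minimal, clearly-labeled stand-in: real
NSB models use probe sequence or mismatch probes, which require chip
metadata this tool does not ingest. It is monotone and order-preserving
within a sample, which is all the downstream steps rely on.

*Expression filter.* A probe counts as expressed in a sample when its
corrected (pre-floor) intensity exceeds $\hat\mu + 2\hat\sigma$; probes
expressed in zero samples are removed ("consistently non-expressed" —
one sample is enough to keep a probe). On planted labels the filter
removes ~100% of pure-background probes and ~6% of signal probes at the
default settings.

*Quantile normalization.* The classic rank-mean procedure: sort each
column, average across columns at each rank, map entries back by rank.
Ties within a column receive the mean of the rank-means they span. Two
consequences are worth stating: on tie-free data every column ends with
the identical multiset of values and a second application is a no-op
(both are tested invariants); on tied data the tie-averaging necessarily
perturbs the common multiset — this matches the behavior of the standard
implementations and is covered by a dedicated tie test rather than the
multiset invariant.

## The summary dialect

The upload payload is deliberately boring: optional `#key=value` metadata
lines with sorted keys, an `id`-led header, one row per feature, values
printed with exactly 6 significant digits (trailing zeros kept, `.`
separator, `\n` endings), written atomically via temp-file-and-rename.
Fixing the dialect down to the byte is what makes the concurrency and
rerun contracts testable as bitwise file equality; 6 significant digits
bounds round-trip error at 10⁻⁵ relative while keeping a 5,000 × 6 matrix
near 200 kB. Output size is $\Theta(\text{rows} \times \text{samples})$,
independent of read depth — the entire size-reduction mechanism.

## Jobs, concurrency and the submission contract

A job walks `created → processing → processed → uploading → submitted`,
with `failed` reachable from any working state. One extra edge,
`failed → uploading`, exists so a failed *submission* can be retried
without reprocessing; it is permitted only when the processed summary
file still exists, which keeps the "download URL non-empty iff submitted"
invariant intact. The store is a single TSV, one record per line,
rewritten atomically on every transition — inspectable with standard
tools, crash-safe (a torn trailing line is ignored on reload), and free
of database dependencies. Summaries, logs and temporaries live under a
relocatable scratch directory so large intermediate data can sit on an
external drive.

Per-input processing is dispatched with fork-based parallelism; results
are combined in input order, so the summary is byte-identical for any
worker count — asserted by the tests as file equality between 1 and 4
workers.

Submission is a multipart POST of the summary plus `data_type`,
`assembly`, `project`, `email` to `<server>/submit`; a 200 response whose
plain-text body contains a URL marks the job `submitted` and stores the
URL. The live protocol of any real server being undocumented, the package
defines this minimal contract and ships `mock_mara_server()`, an
in-process object implementing it exactly — tests run fully offline, and
the same `submit_job()` code path speaks real HTTP (via curl) when given
a URL string. Email validation is syntactic only (contains `@`, may be
empty): the address is merely forwarded for notification.

## What the synthetic generator does and does not emulate

The generator exists so every pipeline is testable with planted truth and
no downloads. It emulates: Poisson read counts proportional to
`rate × length` (RNA-seq) or `rate` (ChIP-seq), positional spread of ChIP
fragments (Normal, SD 200 bp, so a 2 kb window captures essentially all
of a promoter's reads), exonic placement of RNA-seq reads, and the
exponential-plus-Gaussian intensity model with a planted
pure-background fraction. Defaults: promoters every 10 kb on a synthetic
chromosome `chrS1` (a deliberately unreal name, to catch accidental
reliance on real chromosome naming), 1–3 exons per transcript with span
≤ 8 kb, lognormal(0, 1) promoter rates, 50 bp reads, and microarray
parameters $\mu = 100$, $\sigma = 15$, $\theta = 200$, 20% background
probes, 10,000 probes × 4 samples.

It does **not** emulate sequence content, mapping error, duplication
artifacts, GC or fragment-length biases, overlapping genes, spliced-read
junction spans, or batch effects. Passing tests therefore demonstrate
that the *computations* are correct and deterministic under the stated
models — not that the defaults are optimal for any particular real
dataset, where annotation quality and library artifacts dominate.

All generators are pure functions of `(spec, seed)`: identical inputs
yield byte-identical files, which the suite asserts literally.

## Problem sizes and numerical choices

Tests and the acceptance script run at sizes chosen to exercise the
asymptotics while staying quick on one core: the size-reduction check
uses 3 × 10⁶ ChIP-seq reads over 5,000 promoters (reduction factor ≈ 765,
comfortably inside the hundreds-to-thousand range the mechanism implies);
counting is verified exactly against a brute-force all-pairs oracle on
200 random instances up to 5,000 reads × 300 windows; rate recovery uses
10⁵ reads over 100 promoters (Spearman ≈ 0.998); background recovery uses
50,000 probes. Sorting uses radix order on C-locale strings for
determinism across platforms; window clamping at the chromosome start is
the only place a window can be shorter than `w`; all error conditions are
classed conditions (`maraprep_parse_error`, `maraprep_config_error`, …)
so callers and the CLI can map them to exit codes (0/2/3/4).

## Known limitations

Promoter-level output only (no gene- or isoform-level summaries); no
fragment-length extension or input subtraction for ChIP-seq; no EM for
multi-mapping RNA-seq reads; microarray rows are probes, not probesets —
probe→promoter mapping is left to the server side; the NSB floor is a
placeholder for a sequence-aware model; and the submission contract is
self-defined, not verified against any production service.
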
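---
title: "Methods: codecs, indexes and design choices in airdlite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codecs, indexes and design choices in airdlite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

airdlite stores mass-spectrometry runs as a two-file container — a JSON
metadata document plus a binary block file — built for computation rather
than archival: controllable precision, block indexes shaped by the
acquisition mode, and codecs that exploit what MS arrays actually look
like. This vignette explains the methods and the choices behind them.

## The m/z codec (ZDPD)

A centroided spectrum's m/z array has three properties the codec leans
on: values lie between 0 and roughly 3000 Da, the array is sorted, and
peaks arrive in clusters whose members differ by very little. The
pipeline is

1. **Fixed-point quantization.** `q = round(mz * 10^dp)`, half away from
   zero. `dp` is the single precision knob (1–6). The worst-case error
   is `0.5 * 10^-dp` Da, i.e. relative to a 100 Da mass, 10 ppm at
   `dp = 3` and 0.1 ppm at `dp = 5` — the two settings practitioners
   actually ask for. This is the only lossy stage for m/z.
2. **Delta coding.** Sorted integers become a first absolute value plus
   small non-negative gaps. We keep the absolute value in position 0 of
   the delta array rather than in a separate anchor field; the packer's
   exception mechanism absorbs its size.
3. **Patched frame-of-reference packing.** 128-value blocks are packed
   at a common low bit width; values that do not fit store their
   overflow out of band ("exceptions", at most 10% of a block when
   choosing the width). The width minimizing the estimated block size
   wins, ties to the narrower width. The layout is deliberately simple —
   byte-aligned headers, one position byte and a variable-byte overflow
   per exception — so an independent reference codec can verify it
   bit for bit.
4. **DEFLATE** (zlib, level 6) over the packed stream. Packing first
   shrinks the entropy-coder's input; DEFLATE then captures the
   repetition that block packing cannot. We deflate the *packed* stream
   rather than the raw deltas: packing is cheap, and the packed form is
   what benefits from a final entropy pass. The level is fixed at 6 by
   default but exposed for experimentation; the level lives in the
   metadata so readers never depend on it.

Stages 2–4 are lossless, so decoding returns exactly the quantized
integers. Every decoded array is non-decreasing by construction.

At `dp = 6`, a 3000 Da mass quantizes to 3×10⁹, past the signed 32-bit
range. The packer works on doubles and accepts the full unsigned 32-bit
domain, so no special first-value path is needed; this is documented as
a format property (`docs/format.md`).

## Intensity codecs

Intensity arrays are noisy and duplicate-heavy (notably on TOF
instruments), which suits dictionary compression directly:

* **`int-zlib`** (default): round to one decimal place, store as ×10
  integers (4-byte little-endian; the stream flips to 8-byte storage if
  any value would overflow, flagged in its first byte), DEFLATE. Error
  bound: 0.05 counts.
* **`log10-zlib`** (optional): store `round(log10(I) * S)` in a signed
  16-bit slot, `S = 1024`, zero as a sentinel that decodes to exactly 0.
  The half-step bound gives a relative error of `ln(10)/(2S)` ≈ 0.112%,
  inside the 0.25% budget this codec advertises. `S` was derived once
  from that budget (`ln(10) * 0.5 / S <= 0.0025`) and is not a tuning
  target. We implement the log10 variant only; a log2 flavour would be
  an equivalent re-scaling with no added capability.

## Index strategies

The block layout follows how each acquisition mode is read:

* **COMMON (RT-linear)** — spectra sorted by retention time, chunked
  into blocks of at most 1024 spectra. The cap bounds the memory of a
  single block read; equal retention times break ties by scan number so
  ordering is total and deterministic.
* **DDA** — all MS1 spectra in one RT-ordered block (chromatogram
  extraction reads successive MS1 scans), then one block per MS1 parent
  holding its MS2 children. Children attach to the most recent preceding
  MS1 in file order; an MS2 before any MS1 is an error. Since every DDA
  child has its own precursor, those windows are recorded per spectrum
  in the block entry.
* **DIA/SWATH** — one MS1 block, plus one block per distinct isolation
  window, members RT-ordered. Window identity is the exact
  `(lower, upper)` pair within a 1e-6 Da tolerance: SWATH schedules
  repeat exact windows and the tolerance only absorbs parser jitter.
  Overlapping but distinct windows stay distinct keys. Blocks are
  emitted in ascending window order, making the grouping invariant to
  input order. PRM uses this same path — fixed precursor targets behave
  as windows.

Groups are never split in DDA/DIA (grouping is the point of the
strategy); only the COMMON chunker caps block size.

Mode detection is a heuristic with an override: no MS2 means COMMON; a
small recurring window schedule (≤ 200 windows, each seen ≥ 3 times)
means DIA; anything else is DDA. Converters should pass the known mode
when they have it.

## Queries

Retrieval by RT range decodes only blocks whose RT span intersects the
request (closed interval). Window retrieval fetches exactly the matching
window block. Chromatogram extraction sums, per selected spectrum, the
peaks inside `target * (1 ± ppm * 1e-6)` — a closed interval, ppm
defined against the target mass, peaks located by binary search on the
sorted array. Spectra with no matching peak contribute 0 rather than
being dropped, so traces stay aligned with the scan sequence. On DIA
files a level-2 trace requires an explicit window: summing across a
mixed schedule is almost never what the caller means.

## The synthetic generator

`generate_run()` emulates exactly the features the methods exploit:
cluster-structured sorted m/z arrays (cluster centers uniform over the
mass range, members within a small Gaussian width), log-normal
intensities with a controllable duplicated share, monotone retention
times, and per-mode structure (DDA children with unique 1 Da windows;
DIA cycles over an evenly tiled window schedule). An optional Gaussian
elution profile can be injected for chromatogram tests. It does *not*
model isotope envelopes, realistic peak shapes, mass-dependent
resolution or detector saturation — so passing tests demonstrate
correctness of the codecs, indexes and queries, not compression ratios
on any particular instrument's output. Defaults (200 peaks per spectrum,
0.02 Da cluster width, 30% duplicate intensities, m/z in 100–1500 Da)
were chosen once as plausible centroided-run values.

The toy mzML writer emits minimal, CV-annotated mzML 1.1 (64-bit m/z,
32-bit intensity, optional zlib array compression, retention time in
minutes by default to exercise unit conversion). Reading goes through
the ProteoWizard backend (`mzR`), which also serves as the independent
check on the writer.

## Numerical and degenerate-input choices

* Rounding is half away from zero everywhere, implemented as
  `floor(|x| + 0.5)` — `round()`'s round-half-even would make streams
  platform-honest but value-surprising for users comparing printed
  decimals.
* Integers that can exceed 2³¹ (quantized m/z, scaled intensities,
  byte counts) are carried as doubles, exact below 2⁵³.
* Empty spectra (native or emptied by zero filtering) are kept, with
  zero-length payloads, so scan numbering and RT traces stay complete.
* Readers validate before trusting: pointer arithmetic, list lengths,
  contiguous block tiling and spectrum totals must be consistent;
  unknown JSON keys warn instead of failing; payloads refuse a
  mismatched codec id, and count mismatches surface as corruption
  errors rather than silently truncated arrays.
* Conversion is deterministic: identical input and configuration give
  byte-identical `.json` and `.aird` files.

## Problem sizes used in the checks

The shipped tests run entirely on generated data: codec round trips on
arrays up to 10⁴ values, the packer against an independent
variable-byte codec on 500+ random arrays, compression-dominance over
100 seeded 1000-peak spectra, end-to-end conversion fidelity on a
200-spectrum DIA run, and a 10⁶-point log-spaced sweep for the log10
codec bound. These sizes keep the full suite in the tens of seconds
while exercising every block-boundary and exception path.

## Limitations

Vendor raw formats are out of scope (their readers require closed
SDKs); mzML is the ingestion path. Profile spectra are stored as-is
(no centroiding). Chromatogram storage, scanning-SWATH and ion-mobility
dimensions are not supported. The byte layout is this package's own,
fully specified in `docs/format.md`; it is not byte-compatible with
other implementations of the quantize–delta–pack–DEFLATE idea.
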
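# airdlite

Computation-oriented storage for mass spectrometry runs, for people who
read MS data far more often than they archive it: proteomics and
metabolomics tool authors who need controllable precision, small files
and fast, targeted reads (one block, one spectrum, one isolation
window, one chromatogram) instead of streaming a whole mzML.

A dataset is a two-file container — a human-readable JSON metadata
document carrying the full block index, and a `.aird` binary file that
is nothing but concatenated compressed spectra. Spectra are reordered
by acquisition mode before writing (RT-linear; DDA MS1/MS2 groups;
DIA/SWATH per-isolation-window groups) so the reads each mode actually
performs touch contiguous bytes.

## The core codec

m/z arrays are compressed with **ZDPD**
(quantize–delta–pack–DEFLATE). For a sorted array *m* and a chosen
number of decimal places *dp*:

```
q_i = round(m_i · 10^dp)                  # fixed point; the only lossy step
d_0 = q_0,  d_i = q_i − q_{i−1} ≥ 0       # delta coding of sorted integers
pack: 128-value blocks at bit width b,    # patched frame-of-reference;
      outliers as out-of-band exceptions  # ≤10% exceptions per block
DEFLATE (zlib, level 6)                   # final entropy pass
```

Decoding returns exactly the quantized values, so the total m/z error
is the half-step `0.5·10^−dp` — at 100 Da that is 10 ppm for `dp = 3`
and 0.1 ppm for `dp = 5`. Intensities use either a 1-decimal-place
fixed-point codec (error ≤ 0.05) or an optional log10 codec
(`round(log10 I · 1024)` in 16 bits, relative error ≤ 0.25%). The
byte-exact layout is specified in `docs/format.md`.

## Worked example

Everything below runs on generated data — no downloads. Build a small
DIA run with a known elution profile, write it as mzML, convert, and
query:

```r
library(airdlite)

run <- generate_run("dia", n_ms1 = 10, n_windows = 4,
                    peaks_per_spectrum = 300, seed = 42,
                    elution = list(mz = 802.4, rt_center = 10,
                                   rt_sigma = 4, height = 2e5, level = 1))
mzml <- file.path(tempdir(), "demo.mzML")
write_toy_mzml(run, mzml)

rep <- convert(mzml, tempdir(), compressor_config(mz_dp = 4), mode = "auto")
meta <- read_metadata(rep$json)
meta
#> <aird metadata v0.1.0: DIA, 50 spectra, 5 blocks (4 MS2 blocks), m/z dp=4, intensity 'int-zlib'>
```

The converter detected the DIA schedule (10 MS1 + 40 MS2 spectra in 4
recurring windows) and wrote 5 blocks: one MS1 block plus one per
window. The run shrank from 240160 raw bytes (8-byte m/z + 8-byte
intensity) to 73549 bytes, 30.6%. Single-spectrum random access decodes
only that spectrum's bytes:

```r
read_spectrum(meta, 7L, rep$aird)
#> <spectrum #7 MS2, rt 2.400 s, 300 peaks, window [400.0000, 600.0000]>
```

An extracted ion chromatogram at the injected mass recovers the
Gaussian profile (one point per MS1 scan, zeros where nothing matches;
peak apex 200000 at rt 10 s, as injected):

```r
tr <- xic(meta, rep$aird, 802.4, ppm_tol = 20)
round(tr$intensity)
#>  [1]   8787  27067  64930 121306 176499 200000 176499 121306  64930  27067
tr$rt
#>  [1]  0  2  4  6  8 10 12 14 16 18
```

A command-line wrapper covers the same ground
(`system.file("cli", "aird.R", package = "airdlite")`):

```sh
Rscript aird.R convert demo.mzML -o out --mz-dp 4
Rscript aird.R info out/demo.json
Rscript aird.R xic out/demo.json --mz 802.4 --ppm 20
Rscript aird.R bench --seed 7 --n-peaks 1000 --n-spectra 5
```

The `bench` subcommand compares, on one synthetic run, raw 8-byte m/z
storage, plain DEFLATE, and ZDPD per precision level:

```
dp	raw_bytes	deflate_bytes	zdpd_bytes
3	40000	31992	6974
4	40000	31992	9129
5	40000	31992	11439
```

Size grows with precision, and the structured codec stays well under
plain DEFLATE at every setting.

## Scope

mzML 1.1 in (via `mzR`/ProteoWizard), `.json` + `.aird` out. No vendor
raw reading, no centroiding, no chromatogram storage, no ion-mobility
dimension. See the methods vignette
(`vignettes/airdlite-methods.Rmd`) for the design rationale and known
limitations.
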
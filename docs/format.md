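# airdlite on-disk format

A dataset is a pair of files sharing a stem:

* `<base>.json` — UTF-8 JSON metadata (human-readable, schema in
  `inst/schema/aird-metadata.schema.json`)
* `<base>.aird` — binary block file

All multi-byte integers anywhere in the binary format are
**little-endian**. All rounding is **half away from zero**.

## 1. Binary block file

The `.aird` file is the concatenation of *blocks*; a block is the
concatenation of per-spectrum payload pairs:

```
block   := spectrum_payload*
spectrum_payload := mz_payload intensity_payload
```

There are no magic bytes, block headers or padding in the binary file:
every byte is payload, and all addressing lives in the JSON index
(`start_ptr`, `end_ptr`, `mz_byte_sizes`, `intensity_byte_sizes`). Blocks
tile the byte range `[0, file_size)` contiguously without overlap.

## 2. m/z payload — ZDPD

`mz_payload = DEFLATE(pfor_stream)` where `DEFLATE` is an RFC 1950 zlib
stream (default compression level 6) and `pfor_stream` packs the
delta-coded quantized m/z values:

1. **Quantize**: `q[i] = round(mz[i] * 10^dp)` (half away from zero),
   `dp` = `compressor_config.mz_dp`, 1..6. Values are unsigned; at
   `dp = 6` a 3000 Da mass gives 3×10^9, which still fits the unsigned
   32-bit domain of step 3.
2. **Delta**: `d[0] = q[0]`, `d[i] = q[i] − q[i−1]` (non-negative since
   m/z is sorted).
3. **Patched frame-of-reference pack** (`pfor_stream`):

```
pfor_stream := u32 total_count, block*
block       := u8 bit_width b, u8 exception_count e,
               byte[block_size*b/8] packed_low_bits,
               u8[e] exception_positions,      # 0-based within block
               varbyte[e] exception_high_parts # value >> b
```

* `block_size` is 128 by default (any positive multiple of 32 up to 256).
* The last block is zero-padded to `block_size`; `total_count` recovers
  the true length. An empty array is the 4-byte header only.
* `packed_low_bits`: the low `b` bits of each value, value-sequential,
  LSB-first within each value, bits filled into bytes LSB-first.
* Exceptions are values `>= 2^b`; their low `b` bits sit in the packed
  section, the overflow `value >> b` is a variable-byte integer (7 data
  bits per byte, high bit set on every byte except the last,
  little-endian groups).
* `b` is chosen per block to minimize the encoded block size, subject to
  `e <= floor(exception_ratio * block_size)` (default ratio 0.10);
  `b = 32` (always exception-free) is the fallback.

Decoding inverts each stage; the result equals the quantized integers
exactly, so the only loss against the original m/z is the quantization
half-step `0.5 * 10^-dp`.

## 3. Intensity payloads

Both codecs end with the same DEFLATE as above.

### `int-zlib` (default, 1 decimal place)

```
body := u8 width (4 or 8), int[n]     # value = round(intensity * 10)
```

`width = 4`: each integer as `u32`. If any scaled value would reach
`2^31`, the whole stream uses `width = 8`: each value as `u64`
(low `u32`, high `u32`). Decoded intensity is `value / 10`; worst-case
error 0.05.

### `log10-zlib` (optional, near-lossless)

```
body := s16[n]                        # q = round(log10(I) * S), S = 1024
```

Intensity 0 is stored as the sentinel `-32768` and decodes to 0 exactly.
Decoded intensity is `10^(q/S)`; the relative error is at most
`ln(10)/(2S)` ≈ 0.112% < 0.25%. Representable positive domain:
`[10^(-32767/S), 10^(32767/S)]`.

## 4. JSON metadata

Top-level object:

| field | type | meaning |
|---|---|---|
| `version` | string | format version |
| `acquisition_mode` | string | `COMMON`, `DDA`, `DIA`, `PRM` |
| `instrument` | object | free-form descriptor |
| `compressor_config` | object | `mz_dp`, `intensity_codec`, `deflate_level`, `pfor{block_size, exception_ratio}` |
| `ignore_zero_intensity` | bool | whether zero-intensity pairs were dropped |
| `total_spectra` | int | must equal the sum over blocks |
| `indexes` | array | block index, see below |

Block entry:

| field | type | meaning |
|---|---|---|
| `level` | int | 1 or 2 |
| `start_ptr`, `end_ptr` | int | byte range in `.aird`; `end−start` must equal the sum of the size lists |
| `scan_nums` | int[] | per spectrum |
| `rts` | number[] | seconds, non-decreasing within a block |
| `mz_byte_sizes`, `intensity_byte_sizes` | int[] | per-spectrum payload lengths |
| `precursor_window` | [lower, upper] or null | DIA/PRM window shared by the block |
| `precursor_windows` | array of [lower, upper], optional | DDA MS2 blocks: per-spectrum windows (each child has its own precursor) |
| `parent_scan` | int or null | DDA MS2 blocks: scan number of the owning MS1 |

Block order by mode:

* `COMMON` — RT-sorted spectra cut into blocks of at most 1024.
* `DDA` — one level-1 block (all MS1, RT order), then one level-2 block
  per MS1 that has children, in parent RT order.
* `DIA`/`PRM` — one level-1 block, then one level-2 block per distinct
  isolation window (matched within 1e-6 Da), in ascending window order.

Readers accept unknown JSON keys with a warning (forward compatibility)
and reject any document whose pointer arithmetic, list lengths or
spectrum totals are inconsistent.
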
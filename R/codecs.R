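# Byte-level codecs: ZDPD pipeline for m/z, fixed-point and log10 codecs for
# intensity. All multi-byte quantities are little-endian. Integers that may
# exceed .Machine$integer.max are carried as doubles (exact below 2^53).

## ---- small binary helpers ----------------------------------------------

# Round half away from zero; plain round() is round-half-even.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# doubles in [0, 2^32) -> 4 bytes each, little-endian
u32_to_raw <- function(v) {
  if (length(v) == 0L) return(raw(0))
  b0 <- v %% 256; v <- (v - b0) / 256
  b1 <- v %% 256; v <- (v - b1) / 256
  b2 <- v %% 256; b3 <- (v - b2) / 256
  as.raw(rbind(b0, b1, b2, b3))
}

raw_to_u32 <- function(r) {
  if (length(r) == 0L) return(numeric(0))
  stopifnot(length(r) %% 4L == 0L)
  m <- matrix(as.integer(r), nrow = 4L)
  m[1, ] + 256 * (m[2, ] + 256 * (m[3, ] + 256 * m[4, ]))
}

# signed 16-bit <-> 2 bytes little-endian
s16_to_raw <- function(v) {
  u <- ifelse(v < 0, v + 65536, v)
  b0 <- u %% 256
  as.raw(rbind(b0, (u - b0) / 256))
}

raw_to_s16 <- function(r) {
  stopifnot(length(r) %% 2L == 0L)
  m <- matrix(as.integer(r), nrow = 2L)
  u <- m[1, ] + 256 * m[2, ]
  ifelse(u > 32767, u - 65536, u)
}

# variable-byte: 7 payload bits per byte, little-endian groups, high bit set
# on all but the terminal byte
varbyte_encode <- function(v) {
  out <- vector("list", length(v))
  for (i in seq_along(v)) {
    x <- v[i]
    bytes <- integer(0)
    repeat {
      b <- x %% 128
      x <- (x - b) / 128
      if (x > 0) bytes <- c(bytes, b + 128) else { bytes <- c(bytes, b); break }
    }
    out[[i]] <- as.raw(bytes)
  }
  do.call(c, c(out, list(raw(0))))
}

# decode n values starting at position pos (1-based); returns values and the
# next unread position
varbyte_decode <- function(r, n, pos = 1L) {
  vals <- numeric(n)
  for (i in seq_len(n)) {
    x <- 0; mult <- 1
    repeat {
      if (pos > length(r)) stop("corrupt stream: truncated variable-byte value",
                                call. = FALSE)
      b <- as.integer(r[pos]); pos <- pos + 1L
      x <- x + (b %% 128) * mult
      if (b < 128) break
      mult <- mult * 128
    }
    vals[i] <- x
  }
  list(values = vals, pos = pos)
}

## ---- m/z quantization ---------------------------------------------------

#' Quantize an m/z array to fixed-point integers
#'
#' Multiplies each m/z by `10^dp` and rounds half away from zero. The input
#' must be sorted non-decreasing (spectra store m/z sorted); the output is
#' then non-decreasing too and dequantizes back to within `0.5 * 10^-dp` of
#' the input.
#'
#' @param mz Numeric vector of non-negative m/z values (Da), sorted
#'   non-decreasing.
#' @param cfg A [quant_config()].
#' @return Numeric vector of non-negative integral values (kept as doubles:
#'   at `dp = 6` a 3000 Da mass quantizes to 3e9, beyond 32-bit signed
#'   range).
#' @seealso [dequantize_mz()], [zdpd_encode()]
#' @export
quantize_mz <- function(mz, cfg = quant_config()) {
  stopifnot(inherits(cfg, "quant_config"))
  if (length(mz) == 0L) return(numeric(0))
  if (anyNA(mz) || any(mz < 0)) stop("m/z values must be non-negative",
                                     call. = FALSE)
  if (is.unsorted(mz)) stop("m/z array must be sorted non-decreasing",
                            call. = FALSE)
  floor(mz * cfg$scale + 0.5)
}

#' Reverse fixed-point m/z quantization
#'
#' @param q Numeric vector of quantized (integral) values, non-decreasing.
#' @param cfg A [quant_config()].
#' @return Numeric m/z values, `q / 10^dp`.
#' @export
dequantize_mz <- function(q, cfg = quant_config()) {
  stopifnot(inherits(cfg, "quant_config"))
  q / cfg$scale
}

## ---- delta coding -------------------------------------------------------

#' Delta-encode a non-decreasing integer array
#'
#' Position 0 keeps the absolute first value; every later position stores
#' the difference to its predecessor. Sorted m/z arrays give small,
#' similar deltas, which is what the downstream bit packer exploits.
#'
#' @param q Numeric vector, non-decreasing.
#' @return Numeric vector of the same length; all elements after the first
#'   are non-negative.
#' @export
delta_encode <- function(q) {
  if (length(q) == 0L) return(numeric(0))
  if (is.unsorted(q)) stop("delta_encode requires a non-decreasing array",
                           call. = FALSE)
  c(q[1L], diff(q))
}

#' Invert delta encoding by cumulative summation
#'
#' @param d Numeric vector of deltas; elements after the first must be
#'   non-negative.
#' @return The reconstructed non-decreasing array.
#' @export
delta_decode <- function(d) {
  if (length(d) == 0L) return(numeric(0))
  if (length(d) > 1L && any(d[-1L] < 0))
    stop("corrupt delta stream: negative delta after position 0",
         call. = FALSE)
  cumsum(d)
}

## ---- patched frame-of-reference bit packing -----------------------------

# per-block bit width selection: smallest encoded size subject to the
# exception budget; ties go to the smaller width
pfor_choose_width <- function(block, p) {
  max_exc <- floor(p$exception_ratio * p$block_size)
  best_b <- 32L
  best_size <- Inf
  for (b in 0:32) {
    lim <- 2^b
    exc <- block >= lim
    e <- sum(exc)
    if (e > max_exc && b < 32L) next
    size <- 2 + p$block_size * b / 8
    if (e > 0L) {
      high <- floor(block[exc] / lim)
      nb <- ifelse(high == 0, 1, ceiling((floor(log2(pmax(high, 1))) + 1) / 7))
      size <- size + e + sum(nb)
    }
    if (size < best_size) { best_size <- size; best_b <- b }
  }
  best_b
}

#' Pack non-negative integers with a patched frame-of-reference layout
#'
#' The stream starts with the total value count (4-byte unsigned
#' little-endian). Values then go out in fixed-size blocks: a 1-byte bit
#' width `b`, a 1-byte exception count `e`, the low `b` bits of every value
#' packed LSB-first, then `e` exception positions (1 byte each) and `e`
#' variable-byte overflow parts (`value >> b`). The final partial block is
#' zero-padded; the header count recovers the true length.
#'
#' @param v Numeric vector of integral values in `[0, 2^32)`.
#' @param p A [pfor_params()].
#' @return A raw vector (self-delimiting given `p`).
#' @seealso [pfor_decode()]
#' @export
pfor_encode <- function(v, p = pfor_params()) {
  stopifnot(inherits(p, "pfor_params"))
  n <- length(v)
  if (n > 0L) {
    if (anyNA(v) || any(v < 0)) stop("values must be non-negative", call. = FALSE)
    if (any(v >= 2^32)) stop("value out of range: must be < 2^32", call. = FALSE)
  }
  bs <- p$block_size
  parts <- list(u32_to_raw(n))
  nblocks <- if (n == 0L) 0L else ceiling(n / bs)
  for (k in seq_len(nblocks)) {
    idx <- ((k - 1L) * bs + 1L):min(k * bs, n)
    block <- c(v[idx], numeric(bs - length(idx)))
    b <- pfor_choose_width(block, p)
    lim <- 2^b
    exc_pos <- which(block >= lim)            # 1-based
    e <- length(exc_pos)
    low <- block %% lim
    packed <- raw(0)
    if (b > 0L) {
      bits <- matrix(0L, nrow = b, ncol = bs)
      tmp <- low
      for (j in seq_len(b)) {
        bits[j, ] <- tmp %% 2
        tmp <- (tmp - bits[j, ]) / 2
      }
      packed <- packBits(as.logical(bits), "raw")
    }
    exc <- raw(0)
    if (e > 0L) {
      high <- floor(block[exc_pos] / lim)
      exc <- c(as.raw(exc_pos - 1L), varbyte_encode(high))
    }
    parts[[k + 1L]] <- c(as.raw(b), as.raw(e), packed, exc)
  }
  do.call(c, parts)
}

#' Unpack a patched frame-of-reference stream
#'
#' Exact inverse of [pfor_encode()] under the same [pfor_params()].
#'
#' @param r Raw vector as produced by [pfor_encode()].
#' @param p A [pfor_params()].
#' @return Numeric vector of the originally packed values.
#' @export
pfor_decode <- function(r, p = pfor_params()) {
  stopifnot(inherits(p, "pfor_params"))
  if (length(r) < 4L) stop("corrupt stream: missing count header", call. = FALSE)
  n <- raw_to_u32(r[1:4])
  pos <- 5L
  bs <- p$block_size
  nblocks <- if (n == 0) 0L else ceiling(n / bs)
  out <- vector("list", nblocks)
  for (k in seq_len(nblocks)) {
    if (pos + 1L > length(r)) stop("corrupt stream: truncated block header",
                                   call. = FALSE)
    b <- as.integer(r[pos]); e <- as.integer(r[pos + 1L]); pos <- pos + 2L
    if (b > 32L) stop("corrupt stream: bit width > 32", call. = FALSE)
    vals <- numeric(bs)
    if (b > 0L) {
      nbytes <- bs * b / 8L
      if (pos + nbytes - 1L > length(r))
        stop("corrupt stream: truncated packed block", call. = FALSE)
      bits <- matrix(as.integer(rawToBits(r[pos:(pos + nbytes - 1L)])),
                     nrow = b)
      vals <- as.numeric(2^(0:(b - 1L)) %*% bits)
      pos <- pos + nbytes
    }
    if (e > 0L) {
      if (pos + e - 1L > length(r))
        stop("corrupt stream: truncated exception positions", call. = FALSE)
      epos <- as.integer(r[pos:(pos + e - 1L)]) + 1L
      pos <- pos + e
      dec <- varbyte_decode(r, e, pos)
      pos <- dec$pos
      vals[epos] <- vals[epos] + dec$values * 2^b
    }
    out[[k]] <- vals
  }
  if (pos != length(r) + 1L)
    stop("corrupt stream: trailing bytes after final block", call. = FALSE)
  v <- if (nblocks) do.call(c, out) else numeric(0)
  if (length(v) < n) stop("corrupt stream: count exceeds decoded values",
                          call. = FALSE)
  v[seq_len(n)]
}

## ---- DEFLATE ------------------------------------------------------------

#' DEFLATE (RFC 1950 zlib) a raw vector
#'
#' @param data Raw vector.
#' @param level Compression level 0..9; 6 is this format's default.
#' @return Compressed raw vector (zlib stream).
#' @export
deflate_bytes <- function(data, level = 6L) {
  stopifnot(is.raw(data))
  .Call(c_deflate, data, as.integer(level))
}

#' Inverse of [deflate_bytes()]
#'
#' @param data Raw vector holding a zlib stream.
#' @return Decompressed raw vector; corrupt or non-zlib input is an error.
#' @export
inflate_bytes <- function(data) {
  stopifnot(is.raw(data))
  .Call(c_inflate, data)
}

## ---- ZDPD: the composed m/z codec ---------------------------------------

#' Compress a sorted m/z array with the ZDPD pipeline
#'
#' Quantize to `dp` decimal places, delta-code the sorted integers, bit-pack
#' the deltas with the patched frame-of-reference layout, then DEFLATE the
#' packed stream. The stages compose losslessly, so decoding returns exactly
#' the quantized values: total loss is the quantization half-step,
#' `0.5 * 10^-dp`.
#'
#' @param mz Sorted non-negative numeric m/z array (Da).
#' @param cfg A [quant_config()].
#' @param p A [pfor_params()].
#' @param deflate_level zlib level (default 6).
#' @return An [encoded_payload()] with `codec_id = "zdpd"`.
#' @examples
#' pay <- zdpd_encode(c(152.001, 152.004, 380.1), quant_config(3))
#' zdpd_decode(pay, quant_config(3))
#' @export
zdpd_encode <- function(mz, cfg = quant_config(), p = pfor_params(),
                        deflate_level = 6L) {
  q <- quantize_mz(mz, cfg)
  encoded_payload("zdpd",
                  deflate_bytes(pfor_encode(delta_encode(q), p), deflate_level),
                  length(mz))
}

#' Decode a ZDPD payload back to m/z values
#'
#' @param payload An [encoded_payload()] with `codec_id = "zdpd"`.
#' @param cfg The [quant_config()] used at encode time.
#' @param p The [pfor_params()] used at encode time.
#' @return Numeric m/z array, non-decreasing, equal to the quantized input.
#' @export
zdpd_decode <- function(payload, cfg = quant_config(), p = pfor_params()) {
  stopifnot(inherits(payload, "encoded_payload"))
  if (payload$codec_id != "zdpd")
    stop(sprintf("codec mismatch: payload is '%s', expected 'zdpd'",
                 payload$codec_id), call. = FALSE)
  q <- delta_decode(pfor_decode(inflate_bytes(payload$data), p))
  if (!is.na(payload$n_values) && length(q) != payload$n_values)
    stop("corrupt payload: decoded count differs from declared n_values",
         call. = FALSE)
  dequantize_mz(q, cfg)
}

## ---- intensity codecs ---------------------------------------------------

#' Encode intensities at 1 decimal place with DEFLATE
#'
#' Each intensity is rounded (half away from zero) to one decimal place and
#' stored as a x10 integer, 4 bytes little-endian; if any value would
#' overflow a signed 32-bit integer the whole stream switches to 8-byte
#' storage, flagged in the first stream byte. The integer stream is then
#' DEFLATEd, which thrives on the duplicate-heavy intensity arrays TOF
#' instruments produce.
#'
#' @param intensity Numeric vector of non-negative intensities.
#' @param deflate_level zlib level (default 6).
#' @return An [encoded_payload()] with `codec_id = "int-zlib"`.
#' @export
intensity_encode_zlib <- function(intensity, deflate_level = 6L) {
  if (length(intensity) && (anyNA(intensity) || any(intensity < 0)))
    stop("intensities must be non-negative", call. = FALSE)
  q <- floor(intensity * 10 + 0.5)
  wide <- length(q) > 0L && any(q >= 2^31)
  body <- if (wide) {
    lo_r <- matrix(u32_to_raw(q %% 2^32), nrow = 4L)
    hi_r <- matrix(u32_to_raw(floor(q / 2^32)), nrow = 4L)
    c(as.raw(8L), as.vector(rbind(lo_r, hi_r)))
  } else {
    c(as.raw(4L), u32_to_raw(q))
  }
  encoded_payload("int-zlib", deflate_bytes(body, deflate_level),
                  length(intensity))
}

#' Decode an `"int-zlib"` intensity payload
#'
#' @param payload An [encoded_payload()] with `codec_id = "int-zlib"`.
#' @return Numeric intensities, each within 0.05 of the encoded original.
#' @export
intensity_decode_zlib <- function(payload) {
  stopifnot(inherits(payload, "encoded_payload"))
  if (payload$codec_id != "int-zlib")
    stop(sprintf("codec mismatch: payload is '%s', expected 'int-zlib'",
                 payload$codec_id), call. = FALSE)
  body <- inflate_bytes(payload$data)
  if (length(body) < 1L) stop("corrupt payload: missing width flag",
                              call. = FALSE)
  width <- as.integer(body[1L])
  body <- body[-1L]
  q <- if (width == 4L) {
    raw_to_u32(body)
  } else if (width == 8L) {
    if (length(body) %% 8L != 0L)
      stop("corrupt payload: 8-byte stream length not a multiple of 8",
           call. = FALSE)
    m <- matrix(raw_to_u32(body), nrow = 2L)
    m[1, ] + m[2, ] * 2^32
  } else stop("corrupt payload: unknown width flag", call. = FALSE)
  if (!is.na(payload$n_values) && length(q) != payload$n_values)
    stop("codec mismatch or corrupt payload: decoded count differs from expected",
         call. = FALSE)
  q / 10
}

#' Encode intensities with the near-lossless log10 codec
#'
#' Stores `round(log10(I) * scale)` as signed 16-bit little-endian integers
#' (zeros as a sentinel code), DEFLATEd. Reconstruction is
#' `10^(q / scale)`; at the default `scale = 1024` the relative error is at
#' most `ln(10)/2048`, about 0.112%, within this codec's 0.25% budget.
#'
#' @param intensity Numeric vector of non-negative intensities; positive
#'   values must lie in the representable domain
#'   `[10^(-32767/scale), 10^(32767/scale)]`.
#' @param cfg A [log10_config()].
#' @param deflate_level zlib level (default 6).
#' @return An [encoded_payload()] with `codec_id = "log10-zlib"`.
#' @export
intensity_encode_log10 <- function(intensity, cfg = log10_config(),
                                   deflate_level = 6L) {
  stopifnot(inherits(cfg, "log10_config"))
  if (length(intensity) && (anyNA(intensity) || any(intensity < 0)))
    stop("intensities must be non-negative", call. = FALSE)
  q <- numeric(length(intensity))
  zero <- intensity == 0
  q[zero] <- cfg$zero_sentinel
  if (any(!zero)) {
    qi <- round_half_away(log10(intensity[!zero]) * cfg$scale)
    if (any(qi > 32767 | qi < -32767 | qi == cfg$zero_sentinel))
      stop("intensity outside representable domain of the log10 codec",
           call. = FALSE)
    q[!zero] <- qi
  }
  encoded_payload("log10-zlib", deflate_bytes(s16_to_raw(q), deflate_level),
                  length(intensity))
}

#' Decode a `"log10-zlib"` intensity payload
#'
#' @param payload An [encoded_payload()] with `codec_id = "log10-zlib"`.
#' @param cfg The [log10_config()] used at encode time.
#' @return Numeric intensities; zeros exact, positives within 0.25%
#'   relative error.
#' @export
intensity_decode_log10 <- function(payload, cfg = log10_config()) {
  stopifnot(inherits(payload, "encoded_payload"))
  if (payload$codec_id != "log10-zlib")
    stop(sprintf("codec mismatch: payload is '%s', expected 'log10-zlib'",
                 payload$codec_id), call. = FALSE)
  body <- inflate_bytes(payload$data)
  if (length(body) %% 2L != 0L)
    stop("codec mismatch or corrupt payload: odd byte count", call. = FALSE)
  q <- raw_to_s16(body)
  if (!is.na(payload$n_values) && length(q) != payload$n_values)
    stop("codec mismatch or corrupt payload: decoded count differs from expected",
         call. = FALSE)
  out <- 10^(q / cfg$scale)
  out[q == cfg$zero_sentinel] <- 0
  out
}

# dispatch used by the container reader/writer
intensity_encode <- function(intensity, cfg) {
  switch(cfg$intensity_codec,
         "int-zlib" = intensity_encode_zlib(intensity, cfg$deflate_level),
         "log10-zlib" = intensity_encode_log10(intensity,
                                               deflate_level = cfg$deflate_level),
         stop("unknown intensity codec: ", cfg$intensity_codec, call. = FALSE))
}

intensity_decode <- function(payload, codec_id) {
  switch(codec_id,
         "int-zlib" = intensity_decode_zlib(payload),
         "log10-zlib" = intensity_decode_log10(payload),
         stop("unknown intensity codec: ", codec_id, call. = FALSE))
}
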
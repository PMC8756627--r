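#' Fixed-point m/z quantization configuration
#'
#' m/z values are stored as integers after multiplication by `10^dp`, so `dp`
#' decimal places are retained. The worst-case absolute error is
#' `0.5 * 10^-dp`; relative to a mass of 100 Da that is 10 ppm at `dp = 3`
#' and 0.1 ppm at `dp = 5`.
#'
#' @param dp Number of retained decimal places, an integer in 1..6.
#' @return An object of class `quant_config` with fields `dp` and
#'   `scale` (`10^dp`).
#' @examples
#' quant_config(3)
#' @export
quant_config <- function(dp = 4L) {
  dp <- as.integer(dp)
  if (length(dp) != 1L || is.na(dp) || dp < 1L || dp > 6L)
    stop("dp must be a single integer in 1..6", call. = FALSE)
  structure(list(dp = dp, scale = 10^dp), class = "quant_config")
}

#' Patched frame-of-reference packing parameters
#'
#' Controls the block-wise bit packer used on delta-coded m/z integers.
#' Values are packed in fixed-size blocks at a common low bit width; values
#' that do not fit ("exceptions") store their overflow out of band. The bit
#' width is chosen per block to minimize the encoded block size, subject to
#' the exception count not exceeding `exception_ratio * block_size`.
#'
#' @param block_size Integers per packed block; a positive multiple of 32,
#'   at most 256 (exception positions are stored as single bytes).
#' @param exception_ratio Maximum tolerated fraction of exceptions per block
#'   when choosing the bit width, in `[0, 0.5)`.
#' @return An object of class `pfor_params`.
#' @export
pfor_params <- function(block_size = 128L, exception_ratio = 0.10) {
  block_size <- as.integer(block_size)
  if (length(block_size) != 1L || is.na(block_size) ||
      block_size <= 0L || block_size %% 32L != 0L || block_size > 256L)
    stop("block_size must be a positive multiple of 32, <= 256", call. = FALSE)
  if (length(exception_ratio) != 1L || is.na(exception_ratio) ||
      exception_ratio < 0 || exception_ratio >= 0.5)
    stop("exception_ratio must be in [0, 0.5)", call. = FALSE)
  structure(list(block_size = block_size, exception_ratio = exception_ratio),
            class = "pfor_params")
}

#' Log10 intensity codec configuration
#'
#' Stores `round(log10(I) * scale)` as a signed 16-bit integer per value.
#' The half-step quantization error bounds the relative reconstruction error
#' by `ln(10) * 0.5 / scale`; the default `scale = 1024` gives ~0.112%,
#' within the 0.25% budget this codec advertises. Intensity 0 is mapped to a
#' reserved sentinel code and reconstructed exactly.
#'
#' @param scale Fixed-point multiplier applied to `log10(I)`.
#' @param zero_sentinel Reserved 16-bit code for intensity zero.
#' @return An object of class `log10_config`.
#' @export
log10_config <- function(scale = 1024, zero_sentinel = -32768L) {
  if (log(10) * 0.5 / scale > 0.0025)
    stop("scale too small: cannot guarantee 0.25% relative error", call. = FALSE)
  if (zero_sentinel < -32768 || zero_sentinel > 32767)
    stop("zero_sentinel must fit a signed 16-bit integer", call. = FALSE)
  structure(list(scale = scale, zero_sentinel = as.integer(zero_sentinel)),
            class = "log10_config")
}

#' @export
print.quant_config <- function(x, ...) {
  cat(sprintf("m/z quantization: %d decimal places (scale %g, max abs error %g Da)\n",
              x$dp, x$scale, 0.5 / x$scale))
  invisible(x)
}

#' Full compressor configuration for an Aird file
#'
#' @param mz_dp Decimal places retained on m/z (see [quant_config()]).
#' @param intensity_codec `"int-zlib"` (1 decimal place fixed point +
#'   DEFLATE, the default) or `"log10-zlib"` (near-lossless, <= 0.25%
#'   relative error).
#' @param deflate_level zlib compression level, 0..9 (default 6).
#' @param pfor A [pfor_params()] object.
#' @return An object of class `compressor_config`.
#' @examples
#' compressor_config(mz_dp = 3, intensity_codec = "log10-zlib")
#' @export
compressor_config <- function(mz_dp = 4L,
                              intensity_codec = c("int-zlib", "log10-zlib"),
                              deflate_level = 6L,
                              pfor = pfor_params()) {
  intensity_codec <- match.arg(intensity_codec)
  deflate_level <- as.integer(deflate_level)
  if (is.na(deflate_level) || deflate_level < 0L || deflate_level > 9L)
    stop("deflate_level must be in 0..9", call. = FALSE)
  stopifnot(inherits(pfor, "pfor_params"))
  structure(list(mz_dp = quant_config(mz_dp)$dp,
                 intensity_codec = intensity_codec,
                 deflate_level = deflate_level,
                 pfor = pfor),
            class = "compressor_config")
}

#' Encoded payload container
#'
#' An opaque byte sequence produced by one codec, tagged with the codec
#' identity and the number of values it encodes. Decoders refuse payloads
#' whose `codec_id` does not match.
#'
#' @param codec_id One of `"zdpd"`, `"int-zlib"`, `"log10-zlib"`.
#' @param data A raw vector.
#' @param n_values Number of encoded values (`NA` when unknown, e.g. when a
#'   payload is re-read from disk and the count lives inside the stream).
#' @return An object of class `encoded_payload`.
#' @export
encoded_payload <- function(codec_id, data, n_values = NA_integer_) {
  stopifnot(is.character(codec_id), length(codec_id) == 1L, is.raw(data))
  structure(list(codec_id = codec_id, data = data,
                 n_values = as.integer(n_values)),
            class = "encoded_payload")
}

#' @export
print.encoded_payload <- function(x, ...) {
  cat(sprintf("<encoded_payload '%s': %d bytes, %s values>\n",
              x$codec_id, length(x$data),
              if (is.na(x$n_values)) "?" else x$n_values))
  invisible(x)
}
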
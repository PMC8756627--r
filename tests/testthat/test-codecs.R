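# Quantization, delta coding, DEFLATE and the intensity codecs.

test_that("quantization rounds half away from zero and bounds the error", {
  expect_equal(quantize_mz(100.0, quant_config(3)), 100000)
  expect_equal(quantize_mz(123.45678, quant_config(3)), 123457)
  expect_equal(dequantize_mz(100000, quant_config(3)), 100.0)
  expect_identical(quantize_mz(numeric(0), quant_config(2)), numeric(0))
  expect_identical(dequantize_mz(numeric(0), quant_config(2)), numeric(0))

  set.seed(42)
  for (dp in c(1L, 3L, 6L)) {
    cfg <- quant_config(dp)
    x <- sort(runif(2000, 0, 3000))
    q <- quantize_mz(x, cfg)
    expect_false(is.unsorted(q))
    expect_true(all(q == floor(q)))
    expect_lte(max(abs(dequantize_mz(q, cfg) - x)), 0.5 * 10^-dp)
  }
})

test_that("quantization rejects unsorted or negative input", {
  expect_error(quantize_mz(c(2, 1), quant_config(3)), "sorted")
  expect_error(quantize_mz(c(-1, 2), quant_config(3)), "non-negative")
  expect_error(quant_config(0), "1..6")
  expect_error(quant_config(7), "1..6")
})

test_that("quantization ppm error meets the stated precision rules", {
  # >= 100 Da: dp=3 keeps the error within 10 ppm, dp=5 within 0.1 ppm
  m <- seq(100, 3000, length.out = 1e5)
  for (rule in list(list(dp = 3L, ppm = 10), list(dp = 5L, ppm = 0.1))) {
    cfg <- quant_config(rule$dp)
    back <- dequantize_mz(quantize_mz(m, cfg), cfg)
    expect_lte(max(abs(back - m) / m) * 1e6, rule$ppm)
  }
})

test_that("delta coding is exact and order-checked", {
  expect_equal(delta_encode(c(5, 7, 7, 10)), c(5, 2, 0, 3))
  expect_equal(delta_encode(100000), 100000)
  expect_identical(delta_encode(numeric(0)), numeric(0))
  expect_equal(delta_decode(c(5, 2, 0, 3)), c(5, 7, 7, 10))
  expect_identical(delta_decode(numeric(0)), numeric(0))
  expect_error(delta_encode(c(3, 2)), "non-decreasing")
  expect_error(delta_decode(c(3, -1)), "negative delta")

  set.seed(7)
  for (i in 1:200) {
    q <- sort(floor(runif(sample(0:300, 1), 0, 1e7)))
    expect_identical(delta_decode(delta_encode(q)), q)
  }
})

test_that("deflate/inflate round-trip, compress repetition, reject garbage", {
  set.seed(11)
  for (n in c(0, 1, 100, 5000)) {
    x <- as.raw(sample(0:255, n, replace = TRUE))
    expect_identical(inflate_bytes(deflate_bytes(x)), x)
  }
  rep_input <- as.raw(rep(7L, 1e4))
  expect_lt(length(deflate_bytes(rep_input)), length(rep_input))
  expect_error(inflate_bytes(as.raw(c(1, 2, 3))), "zlib")
  # higher level never produces a longer stream on repetitive input
  expect_lte(length(deflate_bytes(rep_input, 9L)),
             length(deflate_bytes(rep_input, 1L)))
})

test_that("1-dp intensity codec rounds half away from zero within 0.05", {
  p <- intensity_encode_zlib(c(1.5, 2.25))
  expect_equal(intensity_decode_zlib(p), c(1.5, 2.3))
  set.seed(13)
  x <- rlnorm(5000, log(1e4), 2)
  expect_lte(max(abs(intensity_decode_zlib(intensity_encode_zlib(x)) - x)),
             0.05)
  expect_identical(intensity_decode_zlib(intensity_encode_zlib(numeric(0))),
                   numeric(0))
  expect_error(intensity_encode_zlib(-1), "non-negative")
})

test_that("1-dp intensity codec switches to 8-byte storage on overflow", {
  x <- c(3.0e8, 12.5, 0)
  p <- intensity_encode_zlib(x)          # 3e9 as x10 int exceeds 2^31
  expect_identical(intensity_decode_zlib(p), x)
  # stream flag byte says 8
  expect_equal(as.integer(inflate_bytes(p$data)[1]), 8L)
  below <- intensity_encode_zlib(c(12.5))
  expect_equal(as.integer(inflate_bytes(below$data)[1]), 4L)
})

test_that("log10 intensity codec: exact zero and 1.0, 0.25% bound, domain check", {
  cfg <- log10_config()
  expect_equal(intensity_decode_log10(intensity_encode_log10(1.0)), 1.0)
  expect_equal(intensity_decode_log10(intensity_encode_log10(0.0)), 0.0)
  p0 <- intensity_encode_log10(c(0, 1, 0))
  expect_equal(intensity_decode_log10(p0), c(0, 1, 0))

  x <- 10^seq(0, 8, length.out = 1e5)
  dec <- intensity_decode_log10(intensity_encode_log10(x))
  expect_lte(max(abs(dec - x) / x), 0.0025)

  expect_error(intensity_encode_log10(1e35), "domain")
  expect_error(intensity_encode_log10(-2), "non-negative")
  expect_error(log10_config(scale = 100), "0.25")
})

test_that("codec payloads refuse a mismatched codec id", {
  pz <- intensity_encode_zlib(c(1, 2, 3))
  expect_error(intensity_decode_log10(pz), "codec mismatch")
  pl <- intensity_encode_log10(c(1, 2, 3))
  expect_error(intensity_decode_zlib(pl), "codec mismatch")
  expect_error(zdpd_decode(pz), "codec mismatch")
})
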
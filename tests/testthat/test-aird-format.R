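# Two-file container: writer, metadata validation, block and spectrum reads.

test_that("block pointers tile the binary file and sizes add up", {
  run <- generate_run("dia", n_ms1 = 3, n_windows = 2, peaks_per_spectrum = 40,
                      seed = 11)
  out <- write_run(run)
  meta <- out$meta
  blocks <- meta$indexes
  for (b in blocks) {
    expect_equal(b$end_ptr - b$start_ptr,
                 sum(b$mz_byte_sizes) + sum(b$intensity_byte_sizes))
    expect_false(is.unsorted(b$rts))
  }
  starts <- sort(vapply(blocks, `[[`, numeric(1), "start_ptr"))
  ends <- sort(vapply(blocks, `[[`, numeric(1), "end_ptr"))
  expect_equal(starts[1], 0)
  expect_equal(ends[length(ends)], file.size(out$aird))
  expect_equal(starts[-1], ends[-length(ends)])
})

test_that("every spectrum reads back at quantized precision", {
  run <- generate_run("dda", n_ms1 = 4, ms2_per_ms1 = 3,
                      peaks_per_spectrum = 60, seed = 13)
  cfg <- compressor_config(mz_dp = 3)
  out <- write_run(run, cfg = cfg)
  got <- read_all_spectra(out$meta, out$aird)
  expect_identical(scan_nums_of(got), scan_nums_of(run))
  byscan <- got[order(vapply(got, `[[`, integer(1), "scan_num"))]
  qc <- quant_config(3)
  for (i in seq_along(run)) {
    s0 <- run[[i]]; s1 <- byscan[[i]]
    expect_identical(s1$mz, dequantize_mz(quantize_mz(s0$mz, qc), qc))
    expect_lte(max(abs(s1$intensity - s0$intensity)), 0.05)
    expect_equal(s1$rt, s0$rt)
    expect_equal(s1$ms_level, s0$ms_level)
    if (s0$ms_level == 2L)
      expect_equal(s1$precursor_window, s0$precursor_window)
  }
})

test_that("metadata JSON survives a write-read-write round trip", {
  run <- generate_run("dia", n_ms1 = 3, n_windows = 2, peaks_per_spectrum = 20,
                      seed = 15)
  out <- write_run(run)
  doc1 <- jsonlite::fromJSON(out$json, simplifyVector = FALSE)
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc1, f2, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  meta2 <- read_metadata(f2)
  expect_equal(meta2$indexes, out$meta$indexes)
  expect_equal(meta2$acquisition_mode, out$meta$acquisition_mode)
})

test_that("corrupted pointers and missing fields are validation errors", {
  run <- generate_run("common", n_ms1 = 4, peaks_per_spectrum = 20, seed = 17)
  out <- write_run(run)
  doc <- jsonlite::fromJSON(out$json, simplifyVector = FALSE)

  bad <- doc
  bad$indexes[[1]]$end_ptr <- bad$indexes[[1]]$end_ptr + 1
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, f, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(read_metadata(f), "indexes\\[1\\]")

  bad2 <- doc
  bad2$indexes[[1]]$rts <- NULL
  jsonlite::write_json(bad2, f, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(read_metadata(f), "missing field")

  bad3 <- doc
  bad3$total_spectra <- bad3$total_spectra + 1L
  jsonlite::write_json(bad3, f, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(read_metadata(f), "total_spectra")
})

test_that("unknown extra metadata keys warn but do not fail", {
  run <- generate_run("common", n_ms1 = 2, peaks_per_spectrum = 10, seed = 19)
  out <- write_run(run)
  doc <- jsonlite::fromJSON(out$json, simplifyVector = FALSE)
  doc$future_feature <- list(enabled = TRUE)
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA, null = "null")
  expect_warning(meta <- read_metadata(f), "future_feature")
  expect_s3_class(meta, "aird_metadata")
})

test_that("single-spectrum random access matches the linear-scan oracle", {
  run <- generate_run("dia", n_ms1 = 5, n_windows = 3, peaks_per_spectrum = 30,
                      seed = 21)                       # 20 spectra
  out <- write_run(run)
  all_sp <- read_all_spectra(out$meta, out$aird)       # full-read oracle
  by_scan <- setNames(all_sp, vapply(all_sp, `[[`, integer(1), "scan_num"))
  for (scan in vapply(run, `[[`, integer(1), "scan_num")) {
    expect_identical(read_spectrum(out$meta, scan, out$aird),
                     by_scan[[as.character(scan)]])
  }
  expect_error(read_spectrum(out$meta, 999L, out$aird), "not present")
})

test_that("block boundary spectra decode via single-spectrum seek", {
  run <- generate_run("common", n_ms1 = 7, peaks_per_spectrum = 25, seed = 23)
  plan <- build_index_rt(run, max_block_spectra = 3L)
  dir <- withr::local_tempdir()
  paths <- write_aird(plan, dir, "chunked")
  meta <- read_metadata(paths$json)
  expect_length(meta$indexes, 3L)
  for (b in meta$indexes) {
    first <- read_spectrum(meta, b$scan_nums[1], paths$aird)
    last <- read_spectrum(meta, b$scan_nums[length(b$scan_nums)], paths$aird)
    expect_equal(first$rt, b$rts[1])
    expect_equal(last$rt, b$rts[length(b$rts)])
  }
})

test_that("a wrong intensity codec id in the metadata is caught at decode", {
  run <- generate_run("common", n_ms1 = 2, peaks_per_spectrum = 30, seed = 25)
  out <- write_run(run, cfg = compressor_config(intensity_codec = "int-zlib"))
  doc <- jsonlite::fromJSON(out$json, simplifyVector = FALSE)
  doc$compressor_config$intensity_codec <- "log10-zlib"
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA, null = "null")
  meta <- read_metadata(f)
  expect_error(read_block(meta, meta$indexes[[1]], out$aird),
               "codec mismatch|corrupt")
})

test_that("empty spectra occupy zero-length-decodable payloads", {
  run <- list(spectrum(numeric(0), numeric(0), rt = 0, ms_level = 1,
                       scan_num = 1),
              spectrum(c(100, 200), c(5, 6), rt = 1, ms_level = 1,
                       scan_num = 2))
  out <- write_run(run, mode = "COMMON")
  got <- read_all_spectra(out$meta, out$aird)
  expect_length(got[[1]]$mz, 0L)
  expect_equal(got[[2]]$intensity, c(5, 6))
  expect_error(write_aird(build_index_rt(run)["spectra"], tempdir(), "x"),
               class = "error")
  expect_error(build_index_rt(list()), "no spectra")
})
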
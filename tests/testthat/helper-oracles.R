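# Independent reference implementations and small utilities used as
# oracles. These deliberately share no code with the package internals.

# reference integer codec: 4-byte little-endian count, then every value as
# a plain variable-byte (7 bits per byte, high bit = continuation)
ref_vb_encode <- function(v) {
  bytes <- c(length(v) %% 256,
             (length(v) %/% 256) %% 256,
             (length(v) %/% 65536) %% 256,
             (length(v) %/% 16777216) %% 256)
  for (x in v) {
    repeat {
      lo7 <- x %% 128
      x <- (x - lo7) / 128
      bytes <- c(bytes, if (x > 0) lo7 + 128 else lo7)
      if (x == 0) break
    }
  }
  as.raw(bytes)
}

ref_vb_decode <- function(r) {
  b <- as.integer(r)
  n <- b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
  out <- numeric(n)
  pos <- 5
  for (i in seq_len(n)) {
    val <- 0; shift <- 1
    repeat {
      val <- val + (b[pos] %% 128) * shift
      cont <- b[pos] >= 128
      pos <- pos + 1
      if (!cont) break
      shift <- shift * 128
    }
    out[i] <- val
  }
  out
}

# value a float32 round trip would store
fl32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4), "numeric",
          n = length(x), size = 4)
}

# random sorted non-negative integer array with occasional large outliers
random_sorted_ints <- function(n, max_small = 1e4, outlier_frac = 0.05,
                               outlier_max = 2^28) {
  v <- runif(n, 0, max_small)
  n_out <- round(outlier_frac * n)
  if (n_out > 0) v[sample.int(n, n_out)] <- runif(n_out, 0, outlier_max)
  sort(floor(v))
}

scan_nums_of <- function(spectra) {
  sort(vapply(spectra, `[[`, integer(1), "scan_num"))
}

# write spectra to an aird pair under a temp dir, return meta + aird path
write_run <- function(spectra, mode = NULL, cfg = compressor_config(),
                      basename = "run") {
  if (is.null(mode)) mode <- detect_mode(spectra)
  plan <- build_index(spectra, mode)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- write_aird(plan, dir, basename, cfg)
  list(meta = read_metadata(paths$json), aird = paths$aird,
       json = paths$json, plan = plan)
}
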
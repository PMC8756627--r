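# The two-file container: a UTF-8 JSON metadata document ("<base>.json")
# and a binary block file ("<base>.aird"). The binary file is nothing but
# concatenated per-spectrum payloads — m/z payload then intensity payload —
# laid out in block order; all structure lives in the metadata's block
# index, so a reader can fetch one block (or one spectrum) with a single
# seek and read. Layout details: docs/format.md.

AIRD_VERSION <- "0.1.0"

block_names_required <- c("level", "start_ptr", "end_ptr", "scan_nums", "rts",
                          "mz_byte_sizes", "intensity_byte_sizes")
meta_names_required <- c("version", "acquisition_mode", "instrument",
                         "compressor_config", "ignore_zero_intensity",
                         "total_spectra", "indexes")

#' Write spectra and their index plan to an Aird file pair
#'
#' Compresses every spectrum (m/z with the ZDPD pipeline, intensity with
#' the configured codec), lays the payloads out block by block in
#' `<basename>.aird`, and writes `<basename>.json` with the full block
#' index: byte range per block plus per-spectrum scan numbers, retention
#' times and payload sizes, so both whole-block reads and single-spectrum
#' seeks need no scan of the binary file.
#'
#' @param plan An index plan from [build_index()] (or one of the
#'   `build_index_*` functions).
#' @param dir Output directory (created if missing).
#' @param basename File stem for the `.json`/`.aird` pair.
#' @param cfg A [compressor_config()].
#' @param instrument Free-form named list describing instrument/run.
#' @param ignore_zero_intensity Flag recorded in the metadata (the
#'   converter sets it to whether zero filtering ran).
#' @return Named list with elements `json` and `aird` (file paths).
#' @seealso [read_metadata()], [read_block()], [read_spectrum()]
#' @export
write_aird <- function(plan, dir, basename, cfg = compressor_config(),
                       instrument = list(), ignore_zero_intensity = TRUE) {
  stopifnot(inherits(plan, "aird_index_plan"), inherits(cfg, "compressor_config"))
  if (length(plan$spectra) == 0L) stop("no spectra to write", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  qc <- quant_config(cfg$mz_dp)

  payload_mz <- vector("list", length(plan$spectra))
  payload_int <- vector("list", length(plan$spectra))
  for (i in seq_along(plan$spectra)) {
    s <- plan$spectra[[i]]
    payload_mz[[i]] <- zdpd_encode(s$mz, qc, cfg$pfor, cfg$deflate_level)$data
    payload_int[[i]] <- intensity_encode(s$intensity, cfg)$data
  }

  offset <- 0
  blocks <- vector("list", length(plan$groups))
  chunks <- vector("list", length(plan$groups))
  for (g in seq_along(plan$groups)) {
    grp <- plan$groups[[g]]
    memb <- grp$members
    mz_sizes <- vapply(payload_mz[memb], length, integer(1))
    int_sizes <- vapply(payload_int[memb], length, integer(1))
    nbytes <- sum(mz_sizes) + sum(int_sizes)
    # DDA MS2 blocks: every child has its own precursor window, so record
    # them per spectrum; DIA blocks share the block-level window
    per_spec_windows <- NULL
    if (grp$level == 2L && is.null(grp$precursor_window))
      per_spec_windows <- lapply(plan$spectra[memb], `[[`, "precursor_window")
    blocks[[g]] <- list(
      level = grp$level,
      start_ptr = offset,
      end_ptr = offset + nbytes,
      scan_nums = vapply(plan$spectra[memb], `[[`, integer(1), "scan_num"),
      rts = vapply(plan$spectra[memb], `[[`, numeric(1), "rt"),
      mz_byte_sizes = as.integer(mz_sizes),
      intensity_byte_sizes = as.integer(int_sizes),
      precursor_window = grp$precursor_window,
      precursor_windows = per_spec_windows,
      parent_scan = grp$parent_scan)
    interleaved <- vector("list", 2L * length(memb))
    interleaved[seq(1L, by = 2L, length.out = length(memb))] <- payload_mz[memb]
    interleaved[seq(2L, by = 2L, length.out = length(memb))] <- payload_int[memb]
    chunks[[g]] <- do.call(c, interleaved)
    offset <- offset + nbytes
  }

  aird_path <- file.path(dir, paste0(basename, ".aird"))
  json_path <- file.path(dir, paste0(basename, ".json"))
  con <- file(aird_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(do.call(c, chunks), con)

  meta <- list(
    version = AIRD_VERSION,
    acquisition_mode = plan$mode,
    instrument = instrument,
    compressor_config = list(
      mz_dp = cfg$mz_dp,
      intensity_codec = cfg$intensity_codec,
      deflate_level = cfg$deflate_level,
      pfor = list(block_size = cfg$pfor$block_size,
                  exception_ratio = cfg$pfor$exception_ratio)),
    ignore_zero_intensity = ignore_zero_intensity,
    total_spectra = length(plan$spectra),
    indexes = blocks)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  list(json = json_path, aird = aird_path)
}

# coerce a simplify-free jsonlite list to a numeric/integer vector
.num <- function(x) as.numeric(unlist(x, use.names = FALSE))
.int <- function(x) as.integer(unlist(x, use.names = FALSE))

validate_block <- function(b, i) {
  missing <- setdiff(block_names_required, names(b))
  if (length(missing))
    stop(sprintf("metadata format error at indexes[%d]: missing field(s) %s",
                 i, paste(missing, collapse = ", ")), call. = FALSE)
  n <- length(b$scan_nums)
  lens <- c(rts = length(b$rts), mz = length(b$mz_byte_sizes),
            intensity = length(b$intensity_byte_sizes))
  if (any(lens != n))
    stop(sprintf("metadata format error at indexes[%d]: per-spectrum list lengths differ", i),
         call. = FALSE)
  if (b$end_ptr - b$start_ptr !=
      sum(b$mz_byte_sizes) + sum(b$intensity_byte_sizes))
    stop(sprintf("metadata format error at indexes[%d]: end_ptr - start_ptr does not equal the payload size sum", i),
         call. = FALSE)
  if (n > 1L && is.unsorted(b$rts))
    stop(sprintf("metadata format error at indexes[%d]: rts not sorted", i),
         call. = FALSE)
  if (!b$level %in% c(1, 2))
    stop(sprintf("metadata format error at indexes[%d]: level must be 1 or 2", i),
         call. = FALSE)
  invisible(b)
}

#' Read and validate an Aird JSON metadata document
#'
#' Parses the metadata, checks the structural schema (required fields,
#' consistent per-spectrum list lengths, block pointer arithmetic,
#' contiguous non-overlapping block tiling from byte 0, spectrum count),
#' and returns a validated object. Unknown extra keys are accepted with a
#' warning for forward compatibility.
#'
#' @param path Path to the `.json` metadata file.
#' @return An object of class `aird_metadata`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  extra <- setdiff(names(raw), meta_names_required)
  if (length(extra))
    warning("ignoring unknown metadata key(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  missing <- setdiff(meta_names_required, names(raw))
  if (length(missing))
    stop("metadata format error: missing field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  cc <- raw$compressor_config
  cfg <- compressor_config(mz_dp = cc$mz_dp,
                           intensity_codec = cc$intensity_codec,
                           deflate_level = cc$deflate_level,
                           pfor = pfor_params(cc$pfor$block_size,
                                              cc$pfor$exception_ratio))
  blocks <- lapply(seq_along(raw$indexes), function(i) {
    b <- raw$indexes[[i]]
    absent <- setdiff(block_names_required, names(b))
    if (length(absent))
      stop(sprintf("metadata format error at indexes[%d]: missing field(s) %s",
                   i, paste(absent, collapse = ", ")), call. = FALSE)
    blk <- list(level = .int(b$level),
                start_ptr = .num(b$start_ptr),
                end_ptr = .num(b$end_ptr),
                scan_nums = .int(b$scan_nums),
                rts = .num(b$rts),
                mz_byte_sizes = .num(b$mz_byte_sizes),
                intensity_byte_sizes = .num(b$intensity_byte_sizes),
                precursor_window = if (is.null(b$precursor_window)) NULL
                                   else .num(b$precursor_window),
                precursor_windows = if (is.null(b$precursor_windows)) NULL
                                    else lapply(b$precursor_windows, .num),
                parent_scan = if (is.null(b$parent_scan)) NULL
                              else .int(b$parent_scan))
    validate_block(blk, i)
  })
  ord <- order(vapply(blocks, `[[`, numeric(1), "start_ptr"))
  starts <- vapply(blocks[ord], `[[`, numeric(1), "start_ptr")
  ends <- vapply(blocks[ord], `[[`, numeric(1), "end_ptr")
  if (length(starts) && (starts[1] != 0 ||
      (length(starts) > 1L && any(starts[-1L] != ends[-length(ends)]))))
    stop("metadata format error: blocks do not tile the byte range contiguously",
         call. = FALSE)
  n_spectra <- sum(vapply(blocks, function(b) length(b$scan_nums), integer(1)))
  if (n_spectra != raw$total_spectra)
    stop("metadata format error: total_spectra does not match the block index",
         call. = FALSE)
  structure(list(version = as.character(raw$version),
                 acquisition_mode = as.character(raw$acquisition_mode),
                 instrument = raw$instrument,
                 compressor_config = cfg,
                 ignore_zero_intensity = isTRUE(raw$ignore_zero_intensity),
                 total_spectra = as.integer(raw$total_spectra),
                 indexes = blocks),
            class = "aird_metadata")
}

#' @export
print.aird_metadata <- function(x, ...) {
  n2 <- sum(vapply(x$indexes, function(b) b$level == 2L, logical(1)))
  cat(sprintf("<aird metadata v%s: %s, %d spectra, %d blocks (%d MS2 blocks), m/z dp=%d, intensity '%s'>\n",
              x$version, x$acquisition_mode, x$total_spectra,
              length(x$indexes), n2, x$compressor_config$mz_dp,
              x$compressor_config$intensity_codec))
  invisible(x)
}

# decode one spectrum from its raw payload bytes
decode_spectrum_raw <- function(mz_bytes, int_bytes, rt, scan_num, level,
                                window, cfg) {
  qc <- quant_config(cfg$mz_dp)
  mz <- zdpd_decode(encoded_payload("zdpd", mz_bytes), qc, cfg$pfor)
  ip <- encoded_payload(cfg$intensity_codec, int_bytes, length(mz))
  intensity <- intensity_decode(ip, cfg$intensity_codec)
  spectrum(mz, intensity, rt = rt, ms_level = level, scan_num = scan_num,
           precursor_window = window)
}

read_range <- function(aird_path, start, n) {
  con <- file(aird_path, "rb")
  on.exit(close(con), add = TRUE)
  seek(con, where = start, origin = "start")
  r <- readBin(con, "raw", n = n)
  if (length(r) != n)
    stop("short read: the .aird file is smaller than the index claims",
         call. = FALSE)
  r
}

#' Read one indexed block from the binary file
#'
#' Seeks to the block's start pointer, reads its byte range in one go, and
#' splits it into per-spectrum payloads using the size lists in the index.
#'
#' @param meta An [read_metadata()] object.
#' @param block One element of `meta$indexes`.
#' @param aird_path Path to the `.aird` binary file.
#' @return List of [spectrum()] objects, in block (RT) order.
#' @export
read_block <- function(meta, block, aird_path) {
  stopifnot(inherits(meta, "aird_metadata"))
  n <- length(block$scan_nums)
  bytes <- read_range(aird_path, block$start_ptr,
                      block$end_ptr - block$start_ptr)
  sizes <- as.vector(rbind(block$mz_byte_sizes, block$intensity_byte_sizes))
  ends <- cumsum(sizes)
  starts <- c(1, ends[-length(ends)] + 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    mzb <- bytes[seq2(starts[2 * i - 1], ends[2 * i - 1])]
    inb <- bytes[seq2(starts[2 * i], ends[2 * i])]
    win <- if (!is.null(block$precursor_windows)) block$precursor_windows[[i]]
           else block$precursor_window
    out[[i]] <- decode_spectrum_raw(mzb, inb, block$rts[i],
                                    block$scan_nums[i], block$level,
                                    win, meta$compressor_config)
  }
  out
}

# integer sequence that is empty when to < from (payloads can be 0 bytes)
seq2 <- function(from, to) if (to < from) integer(0) else seq.int(from, to)

#' Random access to a single spectrum by scan number
#'
#' Locates the owning block in the metadata index, computes the
#' within-block byte offset from the per-spectrum size lists, and reads
#' only that spectrum's payload bytes.
#'
#' @param meta An [read_metadata()] object.
#' @param scan_num Scan number to fetch.
#' @param aird_path Path to the `.aird` binary file.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(meta, scan_num, aird_path) {
  stopifnot(inherits(meta, "aird_metadata"))
  for (block in meta$indexes) {
    i <- match(scan_num, block$scan_nums)
    if (!is.na(i)) {
      pair <- block$mz_byte_sizes + block$intensity_byte_sizes
      off <- block$start_ptr + if (i > 1L) sum(pair[seq_len(i - 1L)]) else 0
      bytes <- read_range(aird_path, off, pair[i])
      mzb <- bytes[seq2(1, block$mz_byte_sizes[i])]
      inb <- bytes[seq2(block$mz_byte_sizes[i] + 1, pair[i])]
      win <- if (!is.null(block$precursor_windows)) block$precursor_windows[[i]]
             else block$precursor_window
      return(decode_spectrum_raw(mzb, inb, block$rts[i], scan_num,
                                 block$level, win,
                                 meta$compressor_config))
    }
  }
  stop("scan_num ", scan_num, " not present in this file", call. = FALSE)
}

#' Read every spectrum of an Aird file
#'
#' Convenience full read: concatenation of [read_block()] over all blocks.
#'
#' @inheritParams read_block
#' @return List of [spectrum()] objects in block order.
#' @export
read_all_spectra <- function(meta, aird_path) {
  do.call(c, lapply(meta$indexes, read_block, meta = meta,
                    aird_path = aird_path))
}
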
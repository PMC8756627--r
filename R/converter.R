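# mzML -> Aird conversion: parse, optional zero filtering, acquisition-mode
# detection, reordering/indexing, compression, container write.

#' Parse an mzML file into spectra
#'
#' Reads centroided or profile mzML 1.1 through the `mzR` (ProteoWizard)
#' backend: m/z and intensity arrays (plain or zlib-compressed, 32- or
#' 64-bit), MS level, retention time (normalized to seconds regardless of
#' the file's unit), scan number, and the precursor isolation window
#' (target minus lower offset, target plus upper offset) when present.
#'
#' @param path Path to an mzML file.
#' @return List with `spectra` (list of [spectrum()]) and `instrument`
#'   (named list descriptor).
#' @export
parse_mzml <- function(path) {
  if (!file.exists(path)) stop("mzML file not found: ", path, call. = FALSE)
  handle <- mzR::openMSfile(path, backend = "pwiz")
  on.exit(mzR::close(handle), add = TRUE)
  hd <- mzR::header(handle)
  instrument <- tryCatch(
    Filter(nzchar, lapply(mzR::instrumentInfo(handle), as.character)),
    error = function(e) list())
  spectra <- vector("list", nrow(hd))
  for (i in seq_len(nrow(hd))) {
    pk <- mzR::peaks(handle, i)
    lvl <- hd$msLevel[i]
    win <- NULL
    if (lvl >= 2L) {
      tgt <- hd$isolationWindowTargetMZ[i]
      if (!is.na(tgt)) {
        lo <- hd$isolationWindowLowerOffset[i]
        up <- hd$isolationWindowUpperOffset[i]
        if (is.na(lo)) lo <- 0
        if (is.na(up)) up <- 0
        win <- c(tgt - lo, tgt + up)
      } else if (!is.na(hd$precursorMZ[i])) {
        win <- c(hd$precursorMZ[i], hd$precursorMZ[i])
      } else {
        stop("MS2 spectrum without precursor information at scan index ", i,
             call. = FALSE)
      }
    }
    scan <- hd$acquisitionNum[i]
    if (is.na(scan)) scan <- hd$seqNum[i]
    mz <- pk[, 1]
    # pwiz may emit unsorted profile points; the format requires sorted m/z
    if (is.unsorted(mz)) {
      o <- order(mz); mz <- mz[o]; pk <- pk[o, , drop = FALSE]
    }
    spectra[[i]] <- spectrum(mz, pk[, 2], rt = hd$retentionTime[i],
                             ms_level = min(lvl, 2L), scan_num = scan,
                             precursor_window = win)
  }
  list(spectra = spectra, instrument = instrument)
}

#' Convert an mzML file to an Aird file pair
#'
#' Runs the full conversion workflow: parse the mzML, optionally drop
#' zero-intensity points, detect the acquisition mode (or honor an
#' override), reorder and index the spectra for that mode, compress every
#' spectrum with the configured codecs, and write the `.json`/`.aird`
#' pair. Partial outputs are removed if any step fails. Conversion is
#' deterministic: the same input and configuration produce byte-identical
#' outputs.
#'
#' @param in_path Input mzML path.
#' @param out_dir Output directory.
#' @param cfg A [compressor_config()].
#' @param mode `"auto"` (detect) or one of `"common"`, `"dda"`, `"dia"`,
#'   `"prm"`.
#' @param ignore_zero_intensity Drop zero-intensity pairs before
#'   compression (default `TRUE`).
#' @param basename Output file stem; default: input file name without
#'   extension.
#' @return Invisibly, a conversion report: paths, mode, spectrum counts
#'   per MS level, and byte totals before (raw 8-byte m/z + 8-byte
#'   intensity doubles) and after compression.
#' @export
convert <- function(in_path, out_dir, cfg = compressor_config(),
                    mode = "auto", ignore_zero_intensity = TRUE,
                    basename = NULL) {
  if (is.null(basename))
    basename <- sub("\\.[mM][zZ][mM][lL]$", "", base::basename(in_path))
  parsed <- parse_mzml(in_path)
  spectra <- parsed$spectra
  if (ignore_zero_intensity)
    spectra <- lapply(spectra, filter_zero_intensity)
  resolved <- detect_mode(spectra,
                          override = if (identical(mode, "auto")) NULL else mode)
  plan <- build_index(spectra, resolved)
  paths <- tryCatch(
    write_aird(plan, out_dir, basename, cfg,
               instrument = parsed$instrument,
               ignore_zero_intensity = ignore_zero_intensity),
    error = function(e) {
      unlink(file.path(out_dir, paste0(basename, c(".json", ".aird"))))
      stop(e)
    })
  levels <- vapply(spectra, `[[`, integer(1), "ms_level")
  n_points <- sum(vapply(spectra, function(s) length(s$mz), integer(1)))
  report <- list(json = paths$json, aird = paths$aird,
                 acquisition_mode = resolved,
                 n_ms1 = sum(levels == 1L), n_ms2 = sum(levels == 2L),
                 raw_bytes = 16 * n_points,
                 aird_bytes = file.size(paths$aird),
                 json_bytes = file.size(paths$json))
  invisible(report)
}
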
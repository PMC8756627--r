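# Deterministic synthetic runs. The generator reproduces the two digital
# features the codecs exploit: sorted m/z values arriving in tight clusters
# (small, similar deltas) and duplicate-heavy intensity arrays, as TOF
# instruments produce. It is first-class package code so every other module
# is testable without downloading real data.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# clustered sorted m/z: cluster centers uniform over the range, peaks sit
# within cluster_width (Da, sd) of their center
gen_clustered_mz <- function(n, mz_range, cluster_width) {
  if (n == 0L) return(numeric(0))
  n_clusters <- max(1L, ceiling(n / 5))
  centers <- runif(n_clusters, mz_range[1], mz_range[2])
  assign <- sample.int(n_clusters, n, replace = TRUE)
  mz <- centers[assign] + rnorm(n, 0, cluster_width)
  sort(pmin(pmax(mz, mz_range[1]), mz_range[2]))
}

# log-normal intensities with a requested share of duplicated values
gen_intensity <- function(n, duplicate_frac) {
  if (n == 0L) return(numeric(0))
  x <- rlnorm(n, meanlog = log(1e4), sdlog = 1.5)
  ndup <- round(duplicate_frac * n)
  if (ndup > 0L) {
    pool <- x[sample.int(n, max(1L, ceiling(ndup / 20)))]
    x[sample.int(n, ndup)] <- sample(pool, ndup, replace = TRUE)
  }
  x
}

inject_peak <- function(mz, intensity, peak_mz, peak_intensity) {
  i <- findInterval(peak_mz, mz)
  list(mz = append(mz, peak_mz, after = i),
       intensity = append(intensity, peak_intensity, after = i))
}

#' Generate a deterministic synthetic MS run
#'
#' Emulates the statistical structure of real centroided runs at the level
#' the codecs and indexes care about: per-spectrum m/z values drawn as
#' cluster centers plus small within-cluster offsets (so sorted arrays have
#' many tiny deltas), log-normal intensities with a controllable share of
#' exact duplicates, monotone retention times, and acquisition-mode
#' structure (DDA: each MS1 followed by its MS2 children with unique
#' precursor windows; DIA: a repeating schedule of `n_windows` isolation
#' windows per cycle). It does not emulate isotope envelopes or realistic
#' peak shapes; an optional Gaussian elution profile can be injected for
#' chromatogram tests.
#'
#' @param mode `"common"` (MS1 only), `"dda"`, or `"dia"`.
#' @param n_ms1 Number of MS1 spectra (DIA: number of cycles).
#' @param ms2_per_ms1 DDA: MS2 children per MS1.
#' @param n_windows DIA: isolation windows per cycle, tiling
#'   `precursor_range`.
#' @param peaks_per_spectrum Peaks in each spectrum.
#' @param mz_range Fragment m/z range in Da, within `[0, 3000]`.
#' @param precursor_range Precursor m/z range for isolation windows (Da).
#' @param cluster_width Within-cluster m/z spread (Da, standard deviation).
#' @param duplicate_intensity_frac Requested share of duplicated intensity
#'   values per spectrum, in `[0, 1)`.
#' @param rt_step Seconds between successive acquisition cycles.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param elution Optional `list(mz=, rt_center=, rt_sigma=, height=,
#'   level=)`: inject one peak at `mz` into every spectrum of `level`, with
#'   a Gaussian intensity profile over retention time.
#' @return A list of [spectrum()] objects in acquisition order
#'   (`scan_num` 1, 2, ...).
#' @examples
#' run <- generate_run("dia", n_ms1 = 3, n_windows = 4,
#'                     peaks_per_spectrum = 50, seed = 7)
#' run[[2]]
#' @export
generate_run <- function(mode = c("common", "dda", "dia"),
                         n_ms1 = 10L,
                         ms2_per_ms1 = 3L,
                         n_windows = 8L,
                         peaks_per_spectrum = 200L,
                         mz_range = c(100, 1500),
                         precursor_range = c(400, 1200),
                         cluster_width = 0.02,
                         duplicate_intensity_frac = 0.3,
                         rt_step = 2,
                         seed = 1L,
                         elution = NULL) {
  mode <- match.arg(mode)
  if (n_ms1 < 1L || peaks_per_spectrum < 0L)
    stop("n_ms1 must be >= 1 and peaks_per_spectrum >= 0", call. = FALSE)
  if (mz_range[1] < 0 || mz_range[2] > 3000 || mz_range[1] >= mz_range[2])
    stop("mz_range must be increasing and within [0, 3000]", call. = FALSE)
  if (duplicate_intensity_frac < 0 || duplicate_intensity_frac >= 1)
    stop("duplicate_intensity_frac must be in [0, 1)", call. = FALSE)

  with_seed(seed, {
    events_per_cycle <- switch(mode, common = 1L,
                               dda = 1L + as.integer(ms2_per_ms1),
                               dia = 1L + as.integer(n_windows))
    dia_edges <- seq(precursor_range[1], precursor_range[2],
                     length.out = n_windows + 1L)
    spectra <- vector("list", n_ms1 * events_per_cycle)
    scan <- 0L
    for (cyc in seq_len(n_ms1)) {
      rt0 <- (cyc - 1L) * rt_step
      dt <- rt_step / events_per_cycle
      make <- function(level, window, rt) {
        mz <- gen_clustered_mz(peaks_per_spectrum, mz_range, cluster_width)
        it <- gen_intensity(peaks_per_spectrum, duplicate_intensity_frac)
        if (!is.null(elution) &&
            (is.null(elution$level) || elution$level == level)) {
          h <- elution$height *
            exp(-(rt - elution$rt_center)^2 / (2 * elution$rt_sigma^2))
          p <- inject_peak(mz, it, elution$mz, h)
          mz <- p$mz; it <- p$intensity
        }
        scan <<- scan + 1L
        spectrum(mz, it, rt = rt, ms_level = level, scan_num = scan,
                 precursor_window = window)
      }
      sp <- make(1L, NULL, rt0)
      spectra[[sp$scan_num]] <- sp
      if (mode == "dda") {
        for (j in seq_len(ms2_per_ms1)) {
          tgt <- runif(1, precursor_range[1], precursor_range[2])
          sp <- make(2L, c(tgt - 0.5, tgt + 0.5), rt0 + j * dt)
          spectra[[sp$scan_num]] <- sp
        }
      } else if (mode == "dia") {
        for (j in seq_len(n_windows)) {
          sp <- make(2L, c(dia_edges[j], dia_edges[j + 1L]), rt0 + j * dt)
          spectra[[sp$scan_num]] <- sp
        }
      }
    }
    spectra
  })
}

## ---- minimal mzML writer (fixture generator) ----------------------------

b64_array <- function(x, bytes, zlib) {
  r <- writeBin(as.double(x), raw(), size = bytes, endian = "little")
  if (zlib) r <- deflate_bytes(r, 6L)
  gsub("\n", "", jsonlite::base64_enc(r), fixed = TRUE)  # un-wrap long lines
}

mzml_binary_array <- function(x, bytes, zlib, kind) {
  enc <- b64_array(x, bytes, zlib)
  prec <- if (bytes == 8L)
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>'
  comp <- if (zlib)
    '<cvParam cvRef="MS" accession="MS:1000574" name="zlib compression"/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>'
  arr <- if (kind == "mz")
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>'
  sprintf('<binaryDataArray encodedLength="%d">%s%s%s<binary>%s</binary></binaryDataArray>',
          nchar(enc), prec, comp, arr, enc)
}

mzml_spectrum <- function(s, index, zlib, rt_unit, mz_bytes, int_bytes) {
  rt_val <- if (rt_unit == "minute") s$rt / 60 else s$rt
  rt_cv <- sprintf('<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.10g" unitCvRef="UO" unitAccession="%s" unitName="%s"/>',
                   rt_val,
                   if (rt_unit == "minute") "UO:0000031" else "UO:0000010",
                   rt_unit)
  prec <- ""
  if (s$ms_level == 2L) {
    lo <- s$precursor_window[1]; up <- s$precursor_window[2]
    tgt <- (lo + up) / 2
    prec <- sprintf(paste0(
      '<precursorList count="1"><precursor><isolationWindow>',
      '<cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%.10g" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '<cvParam cvRef="MS" accession="MS:1000828" name="isolation window lower offset" value="%.10g" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '<cvParam cvRef="MS" accession="MS:1000829" name="isolation window upper offset" value="%.10g" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '</isolationWindow><selectedIonList count="1"><selectedIon>',
      '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.10g" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '</selectedIon></selectedIonList><activation>',
      '<cvParam cvRef="MS" accession="MS:1000044" name="dissociation method"/>',
      '</activation></precursor></precursorList>'),
      tgt, tgt - lo, up - tgt, tgt)
  }
  sprintf(paste0(
    '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>',
    '<scanList count="1"><scan>%s</scan></scanList>%s',
    '<binaryDataArrayList count="2">%s%s</binaryDataArrayList></spectrum>'),
    index, s$scan_num, length(s$mz), s$ms_level, rt_cv, prec,
    mzml_binary_array(s$mz, mz_bytes, zlib, "mz"),
    mzml_binary_array(s$intensity, int_bytes, zlib, "intensity"))
}

#' Write spectra to a minimal mzML 1.1 file
#'
#' Emits a small, schema-shaped (non-indexed) mzML document sufficient for
#' any compliant reader: per-spectrum MS level, scan start time, precursor
#' isolation window, and base64 binary data arrays (optionally
#' zlib-compressed). Defaults mirror common converter settings: 64-bit m/z,
#' 32-bit intensity, retention time written in minutes. This is a fixture
#' generator for converter tests, not a general-purpose mzML exporter.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output file path.
#' @param compress_arrays Write binary arrays zlib-compressed.
#' @param rt_unit `"minute"` (default, exercises the reader's unit
#'   conversion) or `"second"`.
#' @param mz_bytes 8 (64-bit, default) or 4 bytes per m/z value.
#' @param intensity_bytes 4 (32-bit, default) or 8 bytes per intensity.
#' @return `path`, invisibly.
#' @seealso [parse_mzml()]
#' @export
write_toy_mzml <- function(spectra, path, compress_arrays = FALSE,
                           rt_unit = c("minute", "second"),
                           mz_bytes = 8L, intensity_bytes = 4L) {
  rt_unit <- match.arg(rt_unit)
  stopifnot(length(spectra) > 0L, mz_bytes %in% c(4L, 8L),
            intensity_bytes %in% c(4L, 8L))
  body <- vapply(seq_along(spectra), function(i) {
    mzml_spectrum(spectra[[i]], i - 1L, compress_arrays, rt_unit,
                  mz_bytes, intensity_bytes)
  }, character(1))
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="UNIT-ONTOLOGY" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>',
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sw" version="0.1">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="airdlite"/>',
    '</software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model"/>',
    '</instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="sw">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    '<spectrumList count="%d" defaultDataProcessingRef="dp1">\n%s\n',
    '</spectrumList></run></mzML>\n'),
    length(spectra), paste(body, collapse = "\n"))
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}
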
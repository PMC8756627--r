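#' Construct a mass spectrum
#'
#' One mass-analyzer scan: paired m/z and intensity arrays acquired at a
#' retention time. MS2 spectra carry the precursor isolation window whose
#' ions were fragmented.
#'
#' @param mz Numeric m/z array (Da), sorted non-decreasing.
#' @param intensity Numeric intensity array, same length as `mz`.
#' @param rt Retention time in seconds.
#' @param ms_level 1 or 2.
#' @param scan_num Integer scan number, unique within a run.
#' @param precursor_window For `ms_level = 2`, `c(lower, upper)` in Da.
#' @return An object of class `aird_spectrum`.
#' @examples
#' spectrum(c(100.1, 250.2), c(1500, 800), rt = 12.5, ms_level = 1,
#'          scan_num = 1)
#' @export
spectrum <- function(mz, intensity, rt, ms_level = 1L, scan_num,
                     precursor_window = NULL) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length", call. = FALSE)
  if (length(mz) && is.unsorted(mz))
    stop("mz must be sorted non-decreasing", call. = FALSE)
  ms_level <- as.integer(ms_level)
  if (!ms_level %in% c(1L, 2L)) stop("ms_level must be 1 or 2", call. = FALSE)
  if (ms_level == 2L) {
    if (is.null(precursor_window) || length(precursor_window) != 2L ||
        precursor_window[1] > precursor_window[2])
      stop("ms_level 2 requires precursor_window = c(lower, upper), lower <= upper",
           call. = FALSE)
    precursor_window <- as.numeric(precursor_window)
  } else {
    precursor_window <- NULL
  }
  structure(list(mz = mz, intensity = intensity, rt = as.numeric(rt),
                 ms_level = ms_level, scan_num = as.integer(scan_num),
                 precursor_window = precursor_window),
            class = "aird_spectrum")
}

#' @export
print.aird_spectrum <- function(x, ...) {
  win <- if (is.null(x$precursor_window)) "" else
    sprintf(", window [%.4f, %.4f]", x$precursor_window[1], x$precursor_window[2])
  cat(sprintf("<spectrum #%d MS%d, rt %.3f s, %d peaks%s>\n",
              x$scan_num, x$ms_level, x$rt, length(x$mz), win))
  invisible(x)
}

#' Drop zero-intensity peaks from a spectrum
#'
#' Most computation never touches zero-intensity points (profile-mode
#' baselines), so the converter removes them by default before compression.
#' Order is preserved; a spectrum that becomes empty is kept with zero
#' peaks so scan numbering and the RT trace stay complete.
#'
#' @param s An [spectrum()].
#' @return The spectrum with all `intensity == 0` pairs removed.
#' @export
filter_zero_intensity <- function(s) {
  stopifnot(inherits(s, "aird_spectrum"))
  keep <- s$intensity != 0
  if (all(keep)) return(s)
  s$mz <- s$mz[keep]
  s$intensity <- s$intensity[keep]
  s
}
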
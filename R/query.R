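# Indexed reads the block structure exists to serve. Every query touches
# only the blocks whose index entry can match, then decodes and filters.

#' Retrieve spectra in a retention-time range
#'
#' Decodes only the blocks of the requested MS level whose RT span
#' intersects `[rt_lo, rt_hi]` (closed interval), then filters and returns
#' the spectra RT-ordered.
#'
#' @param meta An [read_metadata()] object.
#' @param aird_path Path to the `.aird` file.
#' @param rt_lo,rt_hi Retention-time bounds in seconds, `rt_lo <= rt_hi`.
#' @param level MS level to retrieve (default 1).
#' @return List of [spectrum()] objects (possibly empty).
#' @export
spectra_in_rt_range <- function(meta, aird_path, rt_lo, rt_hi, level = 1L) {
  stopifnot(inherits(meta, "aird_metadata"), rt_lo <= rt_hi)
  hits <- list()
  for (block in meta$indexes) {
    if (block$level != level || length(block$rts) == 0L) next
    if (max(block$rts) < rt_lo || min(block$rts) > rt_hi) next
    sp <- read_block(meta, block, aird_path)
    keep <- vapply(sp, function(s) s$rt >= rt_lo && s$rt <= rt_hi, logical(1))
    hits <- c(hits, sp[keep])
  }
  rts <- vapply(hits, `[[`, numeric(1), "rt")
  scans <- vapply(hits, `[[`, integer(1), "scan_num")
  hits[order(rts, scans)]
}

#' Retrieve the MS2 spectra of one isolation window
#'
#' DIA/PRM files group all MS2 spectra of an isolation window into one
#' block; this fetches that block. The window is matched by its
#' `(lower, upper)` pair within a 1e-6 Da tolerance.
#'
#' @param meta An [read_metadata()] object.
#' @param aird_path Path to the `.aird` file.
#' @param lower,upper Isolation window bounds in Da.
#' @return List of [spectrum()] objects, RT-ordered.
#' @export
spectra_for_window <- function(meta, aird_path, lower, upper) {
  stopifnot(inherits(meta, "aird_metadata"))
  for (block in meta$indexes) {
    w <- block$precursor_window
    if (block$level == 2L && !is.null(w) &&
        abs(w[1] - lower) <= WINDOW_TOL && abs(w[2] - upper) <= WINDOW_TOL)
      return(read_block(meta, block, aird_path))
  }
  avail <- Filter(Negate(is.null),
                  lapply(meta$indexes, `[[`, "precursor_window"))
  stop(sprintf("no isolation window [%g, %g] in this file; available: %s",
               lower, upper,
               if (length(avail))
                 paste(vapply(avail, function(w) sprintf("[%g, %g]", w[1], w[2]),
                              character(1)), collapse = " ")
               else "(none)"),
       call. = FALSE)
}

# summed intensity of peaks with mz in [lo, hi] (closed), binary search on
# the sorted array
sum_in_window <- function(mz, intensity, lo, hi) {
  if (length(mz) == 0L) return(0)
  i_lo <- findInterval(lo, mz, left.open = TRUE) + 1L  # first mz >= lo
  i_hi <- findInterval(hi, mz)                         # last mz <= hi
  if (i_hi < i_lo) 0 else sum(intensity[i_lo:i_hi])
}

#' Extract an ion chromatogram
#'
#' For every selected spectrum, sums the intensities of peaks whose m/z
#' lies in the closed interval `target_mz * (1 +/- ppm_tol * 1e-6)` (ppm
#' defined relative to the target mass), located by binary search on the
#' sorted m/z array. Spectra with no matching peak contribute 0, so the
#' trace has one point per selected spectrum.
#'
#' @param meta An [read_metadata()] object.
#' @param aird_path Path to the `.aird` file.
#' @param target_mz Target m/z in Da.
#' @param ppm_tol Mass tolerance in ppm, > 0.
#' @param rt_range Optional `c(lo, hi)` in seconds; default: all spectra.
#' @param level MS level to trace (default 1).
#' @param window For `level = 2` on a DIA/PRM file: the isolation window
#'   `c(lower, upper)` to trace in. Required there, since the target ion
#'   appears once per window; omitting it would mix schedules.
#' @return List with numeric vectors `rt` and `intensity`, aligned.
#' @examples
#' \dontrun{
#' trace <- xic(meta, aird, target_mz = 522.1, ppm_tol = 20)
#' plot(trace$rt, trace$intensity, type = "l")
#' }
#' @export
xic <- function(meta, aird_path, target_mz, ppm_tol, rt_range = NULL,
                level = 1L, window = NULL) {
  stopifnot(inherits(meta, "aird_metadata"), ppm_tol > 0)
  if (is.null(rt_range)) rt_range <- c(-Inf, Inf)
  if (level == 2L && is.null(window) &&
      meta$acquisition_mode %in% c("DIA", "PRM"))
    stop("level-2 chromatogram on a DIA/PRM file needs an isolation window",
         call. = FALSE)
  spectra <- if (!is.null(window)) {
    sp <- spectra_for_window(meta, aird_path, window[1], window[2])
    Filter(function(s) s$rt >= rt_range[1] && s$rt <= rt_range[2], sp)
  } else {
    spectra_in_rt_range(meta, aird_path, rt_range[1], rt_range[2], level)
  }
  lo <- target_mz * (1 - ppm_tol * 1e-6)
  hi <- target_mz * (1 + ppm_tol * 1e-6)
  list(rt = vapply(spectra, `[[`, numeric(1), "rt"),
       intensity = vapply(spectra, function(s)
         sum_in_window(s$mz, s$intensity, lo, hi), numeric(1)))
}
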
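# Acquisition-mode-specific spectrum reordering. Each strategy returns an
# "index plan": the reordered spectrum list plus block groups (level,
# member positions, and for DIA the precursor window; for DDA the parent
# scan). The container writer turns groups into byte-addressed BlockIndex
# entries.

WINDOW_TOL <- 1e-6  # Da; absorbs float jitter in repeated SWATH schedules

new_index_plan <- function(spectra, groups, mode) {
  structure(list(spectra = spectra, groups = groups, mode = mode),
            class = "aird_index_plan")
}

#' @export
print.aird_index_plan <- function(x, ...) {
  cat(sprintf("<index plan: %s, %d spectra, %d blocks>\n",
              x$mode, length(x$spectra), length(x$groups)))
  invisible(x)
}

order_by_rt <- function(spectra) {
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  scans <- vapply(spectra, `[[`, integer(1), "scan_num")
  order(rts, scans)   # tie-break: scan_num ascending
}

#' RT-linear index (traditional mzXML/mzML-style ordering)
#'
#' Sorts all spectra by retention time (ties broken by scan number) and
#' cuts the sequence into blocks of at most `max_block_spectra`, bounding
#' the memory needed for a single block read.
#'
#' @param spectra List of [spectrum()] objects.
#' @param max_block_spectra Block size cap (default 1024).
#' @return An index plan: reordered spectra plus block groups.
#' @export
build_index_rt <- function(spectra, max_block_spectra = 1024L) {
  if (length(spectra) == 0L) stop("no spectra to index", call. = FALSE)
  ord <- order_by_rt(spectra)
  spectra <- spectra[ord]
  starts <- seq(1L, length(spectra), by = max_block_spectra)
  groups <- lapply(starts, function(s) {
    list(level = 1L, members = s:min(s + max_block_spectra - 1L, length(spectra)),
         precursor_window = NULL, parent_scan = NULL)
  })
  new_index_plan(spectra, groups, "COMMON")
}

#' DDA index: MS1 group + per-parent MS2 groups
#'
#' All MS1 spectra go into one level-1 block in RT order (successive MS1
#' scans are what chromatogram extraction reads); the MS2 children of each
#' MS1 form one level-2 block, tagged with the parent scan number. Children
#' are attached to the most recent preceding MS1 in input order, the mzML
#' convention. Parents without children contribute no MS2 block.
#'
#' @param spectra List of [spectrum()] objects in acquisition order.
#' @return An index plan.
#' @export
build_index_dda <- function(spectra) {
  if (length(spectra) == 0L) stop("no spectra to index", call. = FALSE)
  levels <- vapply(spectra, `[[`, integer(1), "ms_level")
  parent <- integer(length(spectra))   # input position of owning MS1
  cur <- 0L
  for (i in seq_along(spectra)) {
    if (levels[i] == 1L) cur <- i
    else {
      if (cur == 0L) stop("orphan MS2 spectrum before any MS1", call. = FALSE)
      parent[i] <- cur
    }
  }
  ms1_pos <- which(levels == 1L)
  ms1_ord <- ms1_pos[order_by_rt(spectra[ms1_pos])]
  ordered <- spectra[ms1_ord]
  groups <- list(list(level = 1L, members = seq_along(ms1_ord),
                      precursor_window = NULL, parent_scan = NULL))
  nxt <- length(ms1_ord)
  for (p in ms1_ord) {
    kids <- which(parent == p)
    if (length(kids) == 0L) next
    kids <- kids[order_by_rt(spectra[kids])]
    ordered <- c(ordered, spectra[kids])
    groups[[length(groups) + 1L]] <-
      list(level = 2L, members = nxt + seq_along(kids),
           precursor_window = NULL, parent_scan = spectra[[p]]$scan_num)
    nxt <- nxt + length(kids)
  }
  new_index_plan(ordered, groups, "DDA")
}

# match a window against known keys within tolerance; 0 if new
match_window <- function(win, keys) {
  for (k in seq_along(keys)) {
    if (abs(win[1] - keys[[k]][1]) <= WINDOW_TOL &&
        abs(win[2] - keys[[k]][2]) <= WINDOW_TOL) return(k)
  }
  0L
}

#' DIA/SWATH index: MS1 group + per-isolation-window MS2 groups
#'
#' All MS1 spectra form one level-1 block in RT order. MS2 spectra are
#' partitioned by their precursor isolation window — exact `(lower, upper)`
#' match within a 1e-6 Da tolerance — one level-2 block per distinct
#' window, members RT-ordered. Window blocks are emitted in ascending
#' `(lower, upper)` order, so the grouping is invariant to input order.
#' PRM runs use this same path: fixed precursor targets behave as windows.
#'
#' @param spectra List of [spectrum()] objects.
#' @return An index plan.
#' @export
build_index_dia <- function(spectra) {
  if (length(spectra) == 0L) stop("no spectra to index", call. = FALSE)
  levels <- vapply(spectra, `[[`, integer(1), "ms_level")
  ms2_pos <- which(levels == 2L)
  for (i in ms2_pos) {
    if (is.null(spectra[[i]]$precursor_window))
      stop(sprintf("MS2 spectrum #%d has no precursor isolation window",
                   spectra[[i]]$scan_num), call. = FALSE)
  }
  keys <- list(); assign <- integer(length(ms2_pos))
  for (j in seq_along(ms2_pos)) {
    win <- spectra[[ms2_pos[j]]]$precursor_window
    k <- match_window(win, keys)
    if (k == 0L) { keys[[length(keys) + 1L]] <- win; k <- length(keys) }
    assign[j] <- k
  }
  key_ord <- order(vapply(keys, `[`, numeric(1), 1L),
                   vapply(keys, `[`, numeric(1), 2L))
  ms1_pos <- which(levels == 1L)
  ms1_ord <- ms1_pos[order_by_rt(spectra[ms1_pos])]
  ordered <- spectra[ms1_ord]
  groups <- list(list(level = 1L, members = seq_along(ms1_ord),
                      precursor_window = NULL, parent_scan = NULL))
  nxt <- length(ms1_ord)
  for (k in key_ord) {
    memb <- ms2_pos[assign == k]
    memb <- memb[order_by_rt(spectra[memb])]
    ordered <- c(ordered, spectra[memb])
    groups[[length(groups) + 1L]] <-
      list(level = 2L, members = nxt + seq_along(memb),
           precursor_window = keys[[k]], parent_scan = NULL)
    nxt <- nxt + length(memb)
  }
  new_index_plan(ordered, groups, "DIA")
}

#' Guess the acquisition mode of a run
#'
#' `COMMON` if there are no MS2 spectra; `DIA` if the distinct MS2
#' isolation windows form a small recurring schedule (at most 200 windows,
#' each seen at least 3 times); otherwise `DDA`. An explicit user override
#' always wins over the heuristic.
#'
#' @param spectra List of [spectrum()] objects.
#' @param override `NULL`, or one of `"COMMON"`, `"DDA"`, `"DIA"`, `"PRM"`.
#' @return The mode string.
#' @export
detect_mode <- function(spectra, override = NULL) {
  if (!is.null(override)) {
    override <- toupper(override)
    if (!override %in% c("COMMON", "DDA", "DIA", "PRM"))
      stop("unknown acquisition mode: ", override, call. = FALSE)
    return(override)
  }
  if (length(spectra) == 0L) stop("no spectra", call. = FALSE)
  levels <- vapply(spectra, `[[`, integer(1), "ms_level")
  ms2 <- which(levels == 2L)
  if (length(ms2) == 0L) return("COMMON")
  keys <- list(); counts <- integer(0)
  for (i in ms2) {
    win <- spectra[[i]]$precursor_window
    if (is.null(win)) return("DDA")   # windowless MS2 cannot be DIA
    k <- match_window(win, keys)
    if (k == 0L) { keys[[length(keys) + 1L]] <- win; counts <- c(counts, 1L) }
    else counts[k] <- counts[k] + 1L
  }
  if (length(keys) <= 200L && all(counts >= 3L)) "DIA" else "DDA"
}

#' Build an index plan for a given acquisition mode
#'
#' @param spectra List of [spectrum()] objects.
#' @param mode `"COMMON"`, `"DDA"`, `"DIA"` or `"PRM"` (PRM shares the DIA
#'   grouping path).
#' @param max_block_spectra Block cap for the COMMON strategy.
#' @return An index plan.
#' @export
build_index <- function(spectra, mode, max_block_spectra = 1024L) {
  mode <- toupper(mode)
  plan <- switch(mode,
                 COMMON = build_index_rt(spectra, max_block_spectra),
                 DDA = build_index_dda(spectra),
                 DIA = build_index_dia(spectra),
                 PRM = build_index_dia(spectra),
                 stop("unknown acquisition mode: ", mode, call. = FALSE))
  plan$mode <- mode
  plan
}
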
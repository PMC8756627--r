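# Reordering / block-building strategies and mode detection.

test_that("RT-linear indexing sorts, chunks and is idempotent", {
  run <- generate_run("common", n_ms1 = 25, peaks_per_spectrum = 5, seed = 2)
  shuffled <- run[sample(seq_along(run))]
  plan <- build_index_rt(shuffled, max_block_spectra = 10L)
  rts <- vapply(plan$spectra, `[[`, numeric(1), "rt")
  expect_false(is.unsorted(rts))
  expect_identical(scan_nums_of(plan$spectra), scan_nums_of(run))
  expect_length(plan$groups, 3L)              # 10 + 10 + 5
  expect_equal(vapply(plan$groups, function(g) length(g$members), integer(1)),
               c(10L, 10L, 5L))
  # already-ordered input: same order out
  plan2 <- build_index_rt(plan$spectra, max_block_spectra = 10L)
  expect_identical(plan2$spectra, plan$spectra)
  expect_identical(plan2$groups, plan$groups)
})

test_that("equal retention times break ties by scan number", {
  s <- lapply(c(3L, 1L, 2L), function(k)
    spectrum(100, 1, rt = 5, ms_level = 1, scan_num = k))
  plan <- build_index_rt(s)
  expect_equal(vapply(plan$spectra, `[[`, integer(1), "scan_num"), 1:3)
})

test_that("DDA grouping: one MS1 block, one MS2 block per parent with children", {
  mk <- function(scan, level, rt, win = NULL)
    spectrum(100 + scan, scan, rt = rt, ms_level = level, scan_num = scan,
             precursor_window = win)
  # [MS1a, MS2a1, MS2a2, MS1b, MS2b1]
  run <- list(mk(1, 1, 0), mk(2, 2, 1, c(400, 401)), mk(3, 2, 2, c(500, 501)),
              mk(4, 1, 3), mk(5, 2, 4, c(600, 601)))
  plan <- build_index_dda(run)
  expect_length(plan$groups, 3L)
  g <- plan$groups
  expect_equal(g[[1]]$level, 1L)
  expect_equal(vapply(plan$spectra[g[[1]]$members], `[[`, integer(1),
                      "scan_num"), c(1L, 4L))
  expect_equal(vapply(plan$spectra[g[[2]]$members], `[[`, integer(1),
                      "scan_num"), c(2L, 3L))
  expect_equal(g[[2]]$parent_scan, 1L)
  expect_equal(vapply(plan$spectra[g[[3]]$members], `[[`, integer(1),
                      "scan_num"), 5L)
  expect_equal(g[[3]]$parent_scan, 4L)
  expect_identical(scan_nums_of(plan$spectra), 1:5)
})

test_that("MS1-only input yields a single level-1 block; orphan MS2 errors", {
  run <- generate_run("common", n_ms1 = 6, peaks_per_spectrum = 5, seed = 4)
  plan <- build_index_dda(run)
  expect_length(plan$groups, 1L)
  expect_equal(plan$groups[[1]]$level, 1L)

  orphan <- list(spectrum(100, 1, rt = 0, ms_level = 2, scan_num = 1,
                          precursor_window = c(400, 425)))
  expect_error(build_index_dda(orphan), "orphan")
})

test_that("DIA grouping partitions MS2 spectra by isolation window", {
  run <- generate_run("dia", n_ms1 = 3, n_windows = 2, peaks_per_spectrum = 10,
                      seed = 6)
  plan <- build_index_dia(run)
  expect_length(plan$groups, 3L)              # 1 MS1 + 2 windows
  expect_equal(vapply(plan$groups, `[[`, integer(1), "level"), c(1L, 2L, 2L))
  expect_equal(vapply(plan$groups[2:3], function(g) length(g$members),
                      integer(1)), c(3L, 3L))
  expect_identical(scan_nums_of(plan$spectra), scan_nums_of(run))
  # each MS2 scan lands in exactly one window block
  ms2_members <- unlist(lapply(plan$groups[2:3], `[[`, "members"))
  expect_identical(sort(ms2_members), seq(4L, 9L))

  # grouping invariant to input order
  plan_shuffled <- build_index_dia(run[rev(seq_along(run))])
  expect_identical(lapply(plan_shuffled$spectra, `[[`, "scan_num"),
                   lapply(plan$spectra, `[[`, "scan_num"))
})

test_that("overlapping but distinct window pairs form distinct blocks", {
  mk <- function(scan, win) spectrum(100, 1, rt = scan, ms_level = 2,
                                     scan_num = scan, precursor_window = win)
  run <- list(spectrum(100, 1, rt = 0, ms_level = 1, scan_num = 1),
              mk(2, c(400, 425)), mk(3, c(412.5, 437.5)),
              mk(4, c(400, 425)), mk(5, c(412.5, 437.5)))
  plan <- build_index_dia(run)
  wins <- Filter(Negate(is.null), lapply(plan$groups, `[[`, "precursor_window"))
  expect_length(wins, 2L)
  # jitter below the 1e-6 Da tolerance maps to the same key
  runj <- c(run, list(mk(6, c(400 + 5e-7, 425 - 5e-7))))
  planj <- build_index_dia(runj)
  winsj <- Filter(Negate(is.null), lapply(planj$groups, `[[`, "precursor_window"))
  expect_length(winsj, 2L)
})

test_that("MS2 without an isolation window is a metadata error in DIA", {
  s2 <- spectrum(100, 1, rt = 1, ms_level = 2, scan_num = 2,
                 precursor_window = c(400, 425))
  s2$precursor_window <- NULL               # simulate a parser gap
  run <- list(spectrum(100, 1, rt = 0, ms_level = 1, scan_num = 1), s2)
  expect_error(build_index_dia(run), "isolation window")
})

test_that("acquisition mode detection follows the schedule heuristic", {
  ms1 <- generate_run("common", n_ms1 = 5, peaks_per_spectrum = 5, seed = 8)
  expect_equal(detect_mode(ms1), "COMMON")
  swath <- generate_run("dia", n_ms1 = 10, n_windows = 32,
                        peaks_per_spectrum = 5, seed = 8)
  expect_equal(detect_mode(swath), "DIA")
  dda <- generate_run("dda", n_ms1 = 8, ms2_per_ms1 = 5,
                      peaks_per_spectrum = 5, seed = 8)
  expect_equal(detect_mode(dda), "DDA")
  # explicit override always wins
  expect_equal(detect_mode(swath, override = "PRM"), "PRM")
  expect_error(detect_mode(list()), "no spectra")
})
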
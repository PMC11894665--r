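make_psm <- function(sequence, mods = "", q = 0.001, run = "r1", exp = "e1",
                     err = 0, scan = 1L, charge = 2L) {
  data.frame(collection_id = "C1", dataset_id = "D1", experiment_id = exp,
             run_id = run, scan = scan, sequence = sequence, mods = mods,
             charge = charge, mass_error_da = err, q_value = q,
             instrument = NA_character_, stringsAsFactors = FALSE)
}

test_that("modification strings parse and round-trip", {
  m <- parse_mods("7-S-Phospho;10-Y-Phospho", "VHNDAQSFDYDHDAFLGAEEAK")
  expect_equal(m$position, c(7L, 10L))
  expect_equal(m$residue, c("S", "Y"))
  expect_equal(m$name, c("Phospho", "Phospho"))
  expect_equal(format_mods(m), "7-S-Phospho;10-Y-Phospho")
  expect_equal(nrow(parse_mods("")), 0L)
  # residue mismatch is an error
  expect_error(parse_mods("7-Y-Phospho", "VHNDAQSFDYDHDAFLGAEEAK"),
               "mismatch")
  expect_error(parse_mods("banana"), "unparsable")
})

test_that("PSM tables round-trip through TSV read/write", {
  b <- test_build()
  path <- tempfile(fileext = ".tsv")
  small <- b$psms[1:3, ]
  write_psm_table(small, path)
  back <- read_psm_table(path)
  for (col in c("collection_id", "run_id", "scan", "sequence", "mods",
                "charge", "q_value")) {
    expect_equal(back[[col]], small[[col]], info = col)
  }
  expect_equal(back$mass_error_da, small$mass_error_da, tolerance = 1e-12)

  # empty file with a valid header gives an empty table
  write_psm_table(small[0, ], path)
  expect_equal(nrow(read_psm_table(path)), 0L)

  # missing required column is a configuration error
  writeLines("collection_id\tscan", path)
  expect_error(read_psm_table(path), "missing required column")
})

test_that("invalid rows are rejected with a count, not silently", {
  good <- make_psm("PEPSYR", "4-S-Phospho")
  bad1 <- make_psm("PEPSYR", "4-Y-Phospho")     # residue mismatch
  bad2 <- make_psm("PEPSYR", q = 2)             # q outside [0,1]
  tab <- rbind(good, good, good, bad1, bad2)
  path <- tempfile(fileext = ".tsv")
  write_psm_table(tab, path)
  expect_message(out <- read_psm_table(path), "rejected 2")
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "n_rejected"), 2L)
  # majority-invalid file is fatal
  write_psm_table(rbind(bad1, bad2, good), path)
  expect_error(read_psm_table(path), "more than half")
})

test_that("FDR filter uses strict inequality and preserves order", {
  tab <- rbind(make_psm("PEPSYR", "4-S-Phospho", q = 0.005),
               make_psm("PEPSYR", "4-S-Phospho", q = 0.01),
               make_psm("PEPSYR", "4-S-Phospho", q = 0.02))
  expect_equal(filter_fdr(tab)$q_value, 0.005)
  expect_equal(nrow(filter_fdr(tab, 1.0)), 3L)
  expect_equal(nrow(filter_fdr(tab[0, ])), 0L)
  # nesting: lower threshold output is a subset of higher threshold output
  expect_true(all(filter_fdr(tab, 0.01)$q_value %in%
                    filter_fdr(tab, 0.05)$q_value))
})

test_that("recalibration subtracts the per-run median", {
  tab <- rbind(make_psm("PEPSYR", "4-S-Phospho", err = 0.001),
               make_psm("PEPSYR", "4-S-Phospho", err = 0.003),
               make_psm("PEPSYR", "4-S-Phospho", err = 0.002))
  out <- recalibrate(tab)
  expect_equal(out$mass_error_cal, c(-0.001, 0.001, 0))

  # constant per-run offsets cancel: identical calibrated distributions
  base <- c(-0.002, 0, 0.001, 0.004)
  runA <- do.call(rbind, lapply(base + 0.004, function(e)
    make_psm("PEPSYR", "4-S-Phospho", err = e, run = "A")))
  runB <- do.call(rbind, lapply(base - 0.006, function(e)
    make_psm("PEPSYR", "4-S-Phospho", err = e, run = "B")))
  out <- recalibrate(rbind(runA, runB))
  expect_equal(sort(out$mass_error_cal[out$run_id == "A"]),
               sort(out$mass_error_cal[out$run_id == "B"]))

  # single-PSM run is calibrated to exactly zero
  out1 <- recalibrate(make_psm("PEPSYR", "4-S-Phospho", err = 0.0042))
  expect_equal(out1$mass_error_cal, 0)
})

test_that("recalibration is idempotent and preserves within-run differences", {
  b <- test_build()
  fdr <- filter_fdr(b$psms)
  once <- recalibrate(fdr)
  # per-run median of calibrated errors is zero
  med <- tapply(once$mass_error_cal, once$run_id, stats::median)
  expect_true(all(abs(med) < 1e-12))
  # idempotence: a second pass on already-centred raw errors changes nothing
  again <- once
  again$mass_error_da <- once$mass_error_cal
  twice <- recalibrate(again)
  expect_equal(twice$mass_error_cal, once$mass_error_cal, tolerance = 1e-12)
  # within-run pairwise differences are untouched
  r <- once$run_id == once$run_id[1]
  expect_equal(diff(once$mass_error_cal[r]), diff(once$mass_error_da[r]))
})

test_that("phospho filter keeps only pS/pT/pY records", {
  tab <- rbind(
    make_psm("AMSDYR", "2-M-Oxidation"),            # no phospho
    make_psm("AMSDYR", "5-Y-Phospho"),              # pY
    make_psm("AHSDYR", "2-H-Phospho"),              # phospho on H: dropped
    make_psm("AMSDYR", "3-S-Phospho;2-M-Oxidation") # pS plus oxidation
  )
  out <- filter_phospho(tab)
  expect_equal(out$mods, c("5-Y-Phospho", "3-S-Phospho;2-M-Oxidation"))
})
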
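mc <- mass_constants()

test_that("labile sulfation leaves fragments unmodified; phospho shifts them", {
  # dipeptide AY at 2+: y1 under {Sulfo} equals the unmodified y1
  sulfo <- spectrum_interpretation("AY", data.frame(
    position = 2L, residue = "Y", name = "Sulfo"), charge = 2L)
  phospho <- spectrum_interpretation("AY", parse_mods("2-Y-Phospho", "AY"),
                                     charge = 2L)
  y1 <- function(interp) {
    fr <- theoretical_fragments(interp)
    fr$mz[fr$type == "y" & fr$index == 1 & fr$charge == 1]
  }
  expect_equal(round(y1(sulfo), 4), 182.0812)
  expect_equal(y1(sulfo),
               mc$residue_masses[["Y"]] + mc$water_mass + mc$proton_mass)
  expect_equal(round(y1(phospho), 4), 262.0475)
  expect_equal(y1(phospho) - y1(sulfo), mc$phospho_mass)
  # precursor masses differ by exactly the sulfo/phospho delta
  expect_equal(precursor_neutral_mass(phospho) - precursor_neutral_mass(sulfo),
               mc$sulfo_phospho_delta)
})

test_that("sulfo and phospho fragment lists differ only at site-spanning ions", {
  seqs <- "LESYADKR"
  sulfo <- spectrum_interpretation(seqs, data.frame(
    position = 4L, residue = "Y", name = "Sulfo"), charge = 2L)
  phospho <- spectrum_interpretation(seqs, parse_mods("4-Y-Phospho", seqs),
                                     charge = 2L)
  fs <- theoretical_fragments(sulfo)
  fp <- theoretical_fragments(phospho)
  expect_equal(nrow(fs), nrow(fp))
  spans <- ifelse(fp$type == "b", fp$index >= 4, fp$index > nchar(seqs) - 4)
  expect_equal(fp$mz[!spans], fs$mz[!spans])
  expect_equal(fp$mz[spans] - fs$mz[spans],
               mc$phospho_mass / fp$charge[spans])
})

test_that("peak matching picks the most intense peak within tolerance", {
  theo <- data.frame(type = "y", index = 1L, charge = 1L, mz = 300)
  attr(theo, "peptide_length") <- 2L
  peaks <- data.frame(mz = c(300.02, 299.99, 310), intensity = c(80, 100, 50))
  ann <- match_peaks(peaks, theo, tolerance = 0.05)
  expect_equal(ann$matches$observed_mz, 299.99)   # intensity wins
  # outside tolerance: no match
  ann2 <- match_peaks(data.frame(mz = 300.06, intensity = 999), theo)
  expect_equal(nrow(ann2$matches), 0L)
  expect_equal(ann2$tic_fraction_annotated, 0)
  # empty peak list
  ann3 <- match_peaks(data.frame(mz = numeric(), intensity = numeric()), theo)
  expect_equal(nrow(ann3$matches), 0L)
  # invariant to peak ordering
  ann4 <- match_peaks(peaks[c(3, 1, 2), ], theo, tolerance = 0.05)
  expect_equal(ann4$matches$observed_mz, ann$matches$observed_mz)
})

test_that("a noiseless self-spectrum is fully annotated", {
  interp <- spectrum_interpretation("LESYADKR",
                                    parse_mods("4-Y-Phospho", "LESYADKR"), 2L)
  sp <- generate_spectrum(interp, hypothesis = "retained", seed = 2)
  ann <- match_peaks(sp$peaks, theoretical_fragments(interp))
  expect_equal(ann$tic_fraction_annotated, 1.0)
  expect_equal(ann$residues_supported, 1.0)
})

test_that("hypothesis comparison recovers the generating chemistry", {
  # realistic spectra: incomplete fragment series plus noise peaks
  seqs <- "VHNDAQSFDYDHDAFLGAEEAK"
  sulfo <- spectrum_interpretation(seqs, data.frame(
    position = 10L, residue = "Y", name = "Sulfo"), charge = 2L)
  phospho <- spectrum_interpretation(seqs, parse_mods("10-Y-Phospho", seqs), 2L)
  verdicts_s <- verdicts_p <- character(20)
  for (i in 1:20) {
    sp_s <- generate_spectrum(sulfo, hypothesis = "neutral_loss",
                              n_noise = 3L, dropout = 0.45, seed = i)
    verdicts_s[i] <- compare_hypotheses(sp_s$peaks, sulfo, phospho)$verdict
    sp_p <- generate_spectrum(phospho, hypothesis = "retained",
                              n_noise = 3L, dropout = 0.45, seed = i)
    verdicts_p[i] <- compare_hypotheses(sp_p$peaks, sulfo, phospho)$verdict
  }
  expect_gte(mean(verdicts_s == "sulfo-favored"), 0.9)
  expect_gte(mean(verdicts_p == "phospho-favored"), 0.9)
  # the wrong call never happens, only occasional inconclusives
  expect_false(any(verdicts_s == "phospho-favored"))
  expect_false(any(verdicts_p == "sulfo-favored"))
  # no peaks: inconclusive
  empty <- data.frame(mz = numeric(), intensity = numeric())
  expect_equal(compare_hypotheses(empty, sulfo, phospho)$verdict,
               "inconclusive")
})

test_that("alternative interpretations rewrite phospho to labile sulfo", {
  psm <- function(seq, mods) {
    data.frame(collection_id = "C", run_id = "r", scan = 5L, sequence = seq,
               mods = mods, charge = 2L, stringsAsFactors = FALSE)
  }
  # pY -> {Sulfo} at the same site
  alts <- alternative_interpretations(psm("LESYADKR", "4-Y-Phospho"))
  expect_length(alts, 1L)
  expect_equal(proforma(alts[[1]]), "LESY{Sulfo}ADKR")
  # phospho on T only: remove it and sulfate the (lowest) tyrosine
  alts2 <- alternative_interpretations(psm("ELETNAYR", "4-T-Phospho"))
  expect_equal(proforma(alts2[[1]]), "ELETNAY{Sulfo}R")
  # two pY and two Y: singly and doubly rewritten variants
  alts3 <- alternative_interpretations(psm("AYDYKR", "2-Y-Phospho;4-Y-Phospho"))
  expect_length(alts3, 2L)
  expect_equal(proforma(alts3[[1]]), "AY{Sulfo}DY[Phospho]KR")
  expect_equal(proforma(alts3[[2]]), "AY{Sulfo}DY{Sulfo}KR")
  # refusals
  expect_error(alternative_interpretations(
    psm("AYDNKR", "2-Y-Phospho;4-N-Deamidated")), "not assessed")
  expect_error(alternative_interpretations(psm("AESTKR", "3-S-Phospho")),
               "no tyrosine")
})

test_that("USIs serialize to the template and parse back losslessly", {
  psm <- data.frame(collection_id = "PXD000001", run_id = "file01",
                    scan = 1234L, sequence = "LESYADKR",
                    mods = "4-Y-Phospho", charge = 2L,
                    stringsAsFactors = FALSE)
  orig <- spectrum_interpretation(psm$sequence, psm$mods, psm$charge)
  usi <- build_usi(psm, orig)
  expect_equal(usi, "mzspec:PXD000001:file01:scan:1234:LESY[Phospho]ADKR/2")
  # the sulfo alternative differs only in the bracket tag
  alt <- alternative_interpretations(psm)[[1]]
  expect_equal(build_usi(psm, alt),
               "mzspec:PXD000001:file01:scan:1234:LESY{Sulfo}ADKR/2")
  # round trip
  back <- parse_usi(usi)
  expect_equal(back$collection_id, "PXD000001")
  expect_equal(back$scan_number, 1234L)
  expect_equal(proforma(back$interpretation), "LESY[Phospho]ADKR")
  expect_equal(back$interpretation$charge, 2L)
  expect_equal(back$interpretation$mods$labile, FALSE)
  # missing identifiers are an error
  psm_bad <- psm; psm_bad$collection_id <- ""
  expect_error(build_usi(psm_bad, orig), "missing identifier")
  expect_error(parse_usi("mzspec:only:three"), "not a valid USI")
})

test_that("ProForma round-trips including multiple and labile tags", {
  for (pf_str in c("LESY{Sulfo}ADKR", "LESY[Phospho]ADKR",
                   "AM[Oxidation]SY{Sulfo}DS[Phospho]KR", "PEPTIDEK")) {
    interp <- parse_proforma(pf_str, 2L)
    expect_equal(proforma(interp), pf_str)
  }
  expect_error(parse_proforma("pep[tide", 2L), "unparsable")
})

test_that("MGF files round-trip", {
  interp <- spectrum_interpretation("LESYADKR",
                                    parse_mods("4-Y-Phospho", "LESYADKR"), 2L)
  sp <- generate_spectrum(interp, hypothesis = "retained", n_noise = 3,
                          seed = 4)
  path <- tempfile(fileext = ".mgf")
  write_mgf(list(sp), path)
  back <- read_mgf(path)
  expect_length(back, 1L)
  expect_equal(back[[1]]$charge, 2L)
  expect_equal(back[[1]]$pepmass, sp$pepmass, tolerance = 1e-6)
  expect_equal(back[[1]]$peaks$mz, sp$peaks$mz, tolerance = 1e-6)
  expect_equal(nrow(back[[1]]$peaks), nrow(sp$peaks))
})
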
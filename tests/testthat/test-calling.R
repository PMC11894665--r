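mix_model <- function(means, sds = rep(0.001, length(means)),
                      weights = rep(1 / length(means), length(means))) {
  structure(list(components = data.frame(weight = weights, mean = means,
                                         sd = sds),
                 selected_k = length(means), n = 100L),
            class = "mass_error_gmm")
}

test_that("components classify into s/ss/p with the fixed type order", {
  th <- calling_thresholds()
  expect_equal(classify_components(mix_model(c(0, -0.0095)), th)$histogram_type,
               "s/p")
  expect_equal(classify_components(mix_model(-0.019), th)$histogram_type, "ss")
  cc <- classify_components(mix_model(c(-0.019, -0.0095, 0)), th)
  expect_equal(cc$histogram_type, "ss/s/p")
  expect_equal(cc$component_classes, c("ss", "s", "p"))
  # off-center component is 'other' and excluded from the type
  expect_equal(classify_components(mix_model(c(0, 0.015)), th)$histogram_type,
               "p")
})

test_that("histogram labels follow the convincing/undetermined rules", {
  th <- calling_thresholds()
  expect_equal(call_histogram(mix_model(-0.0095, 0.001), th)$label,
               "Convincing")
  und <- call_histogram(mix_model(-0.005, 0.005), th)
  expect_equal(und$label, "Undetermined")
  expect_equal(und$histogram_type, "s/p")
  expect_equal(call_histogram(mix_model(-0.002), th)$label, "NotConvincing")
  # calls are deterministic functions of (model, thresholds)
  expect_identical(call_histogram(mix_model(-0.0095), th),
                   call_histogram(mix_model(-0.0095), th))
})

test_that("context labels come from the custom term map", {
  terms <- list(
    known_sY = list(members = c("P1", "P2"), category = "custom"),
    Secreted = list(members = c("P3"), category = "custom"),
    Golgi = list(members = c("P1"), category = "custom"),
    Transmembrane = list(members = character(0), category = "custom"),
    unlikely_sY = list(members = c("P4"), category = "custom")
  )
  expect_setequal(contextualize("P1", terms), c("Sulfated", "Golgi"))
  expect_equal(contextualize("P4", terms), "No prior knowledge")
  expect_equal(contextualize("P3", terms), "Secreted")
  expect_equal(contextualize("UNKNOWN", terms), "No prior knowledge")
  # comma-joined accession strings are accepted
  expect_true("Secreted" %in% contextualize("P3,P4", terms))
})

test_that("candidate shortlisting integrates label, context and deamidation", {
  calls <- data.frame(
    id = c("a", "b", "c", "d"),
    sequence = "PEPYR",
    accessions = c("P1", "P2", "P3", "P4"),
    label = c("Convincing", "Convincing", "NotConvincing", "Convincing"),
    histogram_type = c("s", "s/p", "p", "ss"),
    context = c("Sulfated;Golgi", "No prior knowledge", "Sulfated",
                "Secreted"),
    has_deamidation = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  sl <- shortlist_candidates(calls, require_context = TRUE)
  expect_equal(sl$candidates$id, "a")
  expect_equal(sl$by_protein$accession, "P1")
  expect_equal(sl$by_protein$contexts, "Golgi;Sulfated")
  # relaxing the context gate never removes a candidate
  sl2 <- shortlist_candidates(calls, require_context = FALSE)
  expect_true(all(sl$candidates$id %in% sl2$candidates$id))
  expect_setequal(sl2$candidates$id, c("a", "b"))  # deamidated still excluded
})

test_that("bin composition reports per-bin feature fractions with NA when empty", {
  pf <- data.frame(
    id = c("x", "y"),
    contains_S = c(TRUE, FALSE), contains_T = c(TRUE, TRUE),
    contains_Y = c(TRUE, TRUE),
    has_pS = c(FALSE, FALSE), has_pT = c(TRUE, FALSE),
    has_pY = c(TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  asn <- list(
    x = list(assigned_bins = "BOI1"),
    y = list(assigned_bins = c("BOI1", "TRUEp2"))
  )
  comp <- bin_composition(asn, pf)
  boi1 <- comp[comp$bin == "BOI1", ]
  expect_equal(boi1$n, 2L)
  expect_equal(boi1$has_pY, 1.0)
  expect_equal(boi1$contains_S, 0.5)
  expect_equal(boi1$pT_with_Y, 1.0)
  # empty bin rows are NA, not zero
  expect_true(is.na(comp$has_pY[comp$bin == "DECOY1"]))
  expect_equal(comp$n[comp$bin == "DECOY1"], 0L)
})

test_that("planted sulfation enriches Y features in BOIs on synthetic data", {
  b <- test_build()
  pf <- test_build_peptidoforms()
  fits <- test_build_fits()
  comp <- bin_composition(fits$assignments, pf)
  y_boi2 <- comp$contains_Y[comp$bin == "BOI2"]
  y_truep <- comp$contains_Y[comp$bin == "TRUEp2"]
  if (!is.na(y_boi2) && !is.na(y_truep)) {
    expect_gt(y_boi2, y_truep)
  }
  # histogram calls recover the planted classes
  th <- calling_thresholds()
  truth <- b$truth
  expected <- c(p = "p", s = "s", ss = "ss", `s/p` = "s/p",
                `ss/s/p` = "ss/s/p")
  check <- truth[truth$true_class %in% names(expected), ]
  got <- vapply(check$peptidoform_id, function(id) {
    call_histogram(fits$models[[id]], th)$histogram_type
  }, "")
  acc <- mean(got == expected[check$true_class])
  expect_gte(acc, 0.9)
})
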
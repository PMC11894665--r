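test_that("custom term membership follows the annotation string rules", {
  ann <- data.frame(
    accession = c("P1", "P2", "P3", "P4", "P5"),
    protein_name = c("Golgi integral membrane protein", "Some protein",
                     "Another", "Plain", "Flagged"),
    subcellular_location = c("Cytoplasm.", "Secreted. Golgi apparatus.",
                             "Nucleus.", "", "Cytoplasm."),
    transmembrane = c("", "", "TRANSMEM 5..27", "", ""),
    known_sY = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  terms <- build_custom_terms(ann)
  expect_setequal(names(terms),
                  c("known_sY", "Secreted", "Transmembrane", "Golgi",
                    "unlikely_sY"))
  expect_true(all(c("P2") %in% terms$Secreted$members))
  expect_setequal(terms$Golgi$members, c("P1", "P2"))
  expect_equal(terms$Transmembrane$members, "P3")
  expect_equal(terms$known_sY$members, "P5")
  # complement: only proteins matching nothing
  expect_equal(terms$unlikely_sY$members, "P4")
  expect_error(build_custom_terms(ann[, -5]), "missing column")
})

test_that("hypergeometric upper tail matches exhaustive enumeration", {
  # worked example: N=20, K=5, n=6, k=3 -> 5090/38760
  expect_equal(hypergeom_test(3, 6, 5, 20), 5090 / 38760, tolerance = 1e-12)
  expect_equal(hypergeom_test(0, 6, 5, 20), 1)
  expect_equal(hypergeom_test(5, 5, 5, 5), 1)
  expect_warning(p <- hypergeom_test(4, 5, 3, 20), "impossible")
  expect_equal(p, 0)
  # full grid N <= 12 against direct enumeration (deeper grid in acceptance)
  for (N in 1:12) for (K in 0:N) for (n in 0:N) for (k in 0:min(n, K)) {
    expect_equal(hypergeom_test(k, n, K, N), enum_hyper_upper(k, n, K, N),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.05, 4)), rep(0.05, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  # idempotent on already-adjusted monotone input
  adj <- bh_adjust(c(0.001, 0.01, 0.3, 0.7))
  expect_equal(bh_adjust(adj) >= adj, rep(TRUE, 4))
  # returned in input order
  p <- c(0.04, 0.01, 0.02)
  expect_equal(bh_adjust(p), c(0.04, 0.03, 0.03))
})

test_that("ORA handles degenerate foregrounds and set-size limits", {
  bg <- paste0("P", 1:20)
  terms <- list(
    t1 = list(name = "five", category = "custom", members = bg[1:5]),
    t2 = list(name = "single", category = "custom", members = bg[7]),
    t3 = list(name = "alien", category = "custom", members = "Q999")
  )
  # foreground == background: all p-values 1, gene_ratio = K/N scaled
  res <- run_ora(bg, bg, terms, q_cutoff = NA)
  expect_true(all(res$p_value == 1))
  expect_equal(res$k[res$term_id == "t1"], 5L)
  # min_set_size = 1 keeps the singleton term but drops the alien one
  expect_setequal(res$term_id, c("t1", "t2"))
  expect_equal(nrow(run_ora(bg[1:3], bg, terms, q_cutoff = NA,
                            min_set_size = 2)), 1L)
  # foreground outside background is an error; empty foreground warns
  expect_error(run_ora("Q1", bg, terms), "outside the background")
  expect_warning(res0 <- run_ora(character(0), bg, terms), "empty")
  expect_equal(nrow(res0), 0L)
  # invariant to foreground ordering
  fg <- bg[c(3, 1, 5, 2)]
  expect_equal(run_ora(fg, bg, terms, q_cutoff = NA),
               run_ora(rev(fg), bg, terms, q_cutoff = NA))
})

test_that("BH adjustment is applied within each term category separately", {
  bg <- paste0("P", 1:40)
  terms <- list(
    go1 = list(name = "go1", category = "GO-BP", members = bg[1:10]),
    go2 = list(name = "go2", category = "GO-BP", members = bg[11:20]),
    c1 = list(name = "c1", category = "custom", members = bg[1:10])
  )
  res <- run_ora(bg[1:10], bg, terms, q_cutoff = NA)
  # c1 is alone in its category: its adjusted p equals its raw p
  expect_equal(res$p_adjusted[res$term_id == "c1"],
               res$p_value[res$term_id == "c1"])
  # the two GO terms are adjusted together, independent of the custom term
  go <- res[res$category == "GO-BP", ]
  expect_equal(go$p_adjusted[order(go$term_id)],
               bh_adjust(go$p_value[order(go$term_id)]))
})

test_that("planted known_sY enrichment is detected in BOI foregrounds only", {
  b <- test_build()
  pf <- test_build_peptidoforms()
  fits <- test_build_fits()
  terms <- build_custom_terms(b$annotation)
  bg <- unique(unlist(strsplit(pf$accessions, ",")))
  fg_of <- function(prefix) {
    ids <- names(fits$assignments)[vapply(fits$assignments, function(a) {
      any(startsWith(a$assigned_bins, prefix))
    }, logical(1))]
    intersect(unique(unlist(strsplit(pf$accessions[pf$id %in% ids], ","))), bg)
  }
  res_boi <- run_ora(fg_of("BOI"), bg, terms, q_cutoff = NA)
  expect_lt(res_boi$p_adjusted[res_boi$term_id == "known_sY"], 0.05)
  res_dec <- run_ora(fg_of("DECOY"), bg, terms, q_cutoff = NA)
  p_dec <- res_dec$p_adjusted[res_dec$term_id == "known_sY"]
  expect_true(length(p_dec) == 0 || p_dec > 0.05)
})

test_that("GMT files round-trip", {
  terms <- list(
    T1 = list(name = "term one", category = "GO-BP", members = c("A", "B")),
    T2 = list(name = "term two", category = "GO-BP", members = "C")
  )
  path <- tempfile(fileext = ".gmt")
  write_gmt(terms, path)
  back <- read_gmt(path, category = "GO-BP")
  expect_equal(names(back), c("T1", "T2"))
  expect_equal(back$T1$members, c("A", "B"))
  expect_equal(back$T2$name, "term two")
})
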
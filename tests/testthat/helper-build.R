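# Shared small synthetic build, generated once per test run.
.build_cache <- new.env(parent = emptyenv())

test_build <- function() {
  if (is.null(.build_cache$b)) {
    .build_cache$b <- generate_build(generator_config(
      seed = 42L, n_peptidoforms = 24L, psm_range = c(90L, 150L),
      n_runs = 16L, n_experiments = 8L
    ))
  }
  .build_cache$b
}

# Build processed through the ingest stages (FDR -> recalibrate -> phospho).
test_build_processed <- function() {
  if (is.null(.build_cache$processed)) {
    b <- test_build()
    .build_cache$processed <-
      filter_phospho(recalibrate(filter_fdr(b$psms)))
  }
  .build_cache$processed
}

test_build_peptidoforms <- function() {
  if (is.null(.build_cache$pf)) {
    b <- test_build()
    .build_cache$pf <- filter_robust(
      aggregate_peptidoforms(test_build_processed(), b$protein_map)
    )
  }
  .build_cache$pf
}

test_build_fits <- function() {
  if (is.null(.build_cache$fits)) {
    .build_cache$fits <- fit_peptidoform_models(test_build_peptidoforms(),
                                                seed = 1L)
  }
  .build_cache$fits
}

# Independent hypergeometric upper tail by exhaustive enumeration.
enum_hyper_upper <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# A random mixture model object for property tests (no fitting involved).
random_mixture <- function(k = sample(1:3, 1)) {
  w <- stats::runif(k); w <- w / sum(w)
  structure(list(
    components = data.frame(
      weight = w,
      mean = stats::runif(k, -0.022, 0.022),
      sd = stats::runif(k, 5e-4, 8e-3)
    ),
    selected_k = k, n = 100L
  ), class = "mass_error_gmm")
}

# Full-scale default build and fits for the acceptance checks (cached).
acceptance_build <- function() {
  if (is.null(.build_cache$acc)) {
    b <- generate_build(generator_config(seed = 1L))
    psms <- filter_phospho(recalibrate(filter_fdr(b$psms)))
    pf <- filter_robust(aggregate_peptidoforms(psms, b$protein_map))
    fits <- fit_peptidoform_models(pf, seed = 1L)
    .build_cache$acc <- list(b = b, pf = pf, fits = fits)
  }
  .build_cache$acc
}

# Bin names assigned to a peptidoform id under the cached acceptance fits.
assigned_of <- function(acc, ids) {
  lapply(acc$fits$assignments[ids], `[[`, "assigned_bins")
}
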
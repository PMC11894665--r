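#' Predefined mass-error bins
#'
#' Nine contiguous half-open bins of width 0.005 Da covering
#' \[-0.0225, 0.0225) Da, split into three groups: Bins of Interest (BOI)
#' on the negative side cover single (about -0.0095 Da) and double (about
#' -0.019 Da) sulfation shifts; TRUEp bins span -0.0075 to +0.0075 Da where
#' correctly assigned phosphorylation lands after calibration; DECOY bins
#' mirror the BOIs on the positive side and act as negative controls.
#'
#' @return A data.frame with columns `name`, `group`, `lower`, `upper`;
#'   intervals are half-open `[lower, upper)`.
#' @examples
#' standard_bins()
#' @export
standard_bins <- function() {
  out <- data.frame(
    name = c("BOI3", "BOI2", "BOI1", "TRUEp1", "TRUEp2", "TRUEp3",
             "DECOY1", "DECOY2", "DECOY3"),
    group = c("BOI", "BOI", "BOI", "TRUEp", "TRUEp", "TRUEp",
              "DECOY", "DECOY", "DECOY"),
    lower = seq(-0.0225, 0.0175, by = 0.005),
    upper = seq(-0.0175, 0.0225, by = 0.005),
    stringsAsFactors = FALSE
  )
  out
}

#' Probability mass of a fitted mixture over mass-error bins
#'
#' For each bin, integrates the mixture density over `[lower, upper)` in
#' closed form via the normal CDF:
#' `sum_j w_j * (pnorm((upper - mu_j)/sd_j) - pnorm((lower - mu_j)/sd_j))`.
#'
#' @param model A `mass_error_gmm` fit.
#' @param bins Bin table as from [standard_bins()] (any subset works).
#' @return Named numeric vector of per-bin AUC fractions (of total model
#'   mass, which is 1).
#' @export
bin_auc <- function(model, bins = standard_bins()) {
  comp <- model$components
  auc <- vapply(seq_len(nrow(bins)), function(i) {
    sum(comp$weight *
          (stats::pnorm((bins$upper[i] - comp$mean) / comp$sd) -
             stats::pnorm((bins$lower[i] - comp$mean) / comp$sd)))
  }, 0)
  stats::setNames(auc, bins$name)
}

#' Assign a peptidoform to mass-error bins by AUC threshold
#'
#' A peptidoform is assigned to every bin holding at least `threshold` of its
#' fitted mixture's probability mass (default 15%). Multiple assignments are
#' expected (e.g. an s/p mixture straddling a TRUEp bin and BOI1), and a very
#' broad fit may be assigned to no bin at all.
#'
#' @inheritParams bin_auc
#' @param threshold Minimum AUC fraction for assignment (default 0.15).
#' @return A list with `auc_by_bin` (named numeric), `assigned_bins`
#'   (character vector) and `auc_threshold`.
#' @export
assign_bins <- function(model, bins = standard_bins(), threshold = 0.15) {
  auc <- bin_auc(model, bins)
  list(
    auc_by_bin = auc,
    assigned_bins = names(auc)[auc >= threshold],
    auc_threshold = threshold
  )
}

#' Fit mixtures and assign bins for a table of peptidoforms
#'
#' Convenience driver running [fit_mass_error_gmm()] and [assign_bins()]
#' over every row of an aggregated peptidoform table.
#'
#' @param peptidoforms Output of [aggregate_peptidoforms()] /
#'   [filter_robust()].
#' @param bins Bin table.
#' @param threshold AUC assignment threshold.
#' @param seed Seed forwarded to each fit.
#' @param ... Further arguments to [fit_mass_error_gmm()].
#' @return A list with `models` (named list of `mass_error_gmm`),
#'   `assignments` (named list from [assign_bins()]) and `report`, a
#'   data.frame with one row per peptidoform (selected k, BICs, per-bin AUC,
#'   assigned bins).
#' @export
fit_peptidoform_models <- function(peptidoforms, bins = standard_bins(),
                                   threshold = 0.15, seed = 1L, ...) {
  models <- vector("list", nrow(peptidoforms))
  assignments <- vector("list", nrow(peptidoforms))
  names(models) <- names(assignments) <- peptidoforms$id
  for (i in seq_len(nrow(peptidoforms))) {
    m <- fit_mass_error_gmm(peptidoforms$mass_errors[[i]], seed = seed, ...)
    models[[i]] <- m
    assignments[[i]] <- assign_bins(m, bins, threshold)
  }
  report <- do.call(rbind, lapply(seq_len(nrow(peptidoforms)), function(i) {
    m <- models[[i]]; a <- assignments[[i]]
    row <- data.frame(
      id = peptidoforms$id[i],
      n_psms = m$n,
      selected_k = m$selected_k,
      converged = m$converged,
      means = paste(sprintf("%.6f", m$components$mean), collapse = ","),
      sds = paste(sprintf("%.6f", m$components$sd), collapse = ","),
      weights = paste(sprintf("%.4f", m$components$weight), collapse = ","),
      assigned_bins = paste(a$assigned_bins, collapse = ","),
      stringsAsFactors = FALSE
    )
    for (k in names(m$bic_by_k)) row[[paste0("bic_k", k)]] <- m$bic_by_k[[k]]
    for (b in names(a$auc_by_bin)) row[[paste0("auc_", b)]] <- a$auc_by_bin[[b]]
    row
  }))
  list(models = models, assignments = assignments, report = report)
}

#' Export per-peptidoform mass-error histograms with fitted densities
#'
#' Writes, for each peptidoform, binned counts of its calibrated mass errors
#' plus the fitted mixture density sampled on the same grid, enabling
#' external re-plotting of the histogram panels.
#'
#' @param peptidoforms Peptidoform table with `mass_errors` list column.
#' @param models Named list of fits from [fit_peptidoform_models()].
#' @param path Output TSV path.
#' @param bin_width Display bin width in Da (default 0.001).
#' @return The path, invisibly.
#' @export
export_histograms <- function(peptidoforms, models, path, bin_width = 0.001) {
  rows <- lapply(seq_len(nrow(peptidoforms)), function(i) {
    id <- peptidoforms$id[i]
    x <- peptidoforms$mass_errors[[i]]
    lo <- floor(min(x) / bin_width) * bin_width
    hi <- ceiling(max(x) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    breaks <- seq(lo, hi, by = bin_width)
    counts <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    data.frame(id = id, bin_mid = mids, count = counts,
               density = predict(models[[id]], mids),
               stringsAsFactors = FALSE)
  })
  write_tsv_base(do.call(rbind, rows), path)
  invisible(path)
}
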
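#' Thresholds for automated histogram calling
#'
#' Component classification centers come straight from the adduct-mass
#' arithmetic: a singly sulfated peptidoform misreported as phosphorylated
#' sits at minus one sulfo/phospho delta (about -0.0095 Da), a doubly
#' sulfated one at twice that (about -0.019 Da), and a correct
#' phosphorylation at 0. A component counts as "centered near" one of these
#' if its mean falls within `center_tolerance`. The `undetermined_range`
#' captures broad fits drifting toward sulfation without reaching it.
#'
#' @param s_center Expected mean for one sulfation (Da).
#' @param ss_center Expected mean for two sulfations (Da).
#' @param center_tolerance Half-width for the s/ss match (default 0.002 Da).
#' @param p_tolerance Half-width around 0 for a phospho component
#'   (default 0.004 Da).
#' @param undetermined_range Open interval of component means yielding an
#'   Undetermined call when nothing matches s/ss (default (-0.006, -0.004)).
#' @param wide_sd Component sd above which a fit is reported as wide
#'   (informational; default 0.004 Da).
#' @return A list of class `calling_thresholds`.
#' @export
calling_thresholds <- function(s_center = -mass_constants()$sulfo_phospho_delta,
                               ss_center = -2 * mass_constants()$sulfo_phospho_delta,
                               center_tolerance = 0.002,
                               p_tolerance = 0.004,
                               undetermined_range = c(-0.006, -0.004),
                               wide_sd = 0.004) {
  stopifnot(center_tolerance > 0, p_tolerance > 0,
            undetermined_range[1] < undetermined_range[2],
            undetermined_range[2] < 0)
  structure(list(s_center = s_center, ss_center = ss_center,
                 center_tolerance = center_tolerance,
                 p_tolerance = p_tolerance,
                 undetermined_range = undetermined_range,
                 wide_sd = wide_sd),
            class = "calling_thresholds")
}

#' Classify mixture components and derive the histogram type
#'
#' Each fitted component is classified as `ss` (near twice the sulfo shift),
#' `s` (near one sulfo shift), `p` (near zero) or `other`; `ss` and `s` are
#' checked first so the tighter sulfation centers win over the broader
#' phospho window. The histogram type concatenates the distinct non-`other`
#' classes in the fixed order ss, s, p, joined by "/" (e.g. `"ss/s/p"` when
#' PSMs support two, one and no sulfations).
#'
#' @param model A `mass_error_gmm` fit.
#' @param thresholds A [calling_thresholds()] object.
#' @return A list with `component_classes` (character, per component) and
#'   `histogram_type` (string; `""` when all components are `other`).
#' @export
classify_components <- function(model, thresholds = calling_thresholds()) {
  mu <- model$components$mean
  cls <- vapply(mu, function(m) {
    if (abs(m - thresholds$ss_center) <= thresholds$center_tolerance) "ss"
    else if (abs(m - thresholds$s_center) <= thresholds$center_tolerance) "s"
    else if (abs(m) <= thresholds$p_tolerance) "p"
    else "other"
  }, "")
  present <- intersect(c("ss", "s", "p"), cls)
  list(component_classes = cls,
       histogram_type = paste(present, collapse = "/"))
}

#' Call a peptidoform's mass-error histogram
#'
#' Reproduces the annotation rules as a deterministic function of the fitted
#' mixture: `Convincing` when any component is classed s or ss;
#' otherwise `Undetermined` when some component mean lies in the
#' undetermined range (such fits sit between an s and a p pattern and are
#' typed `"s/p"`); otherwise `NotConvincing`.
#'
#' @inheritParams classify_components
#' @return A list with `label`, `histogram_type`, `component_classes`,
#'   `component_means`, `component_sds` and `any_wide` (any component sd
#'   above `wide_sd`).
#' @export
call_histogram <- function(model, thresholds = calling_thresholds()) {
  cc <- classify_components(model, thresholds)
  mu <- model$components$mean
  label <- if (any(cc$component_classes %in% c("s", "ss"))) {
    "Convincing"
  } else if (any(mu > thresholds$undetermined_range[1] &
                 mu < thresholds$undetermined_range[2])) {
    "Undetermined"
  } else {
    "NotConvincing"
  }
  htype <- cc$histogram_type
  if (label == "Undetermined") htype <- "s/p"
  list(label = label, histogram_type = htype,
       component_classes = cc$component_classes,
       component_means = mu, component_sds = model$components$sd,
       any_wide = any(model$components$sd > thresholds$wide_sd))
}

#' Biological-context labels for a peptidoform's proteins
#'
#' Looks the peptidoform's protein accessions up in the custom term map and
#' returns the sulfation-linked context labels, renaming `known_sY` to
#' `Sulfated`. A protein matching none of the sulfation-linked terms (or
#' absent from the annotation) is labelled `"No prior knowledge"`.
#'
#' @param accessions Character vector of protein accessions (or a single
#'   comma-joined string).
#' @param term_map A term map as from [build_custom_terms()] (list of terms,
#'   each with `members`).
#' @return Character vector of context labels.
#' @export
contextualize <- function(accessions, term_map) {
  if (length(accessions) == 1L && grepl(",", accessions, fixed = TRUE)) {
    accessions <- strsplit(accessions, ",", fixed = TRUE)[[1]]
  }
  accessions <- accessions[nzchar(accessions)]
  relabel <- c(known_sY = "Sulfated", Secreted = "Secreted",
               Transmembrane = "Transmembrane", Golgi = "Golgi")
  labels <- character(0)
  for (term in names(relabel)) {
    if (!term %in% names(term_map)) next
    if (any(accessions %in% term_map[[term]]$members)) {
      labels <- c(labels, relabel[[term]])
    }
  }
  if (!length(labels)) labels <- "No prior knowledge"
  unname(labels)
}

#' Shortlist sulfation candidates from histogram calls
#'
#' Integrates the mass-error evidence (Convincing calls) with biological
#' context: by default only peptidoforms whose protein context goes beyond
#' "No prior knowledge" are retained. Deamidated peptidoforms are excluded
#' from candidacy. The output is grouped per protein with the histogram
#' types and per-type peptidoform counts.
#'
#' @param calls A data.frame with one row per called peptidoform and columns
#'   `id`, `sequence`, `accessions`, `label`, `histogram_type`, `context`
#'   (labels joined by ";") and `has_deamidation`.
#' @param require_context Drop candidates whose only context label is
#'   "No prior knowledge" (default TRUE).
#' @return A list with `candidates` (filtered per-peptidoform rows) and
#'   `by_protein` (accession, histogram types, per-type counts, contexts).
#' @export
shortlist_candidates <- function(calls, require_context = TRUE) {
  keep <- calls$label == "Convincing" & !calls$has_deamidation
  if (require_context) {
    keep <- keep & calls$context != "No prior knowledge"
  }
  cand <- calls[keep, , drop = FALSE]
  rownames(cand) <- NULL
  by_protein <- NULL
  if (nrow(cand)) {
    acc_split <- strsplit(cand$accessions, ",", fixed = TRUE)
    flat <- data.frame(
      accession = unlist(acc_split),
      id = rep(cand$id, lengths(acc_split)),
      histogram_type = rep(cand$histogram_type, lengths(acc_split)),
      context = rep(cand$context, lengths(acc_split)),
      stringsAsFactors = FALSE
    )
    by_protein <- do.call(rbind, lapply(split(flat, flat$accession), function(g) {
      tt <- table(g$histogram_type)
      data.frame(
        accession = g$accession[1],
        n_peptidoforms = length(unique(g$id)),
        histogram_types = paste(names(tt), collapse = ";"),
        type_counts = paste(as.integer(tt), collapse = ";"),
        contexts = paste(sort(unique(unlist(strsplit(g$context, ";")))),
                         collapse = ";"),
        stringsAsFactors = FALSE
      )
    }))
    rownames(by_protein) <- NULL
  }
  list(candidates = cand, by_protein = by_protein)
}

#' Per-bin composition of sequence and phospho features
#'
#' For each mass-error bin, the fraction of assigned peptidoforms whose
#' sequence contains S, T or Y, whose modifications include pS, pT or pY,
#' and — among pT-containing peptidoforms — the fraction that also contain a
#' tyrosine. Empty bins report `NA`, not zero.
#'
#' @param assignments Named list of [assign_bins()] results (names =
#'   peptidoform ids).
#' @param peptidoforms Peptidoform table with flag columns.
#' @param bins Bin table.
#' @return Data.frame with one row per bin: `bin`, `n`, feature fractions.
#' @export
bin_composition <- function(assignments, peptidoforms,
                            bins = standard_bins()) {
  flags <- peptidoforms[match(names(assignments), peptidoforms$id), ,
                        drop = FALSE]
  rows <- lapply(bins$name, function(b) {
    in_bin <- vapply(assignments, function(a) b %in% a$assigned_bins,
                     logical(1))
    g <- flags[in_bin, , drop = FALSE]
    n <- nrow(g)
    frac <- function(x) if (n == 0L) NA_real_ else mean(x)
    n_pt <- sum(g$has_pT)
    data.frame(
      bin = b, n = n,
      contains_S = frac(g$contains_S), contains_T = frac(g$contains_T),
      contains_Y = frac(g$contains_Y),
      has_pS = frac(g$has_pS), has_pT = frac(g$has_pT),
      has_pY = frac(g$has_pY),
      pT_with_Y = if (n_pt == 0L) NA_real_ else mean(g$contains_Y[g$has_pT]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
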
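#' Canonical nonstrict peptidoform identifier
#'
#' A nonstrict peptidoform identity keeps the peptide sequence plus the
#' multiset of (modification name, modified residue) pairs, discarding
#' positional information: the same peptide phosphorylated at S4 in one PSM
#' and S9 in another collapses to one peptidoform, while phospho-S and
#' phospho-Y variants of the same peptide remain distinct. The identifier is
#' the sequence followed by sorted `Name@Residue:count` entries joined by
#' `"|"`; an unmodified peptide's id is the bare sequence.
#'
#' @param sequence Peptide sequence (uppercase one-letter codes).
#' @param mods Modification data.frame from [parse_mods()] (or a compact
#'   modification string).
#' @return The canonical id string.
#' @examples
#' make_peptidoform_id("PEPSYR", parse_mods("4-S-Phospho"))
#' @export
make_peptidoform_id <- function(sequence, mods) {
  if (is.character(mods)) mods <- parse_mods(mods, sequence)
  if (nrow(mods) == 0L) return(sequence)
  seq_chars <- strsplit(sequence, "")[[1]]
  pos <- mods$position
  bad <- pos >= 1L & (pos > length(seq_chars) | mods$residue != seq_chars[pmin(pos, length(seq_chars))])
  if (any(bad)) {
    stop("modification residue mismatch at position(s) ",
         paste(pos[bad], collapse = ", "), " of ", sequence)
  }
  key <- paste0(mods$name, "@", mods$residue)
  counts <- table(key)
  entries <- sort(paste0(names(counts), ":", as.integer(counts)))
  paste(c(sequence, entries), collapse = "|")
}

#' Aggregate PSMs into peptidoforms
#'
#' Groups recalibrated, phospho-filtered PSMs by their nonstrict peptidoform
#' id and pools their calibrated mass errors. Sequence/composition flags used
#' by downstream stages (presence of S/T/Y, of phospho on each, and of
#' deamidation) are computed here once.
#'
#' @param psms PSM data.frame with `mass_error_cal` set.
#' @param protein_map Optional data.frame with columns `sequence`,
#'   `accession` mapping peptide sequences to protein accessions; peptides
#'   missing from the map keep an empty accession set.
#' @return A data.frame with one row per peptidoform: `id`, `sequence`,
#'   `mod_composition`, `n_psms`, `n_experiments`, flag columns, comma-joined
#'   `accessions`, and list columns `mass_errors`, `experiment_ids` and
#'   `psm_rows` (row indices into the input).
#' @export
aggregate_peptidoforms <- function(psms, protein_map = NULL) {
  if (nrow(psms) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      mod_composition = character(), n_psms = integer(),
                      n_experiments = integer(), stringsAsFactors = FALSE))
  }
  # parse each distinct (sequence, mods) pair once
  key <- paste(psms$sequence, psms$mods, sep = "\r")
  ukey <- !duplicated(key)
  uidx <- which(ukey)
  umods <- lapply(uidx, function(i) parse_mods(psms$mods[i], psms$sequence[i]))
  uids <- vapply(seq_along(uidx), function(j) {
    make_peptidoform_id(psms$sequence[uidx[j]], umods[[j]])
  }, "")
  key_pos <- match(key, key[uidx])
  mods_list <- umods[key_pos]
  ids <- uids[key_pos]
  groups <- split(seq_len(nrow(psms)), ids)

  acc_lookup <- NULL
  if (!is.null(protein_map)) {
    acc_lookup <- split(protein_map$accession, protein_map$sequence)
  }

  rows <- lapply(names(groups), function(id) {
    idx <- groups[[id]]
    sequence <- psms$sequence[idx[1]]
    m <- mods_list[[idx[1]]]
    comp <- sub("^[^|]*\\|?", "", id)
    has <- function(name, residue) {
      any(m$name == name & m$residue == residue)
    }
    accs <- character(0)
    if (!is.null(acc_lookup)) {
      accs <- unique(acc_lookup[[sequence]] %||% character(0))
    }
    exps <- unique(psms$experiment_id[idx])
    data.frame(
      id = id, sequence = sequence, mod_composition = comp,
      n_psms = length(idx), n_experiments = length(exps),
      contains_S = grepl("S", sequence, fixed = TRUE),
      contains_T = grepl("T", sequence, fixed = TRUE),
      contains_Y = grepl("Y", sequence, fixed = TRUE),
      has_pS = has("Phospho", "S"), has_pT = has("Phospho", "T"),
      has_pY = has("Phospho", "Y"),
      has_deamidation = any(m$name == "Deamidated"),
      accessions = paste(accs, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$mass_errors <- I(lapply(names(groups), function(id) {
    psms$mass_error_cal[groups[[id]]]
  }))
  out$experiment_ids <- I(lapply(names(groups), function(id) {
    unique(psms$experiment_id[groups[[id]]])
  }))
  out$psm_rows <- I(unname(groups))
  rownames(out) <- NULL
  out
}

#' Keep only robustly detected peptidoforms
#'
#' Peptidoforms observed in fewer experiments, or with fewer PSMs, than the
#' thresholds cannot support a reliable mixture fit and are dropped. Both
#' thresholds are inclusive and applied as a conjunction.
#'
#' @param peptidoforms Output of [aggregate_peptidoforms()].
#' @param min_experiments Minimum distinct experiments (default 3).
#' @param min_psms Minimum PSM count (default 90).
#' @return Filtered peptidoform data.frame.
#' @export
filter_robust <- function(peptidoforms, min_experiments = 3L, min_psms = 90L) {
  keep <- peptidoforms$n_experiments >= min_experiments &
    peptidoforms$n_psms >= min_psms
  out <- peptidoforms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname aggregate_peptidoforms
#' @param peptidoforms Peptidoform data.frame.
#' @param path Output TSV path.
#' @export
write_peptidoform_summary <- function(peptidoforms, path) {
  cols <- setdiff(names(peptidoforms),
                  c("mass_errors", "experiment_ids", "psm_rows"))
  write_tsv_base(peptidoforms[, cols, drop = FALSE], path)
}
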
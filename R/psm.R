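#' Column dialect for PSM tables
#'
#' Maps the canonical column names used throughout the package to the column
#' names actually present in a tab-separated PSM file, so tables exported
#' from different search pipelines can be ingested without rewriting them.
#' Mass errors must already be expressed as observed minus theoretical
#' precursor *neutral mass* in Da; converting from m/z error is the
#' exporter's responsibility.
#'
#' @param ... Named overrides, canonical name = file column name, e.g.
#'   `scan = "ScanNum"`.
#' @return Named character vector mapping canonical names to file columns.
#' @export
psm_dialect <- function(...) {
  d <- c(
    collection_id = "collection_id", dataset_id = "dataset_id",
    experiment_id = "experiment_id", run_id = "run_id", scan = "scan",
    sequence = "sequence", mods = "mods", charge = "charge",
    mass_error_da = "mass_error_da", q_value = "q_value",
    instrument = "instrument"
  )
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(d))
    if (length(bad)) stop("unknown dialect keys: ", paste(bad, collapse = ", "))
    d[names(ov)] <- ov
  }
  d
}

.required_psm_cols <- c(
  "collection_id", "dataset_id", "experiment_id", "run_id", "scan",
  "sequence", "mods", "charge", "mass_error_da", "q_value"
)

#' Parse a compact modification string
#'
#' The PSM table stores modifications as semicolon-separated
#' `position-residue-name` triples, e.g. `"7-S-Phospho;10-Y-Phospho"`;
#' the empty string denotes an unmodified peptide. Names are normalized
#' case-insensitively against the controlled vocabulary (Phospho, Sulfo,
#' Oxidation, Deamidated, Carbamidomethyl); unknown names are carried
#' through but are never matched by downstream filters.
#'
#' @param mods Modification string.
#' @param sequence Optional peptide sequence; when given, each triple's
#'   residue letter is checked against the sequence character at its position.
#' @return A data.frame with columns `position` (1-based integer), `residue`,
#'   `name`; zero rows for an unmodified peptide.
#' @examples
#' parse_mods("7-S-Phospho;10-Y-Phospho", "VHNDAQSFDYDHDAFLGAEEAK")
#' @export
parse_mods <- function(mods, sequence = NULL) {
  empty <- data.frame(position = integer(), residue = character(),
                      name = character(), stringsAsFactors = FALSE)
  if (is.na(mods) || !nzchar(mods)) return(empty)
  parts <- strsplit(mods, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)-([A-Z])-(.+)$", parts))
  if (any(lengths(m) != 4L)) {
    stop("unparsable modification string: ", mods)
  }
  out <- data.frame(
    position = as.integer(vapply(m, `[`, "", 2L)),
    residue = vapply(m, `[`, "", 3L),
    name = .normalize_mod_name(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  if (!is.null(sequence)) {
    seq_chars <- strsplit(sequence, "")[[1]]
    ok <- out$position >= 1L & out$position <= length(seq_chars) &
      out$residue == seq_chars[pmin(pmax(out$position, 1L), length(seq_chars))]
    if (!all(ok)) {
      stop("modification residue mismatch with sequence '", sequence,
           "' at position(s) ", paste(out$position[!ok], collapse = ", "))
    }
  }
  out
}

#' @rdname parse_mods
#' @param mod_table A data.frame as returned by `parse_mods()`.
#' @export
format_mods <- function(mod_table) {
  if (nrow(mod_table) == 0L) return("")
  paste(sprintf("%d-%s-%s", mod_table$position, mod_table$residue,
                mod_table$name), collapse = ";")
}

#' Read a tab-separated PSM table
#'
#' Reads one peptide-spectrum match per row, remapping columns through a
#' [psm_dialect()], validating each row against the record invariants
#' (non-empty standard-alphabet sequence, `charge >= 1`, `scan >= 1`,
#' `q_value` in \[0, 1\], finite mass error, parseable modification string
#' whose residues match the sequence). Invalid rows are dropped with a
#' reported count; more than 50% invalid rows is treated as a malformed file.
#'
#' @param path File path.
#' @param dialect Column mapping from [psm_dialect()].
#' @return A data.frame of validated PSMs with canonical column names and an
#'   added empty `mass_error_cal` column (filled by [recalibrate()]).
#'   The number of rejected rows is attached as attribute `"n_rejected"`.
#' @export
read_psm_table <- function(path, dialect = psm_dialect()) {
  if (!file.exists(path)) stop("PSM table not found: ", path)
  raw <- read_tsv_base(path,
                       colClasses = "character")
  missing_cols <- setdiff(dialect[.required_psm_cols], names(raw))
  if (length(missing_cols)) {
    stop("PSM table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    collection_id = raw[[dialect[["collection_id"]]]],
    dataset_id = raw[[dialect[["dataset_id"]]]],
    experiment_id = raw[[dialect[["experiment_id"]]]],
    run_id = raw[[dialect[["run_id"]]]],
    scan = suppressWarnings(as.integer(raw[[dialect[["scan"]]]])),
    sequence = raw[[dialect[["sequence"]]]],
    mods = raw[[dialect[["mods"]]]],
    charge = suppressWarnings(as.integer(raw[[dialect[["charge"]]]])),
    mass_error_da = suppressWarnings(as.numeric(raw[[dialect[["mass_error_da"]]]])),
    q_value = suppressWarnings(as.numeric(raw[[dialect[["q_value"]]]])),
    stringsAsFactors = FALSE
  )
  inst_col <- dialect[["instrument"]]
  out$instrument <- if (inst_col %in% names(raw)) raw[[inst_col]] else NA_character_
  out$mods[is.na(out$mods)] <- ""

  ok <- validate_psm_rows(out)
  n_rejected <- sum(!ok)
  if (nrow(out) > 0L && n_rejected > nrow(out) / 2) {
    stop("more than half of the PSM rows are invalid (", n_rejected, "/",
         nrow(out), "); check the dialect mapping")
  }
  if (n_rejected > 0L) {
    message("read_psm_table: rejected ", n_rejected, " invalid row(s)")
  }
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  out$mass_error_cal <- rep(NA_real_, nrow(out))
  attr(out, "n_rejected") <- n_rejected
  out
}

validate_psm_rows <- function(psms) {
  seq_ok <- !is.na(psms$sequence) & nzchar(psms$sequence) &
    grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", psms$sequence)
  num_ok <- !is.na(psms$scan) & psms$scan >= 1L &
    !is.na(psms$charge) & psms$charge >= 1L &
    is.finite(psms$mass_error_da) &
    !is.na(psms$q_value) & psms$q_value >= 0 & psms$q_value <= 1
  mods_ok <- vapply(seq_len(nrow(psms)), function(i) {
    if (!seq_ok[i]) return(FALSE)
    tryCatch({
      parse_mods(psms$mods[i], psms$sequence[i])
      TRUE
    }, error = function(e) FALSE)
  }, logical(1))
  seq_ok & num_ok & mods_ok
}

#' @rdname read_psm_table
#' @param psms PSM data.frame.
#' @export
write_psm_table <- function(psms, path) {
  cols <- c(.required_psm_cols, "instrument")
  write_tsv_base(psms[, intersect(cols, names(psms)), drop = FALSE], path)
}

#' Filter PSMs by q-value
#'
#' Retains PSMs with `q_value` strictly below the threshold, preserving input
#' order.
#'
#' @param psms PSM data.frame.
#' @param q_threshold FDR threshold; default 0.01.
#' @return Filtered PSM data.frame.
#' @export
filter_fdr <- function(psms, q_threshold = 0.01) {
  stopifnot(!anyNA(psms$q_value))
  out <- psms[psms$q_value < q_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recalibrate precursor mass errors per MS run
#'
#' Computes, for each `run_id`, the median raw mass error across all of the
#' run's (FDR-passing) PSMs and subtracts it from every PSM of that run,
#' writing the result to `mass_error_cal`. A run with a single PSM gets a
#' calibrated error of exactly 0 (the median of one value is itself).
#' Recalibration always starts from `mass_error_da`, so it is idempotent and
#' preserves within-run differences exactly.
#'
#' @param psms PSM data.frame (already FDR-filtered).
#' @param verbose Emit per-run median offsets via `message()`.
#' @return The PSM data.frame with `mass_error_cal` filled; the per-run
#'   medians are attached as attribute `"run_offsets"`.
#' @export
recalibrate <- function(psms, verbose = FALSE) {
  if (nrow(psms) == 0L) {
    psms$mass_error_cal <- numeric(0)
    attr(psms, "run_offsets") <- numeric(0)
    return(psms)
  }
  med <- tapply(psms$mass_error_da, psms$run_id, stats::median)
  psms$mass_error_cal <- as.numeric(psms$mass_error_da - med[psms$run_id])
  singletons <- names(which(table(psms$run_id) == 1L))
  if (verbose) {
    message("recalibrate: ", length(med), " run(s); median offsets in [",
            signif(min(med), 3), ", ", signif(max(med), 3), "] Da")
    if (length(singletons)) {
      message("recalibrate: ", length(singletons),
              " single-PSM run(s) calibrated to 0")
    }
  }
  attr(psms, "run_offsets") <- med
  psms
}

#' Retain PSMs carrying phosphorylation on S, T or Y
#'
#' @param psms PSM data.frame with parsed-compatible `mods` strings.
#' @return PSMs having at least one `Phospho` modification on serine,
#'   threonine or tyrosine. Phosphorylation reported on any other residue
#'   does not qualify.
#' @export
filter_phospho <- function(psms) {
  keep <- vapply(seq_len(nrow(psms)), function(i) {
    m <- parse_mods(psms$mods[i])
    any(m$name == "Phospho" & m$residue %in% c("S", "T", "Y"))
  }, logical(1))
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
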
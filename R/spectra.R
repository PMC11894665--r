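#' Spectrum interpretation: a peptidoform plus charge and notation class
#'
#' Holds a peptide sequence, its modifications and the precursor charge.
#' Each modification carries a notation class: mass-retaining modifications
#' render with square brackets (`Y[Phospho]`) and contribute their mass to
#' every fragment containing the site, while fully labile modifications
#' render with curly braces (`Y{Sulfo}`) and contribute nothing to any
#' fragment — the precursor still carries their mass. Sulfo is labile by
#' default; everything else is mass-retaining.
#'
#' @param sequence Peptide sequence.
#' @param mods Modification data.frame (`position`, `residue`, `name`), as
#'   from [parse_mods()], or a compact mods string. An optional logical
#'   `labile` column overrides the default notation class.
#' @param charge Precursor charge.
#' @return Object of class `spectrum_interpretation`.
#' @export
spectrum_interpretation <- function(sequence, mods, charge) {
  if (is.character(mods)) mods <- parse_mods(mods, sequence)
  if (is.null(mods$labile)) {
    mods$labile <- mods$name == "Sulfo"
  }
  known <- .mod_masses()
  mods$mass_delta <- unname(known[mods$name])
  if (nrow(mods) && anyNA(mods$mass_delta)) {
    stop("modification(s) outside the controlled vocabulary: ",
         paste(unique(mods$name[is.na(mods$mass_delta)]), collapse = ", "))
  }
  stopifnot(charge >= 1)
  structure(list(sequence = sequence, mods = mods,
                 charge = as.integer(charge)),
            class = "spectrum_interpretation")
}

#' @export
print.spectrum_interpretation <- function(x, ...) {
  cat(proforma(x), "/", x$charge, "\n", sep = "")
  invisible(x)
}

#' Render / parse the ProForma notation subset
#'
#' `proforma()` writes the sequence with `[Name]` tags for mass-retaining
#' and `{Name}` tags for labile modifications placed after the modified
#' residue; `parse_proforma()` inverts it. Only this bracket subset of
#' ProForma 2.0 is supported.
#'
#' @param interpretation A [spectrum_interpretation()].
#' @return `proforma()`: the notation string (without charge suffix).
#' @export
proforma <- function(interpretation) {
  chars <- strsplit(interpretation$sequence, "")[[1]]
  m <- interpretation$mods
  if (nrow(m)) {
    m <- m[order(m$position), , drop = FALSE]
    for (i in seq_len(nrow(m))) {
      tag <- if (m$labile[i]) paste0("{", m$name[i], "}")
             else paste0("[", m$name[i], "]")
      chars[m$position[i]] <- paste0(chars[m$position[i]], tag)
    }
  }
  paste(chars, collapse = "")
}

#' @rdname proforma
#' @param string ProForma string (no charge suffix).
#' @param charge Precursor charge for the reconstructed interpretation.
#' @export
parse_proforma <- function(string, charge) {
  tokens <- regmatches(
    string,
    gregexpr("[A-Z](\\[[^]]+\\]|\\{[^}]+\\})*", string)
  )[[1]]
  if (!nzchar(paste(tokens, collapse = "")) ||
      nchar(paste(tokens, collapse = "")) != nchar(string)) {
    stop("unparsable ProForma string: ", string)
  }
  seq_chars <- substr(tokens, 1, 1)
  rows <- list()
  for (i in seq_along(tokens)) {
    tags <- regmatches(tokens[i],
                       gregexpr("\\[[^]]+\\]|\\{[^}]+\\}", tokens[i]))[[1]]
    for (tag in tags) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = i, residue = seq_chars[i],
        name = substr(tag, 2, nchar(tag) - 1L),
        labile = startsWith(tag, "{"),
        stringsAsFactors = FALSE
      )
    }
  }
  mods <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), residue = character(),
               name = character(), labile = logical(),
               stringsAsFactors = FALSE)
  spectrum_interpretation(paste(seq_chars, collapse = ""), mods, charge)
}

#' Precursor neutral mass of an interpretation
#'
#' Sum of residue masses plus water plus all modification masses; labile
#' modifications count here (they are only lost from fragments).
#'
#' @param interpretation A [spectrum_interpretation()].
#' @return Neutral monoisotopic mass (Da).
#' @export
precursor_neutral_mass <- function(interpretation) {
  mc <- mass_constants()
  chars <- strsplit(interpretation$sequence, "")[[1]]
  sum(mc$residue_masses[chars]) + mc$water_mass +
    sum(interpretation$mods$mass_delta)
}

#' Theoretical b/y fragment ions under a modification hypothesis
#'
#' Generates singly and doubly protonated b and y ions for every backbone
#' bond. Mass-retaining modifications add their delta to each fragment
#' containing the modified residue; labile modifications (curly-brace
#' notation, e.g. `{Sulfo}`) are fully lost from all fragments, so the
#' fragment series matches the unmodified peptide while the precursor mass
#' still includes the modification. No phospho neutral-loss series is
#' generated.
#'
#' @param interpretation A [spectrum_interpretation()].
#' @param max_fragment_charge Cap on fragment charge; the effective cap is
#'   `min(max_fragment_charge, precursor charge)`.
#' @return Data.frame with columns `type` ("b"/"y"), `index`, `charge`,
#'   `mz`; peptide length is attached as attribute `"peptide_length"`.
#' @export
theoretical_fragments <- function(interpretation, max_fragment_charge = 2L) {
  mc <- mass_constants()
  chars <- strsplit(interpretation$sequence, "")[[1]]
  if (anyNA(mc$residue_masses[chars])) {
    stop("unknown residue in sequence: ", interpretation$sequence)
  }
  L <- length(chars)
  res <- unname(mc$residue_masses[chars])
  m <- interpretation$mods
  # per-position retained modification mass
  site_mass <- numeric(L)
  if (nrow(m)) {
    retained <- m[!m$labile & m$position >= 1L, , drop = FALSE]
    for (i in seq_len(nrow(retained))) {
      site_mass[retained$position[i]] <-
        site_mass[retained$position[i]] + retained$mass_delta[i]
    }
  }
  prefix <- cumsum(res + site_mass)          # b_i neutral residue sum
  total <- prefix[L]
  zmax <- min(max_fragment_charge, interpretation$charge)
  rows <- list()
  for (z in seq_len(zmax)) {
    idx <- seq_len(L - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      type = "b", index = idx, charge = z,
      mz = (prefix[idx] + z * mc$proton_mass) / z,
      stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1L]] <- data.frame(
      type = "y", index = idx, charge = z,
      mz = (total - prefix[L - idx] + mc$water_mass + z * mc$proton_mass) / z,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "peptide_length") <- L
  out
}

#' Match observed peaks to theoretical fragments
#'
#' For every theoretical ion, the most intense peak within `tolerance` m/z is
#' selected (ties broken by smallest absolute m/z difference). Summary
#' metrics follow the spectrum-annotation conventions: the fraction of total
#' ion current carried by matched (distinct) peaks, and the fraction of
#' inter-residue bonds supported by at least one matched b or y ion.
#'
#' @param peaks Data.frame with columns `mz`, `intensity` (any order).
#' @param theoretical Fragment table from [theoretical_fragments()].
#' @param tolerance Matching half-window in Th (default 0.05).
#' @return A list of class `spectrum_annotation`: `matches` (data.frame of
#'   matched ions with observed m/z and intensity),
#'   `tic_fraction_annotated`, `residues_supported`, `n_bonds`, `n_peaks`.
#' @export
match_peaks <- function(peaks, theoretical, tolerance = 0.05) {
  L <- attr(theoretical, "peptide_length")
  n_bonds <- L - 1L
  if (is.null(peaks) || nrow(peaks) == 0L) {
    return(structure(list(
      matches = cbind(theoretical[0, , drop = FALSE],
                      observed_mz = numeric(0), intensity = numeric(0)),
      tic_fraction_annotated = 0, residues_supported = 0,
      n_bonds = n_bonds, n_peaks = 0L
    ), class = "spectrum_annotation"))
  }
  hit <- integer(nrow(theoretical))
  for (i in seq_len(nrow(theoretical))) {
    d <- abs(peaks$mz - theoretical$mz[i])
    cand <- which(d <= tolerance)
    if (!length(cand)) { hit[i] <- NA_integer_; next }
    best <- cand[order(-peaks$intensity[cand], d[cand])][1]
    hit[i] <- best
  }
  matched <- !is.na(hit)
  matches <- theoretical[matched, , drop = FALSE]
  matches$observed_mz <- peaks$mz[hit[matched]]
  matches$intensity <- peaks$intensity[hit[matched]]
  rownames(matches) <- NULL
  tic <- sum(peaks$intensity)
  tic_fraction <- if (tic > 0) {
    sum(peaks$intensity[unique(hit[matched])]) / tic
  } else 0
  bond <- ifelse(matches$type == "b", matches$index, L - matches$index)
  structure(list(
    matches = matches,
    tic_fraction_annotated = tic_fraction,
    residues_supported = length(unique(bond)) / n_bonds,
    n_bonds = n_bonds,
    n_peaks = nrow(peaks)
  ), class = "spectrum_annotation")
}

#' @export
print.spectrum_annotation <- function(x, ...) {
  cat("Spectrum annotation: ", nrow(x$matches), " matched ions over ",
      x$n_peaks, " peaks\n", sep = "")
  cat(sprintf("  %%TIC annotated: %.1f%%   bonds supported: %.1f%% (%d bonds)\n",
              100 * x$tic_fraction_annotated, 100 * x$residues_supported,
              x$n_bonds))
  invisible(x)
}

#' Compare sulfation and phosphorylation hypotheses on one spectrum
#'
#' Annotates the same peak list under both interpretations and rules for
#' sulfation only when the sulfo annotation strictly beats the phospho
#' annotation on *both* the fraction of bonds supported and the fraction of
#' total ion current annotated; the symmetric rule yields phospho-favored,
#' anything else is inconclusive.
#'
#' @param peaks Peak data.frame (`mz`, `intensity`).
#' @param sulfo_interp,phospho_interp [spectrum_interpretation()] objects
#'   sharing sequence and charge.
#' @param tolerance Matching tolerance in Th (default 0.05).
#' @return List with `verdict` ("sulfo-favored" / "phospho-favored" /
#'   "inconclusive"), `sulfo` and `phospho` annotations.
#' @export
compare_hypotheses <- function(peaks, sulfo_interp, phospho_interp,
                               tolerance = 0.05) {
  stopifnot(sulfo_interp$sequence == phospho_interp$sequence,
            sulfo_interp$charge == phospho_interp$charge)
  ann_s <- match_peaks(peaks, theoretical_fragments(sulfo_interp), tolerance)
  ann_p <- match_peaks(peaks, theoretical_fragments(phospho_interp), tolerance)
  verdict <- if (ann_s$residues_supported > ann_p$residues_supported &&
                 ann_s$tic_fraction_annotated > ann_p$tic_fraction_annotated) {
    "sulfo-favored"
  } else if (ann_p$residues_supported > ann_s$residues_supported &&
             ann_p$tic_fraction_annotated > ann_s$tic_fraction_annotated) {
    "phospho-favored"
  } else {
    "inconclusive"
  }
  list(verdict = verdict, sulfo = ann_s, phospho = ann_p)
}

#' Alternative (sulfation) interpretations for a phospho PSM
#'
#' Builds the sulfation hypotheses to pit against the original phospho
#' assignment. If phosphorylation was assigned to a tyrosine, one
#' `Y[Phospho]` is rewritten to `Y{Sulfo}`; if phosphorylation sits only on
#' non-tyrosine residues, one phospho is removed and a `{Sulfo}` is placed on
#' a tyrosine. When a second rewrite is possible (at least two phosphos and
#' two tyrosines), a doubly rewritten variant is emitted as well. Site
#' selection is deterministic (lowest position) by default; the seeded-random
#' strategy reproduces a random-choice protocol.
#'
#' Deamidated PSMs are refused (the isotopomer artifact makes their precursor
#' shift uninterpretable), as are peptides without tyrosine.
#'
#' @param psm One-row PSM data.frame (columns `sequence`, `mods`, `charge`).
#' @param strategy `"deterministic"` (default) or `"seeded-random"`.
#' @param seed Seed for the random strategy.
#' @return List of [spectrum_interpretation()] objects (singly rewritten
#'   first).
#' @export
alternative_interpretations <- function(psm, strategy = c("deterministic",
                                                          "seeded-random"),
                                        seed = 1L) {
  strategy <- match.arg(strategy)
  mods <- parse_mods(psm$mods, psm$sequence)
  if (any(mods$name == "Deamidated")) {
    stop("deamidated peptidoforms are not assessed for sulfation")
  }
  y_pos <- which(strsplit(psm$sequence, "")[[1]] == "Y")
  if (!length(y_pos)) stop("no tyrosine in sequence; cannot place a sulfation")
  phospho_idx <- which(mods$name == "Phospho")
  if (!length(phospho_idx)) stop("PSM carries no phosphorylation to rewrite")

  pick <- function(choices) {
    if (length(choices) == 1L) return(choices)
    if (strategy == "deterministic") min(choices)
    else with_seed(seed, sample(choices, 1L))
  }

  rewrite_once <- function(mods) {
    p_on_y <- phospho_rows <- which(mods$name == "Phospho")
    p_on_y <- phospho_rows[mods$residue[phospho_rows] == "Y"]
    if (length(p_on_y)) {
      row <- p_on_y[which(mods$position[p_on_y] == pick(mods$position[p_on_y]))][1]
      mods$name[row] <- "Sulfo"
      mods$labile <- NULL
    } else {
      row <- phospho_rows[which(mods$position[phospho_rows] ==
                                  pick(mods$position[phospho_rows]))][1]
      mods <- mods[-row, , drop = FALSE]
      free_y <- setdiff(y_pos, mods$position)
      if (!length(free_y)) stop("no unmodified tyrosine available")
      yp <- pick(free_y)
      mods <- rbind(mods, data.frame(position = yp, residue = "Y",
                                     name = "Sulfo",
                                     stringsAsFactors = FALSE))
    }
    mods[order(mods$position), , drop = FALSE]
  }

  out <- list()
  single <- rewrite_once(mods)
  out[[1]] <- spectrum_interpretation(psm$sequence, single, psm$charge)
  if (length(phospho_idx) >= 2L && length(y_pos) >= 2L) {
    still_phospho <- any(single$name == "Phospho")
    if (still_phospho) {
      double <- rewrite_once(single)
      out[[2]] <- spectrum_interpretation(psm$sequence, double, psm$charge)
    }
  }
  out
}

#' Build and parse Universal Spectrum Identifiers
#'
#' Serializes a PSM plus interpretation to the USI template
#' `mzspec:<CollectionID>:<msRunComponent>:scan:<ScanNumber>:<ProForma>/<charge>`
#' and parses it back losslessly.
#'
#' @param psm One-row PSM data.frame (columns `collection_id`, `run_id`,
#'   `scan`).
#' @param interpretation A [spectrum_interpretation()].
#' @return `build_usi()`: the USI string.
#' @export
build_usi <- function(psm, interpretation) {
  fields <- c(psm$collection_id, psm$run_id, psm$scan)
  if (any(is.na(fields) | !nzchar(as.character(fields)))) {
    stop("missing identifier field (collection_id, run_id or scan)")
  }
  paste0("mzspec:", psm$collection_id, ":", psm$run_id, ":scan:", psm$scan,
         ":", proforma(interpretation), "/", interpretation$charge)
}

#' @rdname build_usi
#' @param usi A USI string.
#' @return `parse_usi()`: a list with `collection_id`, `ms_run_component`,
#'   `index_flag`, `scan_number`, `interpretation`.
#' @export
parse_usi <- function(usi) {
  parts <- strsplit(usi, ":", fixed = TRUE)[[1]]
  if (length(parts) != 6L || parts[1] != "mzspec" || parts[4] != "scan") {
    stop("not a valid USI: ", usi)
  }
  ip <- sub("/[0-9]+$", "", parts[6])
  charge <- as.integer(sub(".*/", "", parts[6]))
  list(
    collection_id = parts[2],
    ms_run_component = parts[3],
    index_flag = parts[4],
    scan_number = as.integer(parts[5]),
    interpretation = parse_proforma(ip, charge)
  )
}
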
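#' Residue-class partition of the 20 standard amino acids
#'
#' Acidic (D, E), basic (K, R, H), neutral (A, V, L, I, M, F, W, P, G) and
#' polar (S, T, Y, N, Q, C). The four classes partition the standard
#' alphabet.
#'
#' @return Named list of character vectors.
#' @export
residue_classes <- function() {
  list(
    acidic = c("D", "E"),
    basic = c("K", "R", "H"),
    neutral = c("A", "V", "L", "I", "M", "F", "W", "P", "G"),
    polar = c("S", "T", "Y", "N", "Q", "C")
  )
}

#' Extract flanking windows around tyrosine sites
#'
#' Returns the up-to-`w` residues on each side of every listed Y position,
#' truncated (never padded) at the protein termini. The stated positions
#' must index tyrosines; anything else is an error naming the offending
#' accession/position.
#'
#' @param protein_sequence Protein sequence string.
#' @param y_positions 1-based positions of Y residues.
#' @param accession Accession used in error messages and output.
#' @param w Flank width on each side (default 7).
#' @param origin Label carried through to [class_composition()]
#'   ("foreground" or "background").
#' @return Data.frame with columns `accession`, `y_position`, `window`,
#'   `origin`; the window string includes the central Y.
#' @export
extract_flanks <- function(protein_sequence, y_positions, accession = "",
                           w = 7L, origin = "foreground") {
  chars <- strsplit(protein_sequence, "")[[1]]
  L <- length(chars)
  windows <- vapply(y_positions, function(p) {
    if (p < 1L || p > L || chars[p] != "Y") {
      stop("position ", p, " of ", accession, " is not a tyrosine")
    }
    paste(chars[max(1L, p - w):min(L, p + w)], collapse = "")
  }, "")
  data.frame(accession = accession, y_position = as.integer(y_positions),
             window = windows, origin = origin, stringsAsFactors = FALSE)
}

#' Residue-class composition of flanking windows
#'
#' Counts acidic/basic/neutral/polar residues over all flanking positions,
#' excluding the central Y itself, and reports fractions per origin
#' (foreground vs background). Windows are deduplicated by
#' (accession, y_position) first, so a site reached through several
#' peptidoforms is counted once.
#'
#' @param windows Data.frame as from [extract_flanks()] (rows from both
#'   origins may be concatenated).
#' @param scheme Residue-class scheme from [residue_classes()].
#' @param exclude_center Drop the central Y from the counts (default TRUE).
#' @param w Flank width used to locate the center in truncated windows.
#' @return Data.frame with columns `origin`, `class`, `count`, `fraction`;
#'   fractions sum to 1 within each origin.
#' @export
class_composition <- function(windows, scheme = residue_classes(),
                              exclude_center = TRUE, w = 7L) {
  stopifnot(nrow(windows) > 0L)
  windows <- windows[!duplicated(windows[, c("accession", "y_position",
                                             "origin")]), , drop = FALSE]
  class_of <- character(0)
  for (cl in names(scheme)) class_of[scheme[[cl]]] <- cl

  rows <- lapply(split(windows, windows$origin), function(g) {
    counts <- stats::setNames(numeric(length(scheme)), names(scheme))
    for (i in seq_len(nrow(g))) {
      chars <- strsplit(g$window[i], "")[[1]]
      if (exclude_center) {
        # center = the Y at min(w, y_position - 1) + 1 in the truncated window
        center <- min(w, g$y_position[i] - 1L) + 1L
        chars <- chars[-center]
      }
      tab <- table(factor(class_of[chars], levels = names(scheme)))
      counts <- counts + as.numeric(tab)
    }
    data.frame(origin = g$origin[1], class = names(scheme),
               count = as.numeric(counts),
               fraction = as.numeric(counts) / sum(counts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a plain named
#' character vector keyed by the first whitespace-delimited token of each
#' header.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  seqs
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
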
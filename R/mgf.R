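#' Read and write Mascot Generic Format (MGF) peak lists
#'
#' Minimal line-oriented MGF support: `BEGIN IONS`/`END IONS` blocks with
#' `TITLE`, `PEPMASS`, `CHARGE` headers and whitespace-separated
#' m/z-intensity pairs.
#'
#' @param path MGF file path.
#' @return `read_mgf()`: a list of spectra, each a list with `title`,
#'   `pepmass`, `charge` and `peaks` (data.frame `mz`, `intensity`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("malformed MGF: unbalanced BEGIN/END IONS")
  }
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    is_header <- grepl("=", block, fixed = TRUE)
    headers <- block[is_header]
    kv <- strsplit(headers, "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, "", 1L))
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    peak_lines <- block[!is_header & nzchar(trimws(block))]
    peaks <- if (length(peak_lines)) {
      mat <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "[ \t]+"),
                                   function(x) as.numeric(x[1:2])))
      data.frame(mz = mat[, 1], intensity = mat[, 2])
    } else {
      data.frame(mz = numeric(), intensity = numeric())
    }
    list(
      title = if ("TITLE" %in% keys) vals[keys == "TITLE"][1] else NA_character_,
      pepmass = if ("PEPMASS" %in% keys)
        as.numeric(strsplit(vals[keys == "PEPMASS"][1], " ")[[1]][1])
        else NA_real_,
      charge = if ("CHARGE" %in% keys)
        as.integer(sub("\\+$", "", vals[keys == "CHARGE"][1])) else NA_integer_,
      peaks = peaks
    )
  })
}

#' @rdname read_mgf
#' @param spectra List of spectra (as returned by `read_mgf()`).
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.null(sp$title) && !is.na(sp$title)) {
      writeLines(paste0("TITLE=", sp$title), con)
    }
    if (!is.null(sp$pepmass) && !is.na(sp$pepmass)) {
      writeLines(sprintf("PEPMASS=%.6f", sp$pepmass), con)
    }
    if (!is.null(sp$charge) && !is.na(sp$charge)) {
      writeLines(paste0("CHARGE=", sp$charge, "+"), con)
    }
    if (nrow(sp$peaks)) {
      writeLines(sprintf("%.6f %.2f", sp$peaks$mz, sp$peaks$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}
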
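#' Read and write GMT term maps
#'
#' GMT is the tab-separated gene-set format: one term per line as
#' `term <tab> description <tab> member1 <tab> member2 ...`. No ontology
#' traversal is performed; if parent-term propagation is wanted it must be
#' pre-baked into the file.
#'
#' @param path GMT file path.
#' @param category Category label attached to every term read
#'   (e.g. "GO-BP", "custom").
#' @return A named list of terms, each a list with `name`, `category`,
#'   `members` (character vector of accessions).
#' @export
read_gmt <- function(path, category = "GO-BP") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    list(name = parts[2], category = category,
         members = unique(parts[-(1:2)]))
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, "", USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @param terms Term map (named list with `members`).
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(names(terms), function(id) {
    t <- terms[[id]]
    paste(c(id, t$name %||% id, t$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Build the custom sulfation-context term map
#'
#' Derives five terms from a protein annotation table using case-insensitive
#' substring rules: `known_sY` (annotation flag), `Secreted` ("secreted"
#' appears in the subcellular location), `Transmembrane` (the transmembrane
#' column is non-empty), `Golgi` ("golgi" appears in the protein name or
#' subcellular location), and `unlikely_sY` (the complement of the union of
#' the other four).
#'
#' @param annotation Data.frame with columns `accession`, `protein_name`,
#'   `subcellular_location`, `transmembrane`, `known_sY` (logical or 0/1).
#' @return A term map (named list) with category `"custom"`.
#' @export
build_custom_terms <- function(annotation) {
  need <- c("accession", "protein_name", "subcellular_location",
            "transmembrane", "known_sY")
  missing_cols <- setdiff(need, names(annotation))
  if (length(missing_cols)) {
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  acc <- annotation$accession
  loc <- ifelse(is.na(annotation$subcellular_location), "",
                annotation$subcellular_location)
  nm <- ifelse(is.na(annotation$protein_name), "", annotation$protein_name)
  tm <- ifelse(is.na(annotation$transmembrane), "", annotation$transmembrane)
  known <- as.logical(annotation$known_sY)
  known[is.na(known)] <- FALSE

  members <- list(
    known_sY = acc[known],
    Secreted = acc[grepl("secreted", loc, ignore.case = TRUE)],
    Transmembrane = acc[nzchar(trimws(tm))],
    Golgi = acc[grepl("golgi", paste(nm, loc), ignore.case = TRUE)]
  )
  members$unlikely_sY <- setdiff(acc, unique(unlist(members)))
  lapply(members, function(m) {
    list(name = NULL, category = "custom", members = unique(m))
  }) -> out
  for (id in names(out)) out[[id]]$name <- id
  out
}

#' One-sided hypergeometric over-representation p-value
#'
#' Probability of observing `k` or more annotated proteins in a foreground of
#' size `n` drawn from a background of `N` proteins of which `K` are
#' annotated, i.e. `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Delegates
#' to [stats::phyper()] (upper tail, computed stably).
#'
#' @param k Foreground hits.
#' @param n Foreground size.
#' @param K Background hits.
#' @param N Background size.
#' @return The upper-tail p-value.
#' @examples
#' hypergeom_test(3, 6, 5, 20)  # 5090/38760
#' @export
hypergeom_test <- function(k, n, K, N) {
  stopifnot(k >= 0, k <= n, n <= N, K <= N)
  if (k > K) {
    warning("k > K: impossible configuration, returning p = 0")
    return(0)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#' Delegates to [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a protein set against a term map
#'
#' Tests each term's background overlap for enrichment in the foreground via
#' the one-sided hypergeometric test, adjusting p-values with
#' Benjamini-Hochberg ([stats::p.adjust()]) *within each term category*
#' (GO-BP, GO-CC, GO-MF and custom are adjusted independently, as separate
#' analyses). Terms whose background overlap is below `min_set_size` are
#' dropped before testing.
#'
#' @param foreground Character vector of protein accessions (subset of
#'   background; deduplicated internally).
#' @param background Character vector, the universe of accessions.
#' @param terms Term map from [read_gmt()] / [build_custom_terms()].
#' @param q_cutoff Keep only results with adjusted p at or below this value;
#'   `NA` disables the cutoff (used for the small custom-term map).
#' @param min_set_size Minimum background overlap for a term to be tested
#'   (default 1).
#' @return Data.frame with columns `term_id`, `term_name`, `category`, `k`,
#'   `n`, `K`, `N`, `gene_ratio`, `p_value`, `p_adjusted`, sorted by
#'   `p_adjusted` then `p_value`.
#' @export
run_ora <- function(foreground, background, terms, q_cutoff = 0.1,
                    min_set_size = 1L) {
  background <- unique(background)
  foreground <- unique(foreground)
  if (!all(foreground %in% background)) {
    stop("foreground contains accessions outside the background universe")
  }
  if (length(foreground) == 0L) {
    warning("empty foreground; returning no results")
    return(data.frame(term_id = character(), term_name = character(),
                      category = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), gene_ratio = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      stringsAsFactors = FALSE))
  }
  N <- length(background)
  n <- length(foreground)
  rows <- lapply(names(terms), function(id) {
    t <- terms[[id]]
    bg_members <- intersect(t$members, background)
    K <- length(bg_members)
    if (K < min_set_size) return(NULL)
    k <- length(intersect(foreground, bg_members))
    data.frame(term_id = id, term_name = t$name %||% id,
               category = t$category %||% "custom",
               k = k, n = n, K = K, N = N,
               gene_ratio = k / n,
               p_value = hypergeom_test(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L) {
    return(data.frame(term_id = character(), term_name = character(),
                      category = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), gene_ratio = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      stringsAsFactors = FALSE))
  }
  res$p_adjusted <- NA_real_
  for (cat in unique(res$category)) {
    idx <- res$category == cat
    res$p_adjusted[idx] <- stats::p.adjust(res$p_value[idx], method = "BH")
  }
  if (!is.na(q_cutoff)) {
    res <- res[res$p_adjusted <= q_cutoff, , drop = FALSE]
  }
  res <- res[order(res$p_adjusted, res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}
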
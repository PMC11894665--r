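#' Pipeline configuration
#'
#' Collects every stage threshold with its default, plus input/output paths.
#' Configurations serialize losslessly to YAML; every pipeline report embeds
#' a hash of the serialized configuration so outputs are traceable to their
#' settings.
#'
#' @param psm_path PSM TSV path (required unless a PSM data.frame is passed
#'   to [run_pipeline()] directly).
#' @param protein_map_path Optional peptide-to-accession TSV
#'   (`sequence`, `accession`).
#' @param annotation_path Optional protein annotation TSV for the custom
#'   terms.
#' @param gmt_path Optional GO-style GMT file.
#' @param fasta_path Optional protein FASTA (enables flank composition).
#' @param out_dir Output directory for stage TSVs and the run log.
#' @param q_threshold FDR threshold (default 0.01, strict).
#' @param min_experiments,min_psms Robustness filters (defaults 3 and 90).
#' @param delta_bic BIC parsimony margin (default 10).
#' @param auc_threshold Bin assignment threshold (default 0.15).
#' @param match_tolerance MS2 matching tolerance, Th (default 0.05).
#' @param flank_width Flank window half-width (default 7).
#' @param ora_q_cutoff Adjusted-p cutoff for GO ORA (default 0.1; the custom
#'   terms are always reported uncut).
#' @param require_context Context gating for the candidate shortlist.
#' @param thresholds A [calling_thresholds()] object.
#' @param seed Seed forwarded to the mixture fits.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(psm_path = NULL, protein_map_path = NULL,
                            annotation_path = NULL, gmt_path = NULL,
                            fasta_path = NULL, out_dir = NULL,
                            q_threshold = 0.01, min_experiments = 3L,
                            min_psms = 90L, delta_bic = 10,
                            auc_threshold = 0.15, match_tolerance = 0.05,
                            flank_width = 7L, ora_q_cutoff = 0.1,
                            require_context = TRUE,
                            thresholds = calling_thresholds(),
                            seed = 1L) {
  structure(list(
    psm_path = psm_path, protein_map_path = protein_map_path,
    annotation_path = annotation_path, gmt_path = gmt_path,
    fasta_path = fasta_path, out_dir = out_dir,
    q_threshold = q_threshold, min_experiments = min_experiments,
    min_psms = min_psms, delta_bic = delta_bic,
    auc_threshold = auc_threshold, match_tolerance = match_tolerance,
    flank_width = flank_width, ora_q_cutoff = ora_q_cutoff,
    require_context = require_context, thresholds = thresholds,
    seed = seed
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- y$thresholds
  y$thresholds <- NULL
  cfg <- do.call(pipeline_config, y)
  if (!is.null(th)) {
    th$undetermined_range <- unlist(th$undetermined_range)
    cfg$thresholds <- do.call(calling_thresholds, th)
  }
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$thresholds <- unclass(y$thresholds)
  yaml::write_yaml(y, path)
  invisible(path)
}

.config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  # small rolling hash; stable across platforms
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full detection pipeline
#'
#' Executes the stages in order: FDR filter, per-run recalibration, phospho
#' filter, peptidoform aggregation, robustness filter, per-peptidoform
#' mixture fitting and bin assignment, bin composition, histogram calling
#' with biological context, candidate shortlisting, per-bin
#' over-representation analyses, and flank acidity composition (when a FASTA
#' is supplied). Per-stage TSVs and a run log with stage counts are written
#' to `config$out_dir` when set.
#'
#' @param config A [pipeline_config()].
#' @param psms Optional PSM data.frame, overriding `config$psm_path`.
#' @return A list with the per-stage tables: `counts`, `peptidoforms`,
#'   `models`, `assignments`, `model_report`, `composition`, `calls`,
#'   `shortlist`, `enrichment`, `flank_composition`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), psms = NULL) {
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  say("config hash: ", .config_hash(config))

  if (is.null(psms)) {
    if (is.null(config$psm_path)) stop("stage ingest: no PSM input provided")
    psms <- read_psm_table(config$psm_path)
  }
  say("ingested PSMs: ", nrow(psms))

  fdr <- filter_fdr(psms, config$q_threshold)
  say("PSMs with q < ", config$q_threshold, ": ", nrow(fdr))
  cal <- recalibrate(fdr)
  offs <- attr(cal, "run_offsets")
  say("recalibrated ", length(offs), " run(s); median offsets in [",
      signif(min(offs), 3), ", ", signif(max(offs), 3), "] Da")
  pho <- filter_phospho(cal)
  say("phospho PSMs (pS/pT/pY): ", nrow(pho))

  protein_map <- NULL
  if (!is.null(config$protein_map_path)) {
    protein_map <- read_tsv_base(config$protein_map_path)
  }
  agg <- aggregate_peptidoforms(pho, protein_map)
  say("distinct peptidoforms: ", nrow(agg))
  robust <- filter_robust(agg, config$min_experiments, config$min_psms)
  say("robust peptidoforms (>= ", config$min_experiments,
      " experiments, >= ", config$min_psms, " PSMs): ", nrow(robust))

  counts <- data.frame(
    stage = c("ingested", "fdr", "phospho", "aggregated", "robust"),
    n = c(nrow(psms), nrow(fdr), nrow(pho), nrow(agg), nrow(robust))
  )

  if (nrow(robust) == 0L) {
    result <- list(counts = counts, peptidoforms = robust, models = list(),
                   assignments = list(), model_report = NULL,
                   composition = NULL, calls = NULL, shortlist = NULL,
                   enrichment = NULL, flank_composition = NULL,
                   config_hash = .config_hash(config), log = log_lines)
    .write_pipeline_outputs(result, config)
    return(result)
  }

  fitted <- fit_peptidoform_models(robust, threshold = config$auc_threshold,
                                   seed = config$seed,
                                   delta = config$delta_bic)
  n_boi <- sum(vapply(fitted$assignments, function(a) {
    any(startsWith(a$assigned_bins, "BOI"))
  }, logical(1)))
  say("peptidoforms assigned to any BOI: ", n_boi)
  counts <- rbind(counts, data.frame(stage = "boi_assigned", n = n_boi))

  composition <- bin_composition(fitted$assignments, robust)

  custom_terms <- NULL
  if (!is.null(config$annotation_path)) {
    custom_terms <- build_custom_terms(read_tsv_base(config$annotation_path))
  }

  # histogram calling for Y-containing peptidoforms assigned to any BOI
  boi_ids <- names(fitted$assignments)[vapply(fitted$assignments, function(a) {
    any(startsWith(a$assigned_bins, "BOI"))
  }, logical(1))]
  call_ids <- intersect(boi_ids, robust$id[robust$contains_Y])
  calls <- NULL
  shortlist <- NULL
  if (length(call_ids)) {
    calls <- do.call(rbind, lapply(call_ids, function(id) {
      row <- robust[robust$id == id, , drop = FALSE]
      hc <- call_histogram(fitted$models[[id]], config$thresholds)
      ctx <- if (is.null(custom_terms)) "No prior knowledge" else
        paste(contextualize(row$accessions, custom_terms), collapse = ";")
      data.frame(id = id, sequence = row$sequence,
                 accessions = row$accessions,
                 label = hc$label, histogram_type = hc$histogram_type,
                 context = ctx, has_deamidation = row$has_deamidation,
                 stringsAsFactors = FALSE)
    }))
    say("Y-containing BOI peptidoforms called: ", nrow(calls),
        " (", sum(calls$label == "Convincing"), " Convincing)")
    shortlist <- shortlist_candidates(calls, config$require_context)
    say("candidate peptidoforms: ", nrow(shortlist$candidates))
    counts <- rbind(counts,
                    data.frame(stage = "convincing",
                               n = sum(calls$label == "Convincing")),
                    data.frame(stage = "candidates",
                               n = nrow(shortlist$candidates)))
  }

  # per-bin enrichment (custom terms and optional GO terms)
  enrichment <- NULL
  background <- unique(unlist(strsplit(robust$accessions, ",")))
  background <- background[nzchar(background)]
  if (length(background)) {
    all_terms <- list()
    if (!is.null(custom_terms)) all_terms <- c(all_terms, custom_terms)
    if (!is.null(config$gmt_path)) {
      all_terms <- c(all_terms, read_gmt(config$gmt_path, category = "GO-BP"))
    }
    if (length(all_terms)) {
      bins <- standard_bins()
      test_bins <- bins$name[bins$group %in% c("BOI", "DECOY")]
      enr_rows <- lapply(test_bins, function(b) {
        ids <- names(fitted$assignments)[vapply(fitted$assignments,
          function(a) b %in% a$assigned_bins, logical(1))]
        fg <- unique(unlist(strsplit(
          robust$accessions[robust$id %in% ids], ",")))
        fg <- intersect(fg[nzchar(fg)], background)
        if (!length(fg)) return(NULL)
        res <- run_ora(fg, background, all_terms, q_cutoff = NA)
        if (nrow(res) == 0L) return(NULL)
        # GO terms respect the q cutoff; the small custom map is never cut
        keep <- res$category == "custom" | res$p_adjusted <= config$ora_q_cutoff
        res <- res[keep, , drop = FALSE]
        if (nrow(res) == 0L) return(NULL)
        cbind(bin = b, res)
      })
      enrichment <- do.call(rbind, enr_rows)
      if (!is.null(enrichment)) rownames(enrichment) <- NULL
    }
  }

  # flank acidity composition: convincing-call sites vs all fitted Y sites
  flank_composition <- NULL
  if (!is.null(config$fasta_path) && !is.null(protein_map)) {
    proteins <- read_fasta(config$fasta_path)
    fg_ids <- if (!is.null(calls)) calls$id[calls$label == "Convincing"]
              else character(0)
    windows <- .collect_y_windows(robust, proteins, protein_map,
                                  fg_ids, config$flank_width)
    if (!is.null(windows) && nrow(windows) &&
        length(unique(windows$origin)) > 0L) {
      flank_composition <- class_composition(windows, w = config$flank_width)
    }
  }

  result <- list(
    counts = counts, peptidoforms = robust,
    models = fitted$models, assignments = fitted$assignments,
    model_report = fitted$report, composition = composition,
    calls = calls, shortlist = shortlist, enrichment = enrichment,
    flank_composition = flank_composition,
    config_hash = .config_hash(config), log = log_lines
  )
  .write_pipeline_outputs(result, config)
  result
}

# Flanking windows around every Y of each peptidoform's peptide, located in
# its protein; foreground = peptidoforms with convincing calls.
.collect_y_windows <- function(robust, proteins, protein_map, fg_ids, w) {
  rows <- list()
  for (i in seq_len(nrow(robust))) {
    if (!robust$contains_Y[i]) next
    seqs <- robust$sequence[i]
    accs <- strsplit(robust$accessions[i], ",")[[1]]
    accs <- accs[nzchar(accs)]
    origin <- if (robust$id[i] %in% fg_ids) "foreground" else "background"
    for (acc in accs) {
      prot <- proteins[[acc]]
      if (is.null(prot) || is.na(prot)) next
      start <- regexpr(seqs, prot, fixed = TRUE)
      if (start < 0) next
      y_in_pep <- which(strsplit(seqs, "")[[1]] == "Y")
      y_in_prot <- y_in_pep + as.integer(start) - 1L
      rows[[length(rows) + 1L]] <-
        extract_flanks(prot, y_in_prot, accession = acc, w = w,
                       origin = origin)
      # foreground sites also belong to the background universe
      if (origin == "foreground") {
        rows[[length(rows) + 1L]] <-
          extract_flanks(prot, y_in_prot, accession = acc, w = w,
                         origin = "background")
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

.write_pipeline_outputs <- function(result, config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_base(result$counts, file.path(out_dir, "stage_counts.tsv"))
  if (nrow(result$peptidoforms)) {
    write_peptidoform_summary(result$peptidoforms,
                              file.path(out_dir, "peptidoforms.tsv"))
  }
  if (!is.null(result$model_report)) {
    write_tsv_base(result$model_report, file.path(out_dir, "models.tsv"))
  }
  if (!is.null(result$composition)) {
    write_tsv_base(result$composition,
                   file.path(out_dir, "bin_composition.tsv"))
  }
  if (!is.null(result$calls)) {
    write_tsv_base(result$calls, file.path(out_dir, "histogram_calls.tsv"))
  }
  if (!is.null(result$shortlist) && !is.null(result$shortlist$by_protein)) {
    write_tsv_base(result$shortlist$by_protein,
                   file.path(out_dir, "candidates_by_protein.tsv"))
    write_tsv_base(result$shortlist$candidates,
                   file.path(out_dir, "candidates.tsv"))
  }
  if (!is.null(result$enrichment)) {
    write_tsv_base(result$enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  if (!is.null(result$flank_composition)) {
    write_tsv_base(result$flank_composition,
                   file.path(out_dir, "flank_composition.tsv"))
  }
  writeLines(c(paste0("# config ", result$config_hash), result$log),
             file.path(out_dir, "run_log.txt"))
  invisible(NULL)
}
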
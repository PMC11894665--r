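#' Configuration for the synthetic phosphoproteome build generator
#'
#' The generator plants peptidoforms of known class and emits the exact file
#' dialects the pipeline ingests. Classes: `p` (true phosphorylation, mass
#' errors centered at 0), `s` (one sulfation misreported as phospho,
#' -0.0095 Da), `ss` (two sulfations, -0.019 Da), `s/p` and `ss/s/p`
#' (mixtures of those centers within one peptidoform), `deam_artifact`
#' (correct phospho wrongly searched with deamidation while the +1
#' isotopomer was selected, +0.0193 Da) and `decoy_shift` (+0.0095 Da,
#' mirror control).
#'
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param n_peptidoforms Number of peptidoforms (one synthetic protein each).
#' @param psm_range Range of FDR-passing PSM counts per peptidoform.
#' @param n_runs,n_experiments MS runs and experiments; runs are dealt to
#'   experiments round-robin.
#' @param run_offset_range Per-run miscalibration offsets, Uniform (Da).
#' @param error_sd Gaussian mass-error spread per component (Da).
#' @param class_proportions Named proportions over the seven classes
#'   (must sum to 1); counts are apportioned deterministically.
#' @param mixture_weights Component weights for the mixed classes.
#' @param pT_ambiguity_rate Probability an `s` peptidoform is reported as
#'   phospho-T rather than phospho-Y (search-engine site ambiguity).
#' @param acidic_flank_bias Probability that a residue within 7 positions of
#'   a true sY site is D/E.
#' @param annotation_enrichment Probability a sulfated-class protein is
#'   tagged known_sY (and, scaled, Secreted/Golgi).
#' @param annotation_background_rate known_sY mis-tag rate for other
#'   proteins.
#' @param q_fail_rate Fraction of emitted PSM rows that fail the q < 0.01
#'   filter (added on top of `psm_range` counts).
#' @param peptide_length Range of tryptic-like peptide lengths.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_peptidoforms = 120L,
                             psm_range = c(90L, 500L),
                             n_runs = 24L,
                             n_experiments = 8L,
                             run_offset_range = c(-0.01, 0.01),
                             error_sd = 0.002,
                             class_proportions = c(
                               p = 0.55, s = 0.12, ss = 0.06,
                               `s/p` = 0.08, `ss/s/p` = 0.04,
                               deam_artifact = 0.08, decoy_shift = 0.07
                             ),
                             mixture_weights = list(
                               `s/p` = c(0.5, 0.5),
                               `ss/s/p` = c(1, 1, 1) / 3
                             ),
                             pT_ambiguity_rate = 0.1,
                             acidic_flank_bias = 0.6,
                             annotation_enrichment = 0.8,
                             annotation_background_rate = 0.02,
                             q_fail_rate = 0.05,
                             peptide_length = c(7L, 30L)) {
  classes <- c("p", "s", "ss", "s/p", "ss/s/p", "deam_artifact", "decoy_shift")
  if (!setequal(names(class_proportions), classes)) {
    stop("class_proportions must be named over: ", paste(classes, collapse = ", "))
  }
  class_proportions <- class_proportions[classes]
  if (abs(sum(class_proportions) - 1) > 1e-9 || any(class_proportions < 0)) {
    stop("class_proportions must be nonnegative and sum to 1")
  }
  stopifnot(error_sd > 0, n_peptidoforms >= 1L,
            psm_range[1] >= 2L, psm_range[2] >= psm_range[1],
            peptide_length[1] >= 7L, peptide_length[2] >= peptide_length[1])
  structure(list(
    seed = as.integer(seed), n_peptidoforms = as.integer(n_peptidoforms),
    psm_range = as.integer(psm_range), n_runs = as.integer(n_runs),
    n_experiments = as.integer(n_experiments),
    run_offset_range = run_offset_range, error_sd = error_sd,
    class_proportions = class_proportions, mixture_weights = mixture_weights,
    pT_ambiguity_rate = pT_ambiguity_rate,
    acidic_flank_bias = acidic_flank_bias,
    annotation_enrichment = annotation_enrichment,
    annotation_background_rate = annotation_background_rate,
    q_fail_rate = q_fail_rate, peptide_length = as.integer(peptide_length)
  ), class = "generator_config")
}

# Deterministic apportionment of n items to proportions (largest remainder).
.apportion <- function(proportions, n) {
  raw <- proportions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0L) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  stats::setNames(as.integer(counts), names(proportions))
}

# True component means (calibration-free) and weights per class.
.class_components <- function(class, config) {
  mc <- mass_constants()
  d <- mc$sulfo_phospho_delta
  switch(class,
    p = list(means = 0, weights = 1),
    s = list(means = -d, weights = 1),
    ss = list(means = -2 * d, weights = 1),
    `s/p` = list(means = c(-d, 0), weights = config$mixture_weights[["s/p"]]),
    `ss/s/p` = list(means = c(-2 * d, -d, 0),
                    weights = config$mixture_weights[["ss/s/p"]]),
    deam_artifact = list(means = mc$c13_c12_delta - mc$deamidation_mass,
                         weights = 1),
    decoy_shift = list(means = d, weights = 1),
    stop("unknown class: ", class)
  )
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")

# Build one tryptic-like peptide meeting the class's residue requirements.
# Returns list(sequence, mods (data.frame), sy_sites (peptide coords)).
.make_peptide <- function(class, config) {
  L <- sample(config$peptide_length[1]:config$peptide_length[2], 1L)
  chars <- sample(.AA20, L, replace = TRUE)
  chars[L] <- sample(c("K", "R"), 1L)
  interior <- seq_len(L - 1L)

  place <- function(res, exclude = integer(0)) {
    pos <- sample(setdiff(interior, exclude), 1L)
    chars[pos] <<- res
    pos
  }
  sy_sites <- integer(0)
  mods <- data.frame(position = integer(), residue = character(),
                     name = character(), stringsAsFactors = FALSE)
  add_mod <- function(pos, name) {
    mods <<- rbind(mods, data.frame(position = pos, residue = chars[pos],
                                    name = name, stringsAsFactors = FALSE))
  }

  if (class %in% c("p", "decoy_shift")) {
    res <- sample(c("S", "T", "Y"), 1L)
    add_mod(place(res), "Phospho")
  } else if (class %in% c("s", "s/p")) {
    ypos <- place("Y")
    sy_sites <- ypos
    ambiguous <- class == "s" &&
      stats::runif(1) < config$pT_ambiguity_rate
    if (ambiguous) {
      add_mod(place("T", exclude = ypos), "Phospho")
    } else {
      add_mod(ypos, "Phospho")
    }
  } else if (class %in% c("ss", "ss/s/p")) {
    y1 <- place("Y")
    y2 <- place("Y", exclude = y1)
    sy_sites <- sort(c(y1, y2))
    add_mod(sy_sites[1], "Phospho")
    add_mod(sy_sites[2], "Phospho")
  } else if (class == "deam_artifact") {
    spos <- place(sample(c("S", "T"), 1L))
    npos <- place("N", exclude = spos)
    add_mod(spos, "Phospho")
    add_mod(npos, "Deamidated")
  }

  # acidity bias around true sY sites, sparing forced/modified positions
  if (length(sy_sites) && config$acidic_flank_bias > 0) {
    protected <- unique(c(sy_sites, mods$position, L))
    for (sp in sy_sites) {
      flank <- setdiff(max(1L, sp - 7L):min(L, sp + 7L), protected)
      biased <- flank[stats::runif(length(flank)) < config$acidic_flank_bias]
      if (length(biased)) {
        chars[biased] <- sample(c("D", "E"), length(biased), replace = TRUE)
      }
    }
  }
  # refresh residues recorded in mods (bias never touches them, but be safe)
  mods$residue <- chars[mods$position]
  list(sequence = paste(chars, collapse = ""), mods = mods,
       sy_sites = sy_sites)
}

#' Generate a synthetic phosphoproteome build with ground truth
#'
#' Emits a PSM table, protein FASTA, protein annotation table, a GO-style
#' GMT term map and a truth table, all consistent with each other and with
#' the dialects the ingest functions read. Raw mass errors are the sum of a
#' per-run miscalibration offset and a draw from the peptidoform class's
#' (mixture of) Gaussians, so running the pipeline end to end must recover
#' the planted classes.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional directory; when given, writes `psms.tsv`,
#'   `proteins.fasta`, `annotation.tsv`, `go_terms.gmt`, `truth.tsv`.
#' @return A list with `psms`, `proteins` (named character), `annotation`,
#'   `go_terms`, `truth`, `protein_map`, `run_offsets`, `config`.
#' @export
generate_build <- function(config = generator_config(), out_dir = NULL) {
  with_seed(config$seed, .generate_build_impl(config, out_dir))
}

.generate_build_impl <- function(config, out_dir) {
  n <- config$n_peptidoforms
  counts <- .apportion(config$class_proportions, n)
  classes <- rep(names(counts), counts)

  run_ids <- sprintf("run%03d", seq_len(config$n_runs))
  run_offsets <- stats::setNames(
    stats::runif(config$n_runs, config$run_offset_range[1],
                 config$run_offset_range[2]),
    run_ids
  )
  experiment_of_run <- stats::setNames(
    sprintf("exp%02d", ((seq_len(config$n_runs) - 1L) %% config$n_experiments) + 1L),
    run_ids
  )

  peptides <- list()
  seen <- character(0)
  for (i in seq_len(n)) {
    repeat {
      pep <- .make_peptide(classes[i], config)
      if (!pep$sequence %in% seen) break
    }
    seen <- c(seen, pep$sequence)
    peptides[[i]] <- pep
  }

  accessions <- sprintf("SYN%04d", seq_len(n))
  sulfated <- classes %in% c("s", "ss", "s/p", "ss/s/p")

  # proteins: random flanks around each peptide, acid-biased near sY sites
  proteins <- character(n)
  sy_protein_sites <- vector("list", n)
  for (i in seq_len(n)) {
    pre_len <- sample(10:30, 1L)
    suf_len <- sample(10:30, 1L)
    pre <- sample(.AA20, pre_len, replace = TRUE)
    suf <- sample(.AA20, suf_len, replace = TRUE)
    pep <- peptides[[i]]
    if (length(pep$sy_sites)) {
      pl <- nchar(pep$sequence)
      for (sp in pep$sy_sites) {
        # prefix positions within 7 of the site
        near_pre <- which(pre_len - seq_len(pre_len) + sp <= 7L)
        near_suf <- which(seq_len(suf_len) + (pl - sp) <= 7L)
        for (j in near_pre) {
          if (stats::runif(1) < config$acidic_flank_bias) {
            pre[j] <- sample(c("D", "E"), 1L)
          }
        }
        for (j in near_suf) {
          if (stats::runif(1) < config$acidic_flank_bias) {
            suf[j] <- sample(c("D", "E"), 1L)
          }
        }
      }
      sy_protein_sites[[i]] <- pep$sy_sites + pre_len
    } else {
      sy_protein_sites[[i]] <- integer(0)
    }
    proteins[i] <- paste0(paste(pre, collapse = ""), pep$sequence,
                          paste(suf, collapse = ""))
  }
  names(proteins) <- accessions

  # annotation table with planted context
  enr <- config$annotation_enrichment
  bg <- config$annotation_background_rate
  known <- ifelse(sulfated, stats::runif(n) < enr, stats::runif(n) < bg)
  secreted <- ifelse(sulfated, stats::runif(n) < 0.6 * enr,
                     stats::runif(n) < 0.08)
  golgi <- ifelse(sulfated, stats::runif(n) < 0.6 * enr,
                  stats::runif(n) < 0.05)
  tm <- stats::runif(n) < 0.15
  annotation <- data.frame(
    accession = accessions,
    protein_name = ifelse(golgi,
                          sprintf("Synthetic Golgi protein %d", seq_len(n)),
                          sprintf("Synthetic protein %d", seq_len(n))),
    subcellular_location = paste0(
      ifelse(secreted, "Secreted. ", ""),
      ifelse(golgi, "Golgi apparatus lumen.", "Cytoplasm.")
    ),
    transmembrane = ifelse(tm, "TRANSMEM 10..32", ""),
    known_sY = known,
    stringsAsFactors = FALSE
  )

  # small GO-style term map (random sets; shape-testing only)
  go_terms <- list()
  sz_range <- seq(min(10L, max(2L, n - 1L)), min(30L, n))
  for (g in 1:5) {
    sz <- sz_range[sample.int(length(sz_range), 1L)]
    go_terms[[sprintf("GO:%07d", g)]] <- list(
      name = sprintf("synthetic GO term %d", g),
      category = "GO-BP",
      members = sort(sample(accessions, sz))
    )
  }

  # PSM rows
  psm_list <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    pep <- peptides[[i]]
    comp <- .class_components(classes[i], config)
    n_pass <- sample(config$psm_range[1]:config$psm_range[2], 1L)
    n_fail <- round(config$q_fail_rate / (1 - config$q_fail_rate) * n_pass)
    n_tot <- n_pass + n_fail
    runs <- sample(run_ids, n_tot, replace = TRUE)
    which_comp <- sample.int(length(comp$means), n_tot, replace = TRUE,
                             prob = comp$weights)
    err <- run_offsets[runs] +
      stats::rnorm(n_tot, comp$means[which_comp], config$error_sd)
    qv <- c(stats::runif(n_pass, 0, 0.0099),
            stats::runif(n_fail, 0.01, 0.2))
    psm_list[[i]] <- data.frame(
      collection_id = "SYNBUILD",
      dataset_id = "SYN-DS1",
      experiment_id = unname(experiment_of_run[runs]),
      run_id = runs,
      scan = NA_integer_,
      sequence = pep$sequence,
      mods = format_mods(pep$mods),
      charge = sample(2:4, n_tot, replace = TRUE, prob = c(0.5, 0.35, 0.15)),
      mass_error_da = unname(err),
      q_value = qv,
      instrument = "SyntheticOrbitrap",
      stringsAsFactors = FALSE
    )
    truth_rows[[i]] <- data.frame(
      peptidoform_id = make_peptidoform_id(pep$sequence, pep$mods),
      accession = accessions[i],
      true_class = classes[i],
      true_means = paste(sprintf("%.6f", comp$means), collapse = ","),
      true_weights = paste(sprintf("%.4f", comp$weights), collapse = ","),
      sy_sites_peptide = paste(pep$sy_sites, collapse = ","),
      sy_sites_protein = paste(sy_protein_sites[[i]], collapse = ","),
      n_psms_planted = n_pass,
      n_psms_failing = n_fail,
      known_sY_planted = known[i],
      stringsAsFactors = FALSE
    )
  }
  psms <- do.call(rbind, psm_list)
  # sequential scan numbers within each run
  psms <- psms[order(psms$run_id), , drop = FALSE]
  psms$scan <- stats::ave(seq_len(nrow(psms)), psms$run_id,
                          FUN = seq_along)
  psms <- psms[sample.int(nrow(psms)), , drop = FALSE]  # shuffle rows
  rownames(psms) <- NULL
  truth <- do.call(rbind, truth_rows)
  protein_map <- data.frame(
    sequence = vapply(peptides, `[[`, "", "sequence"),
    accession = accessions, stringsAsFactors = FALSE
  )

  out <- list(psms = psms, proteins = proteins, annotation = annotation,
              go_terms = go_terms, truth = truth, protein_map = protein_map,
              run_offsets = run_offsets, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_psm_table(psms, file.path(out_dir, "psms.tsv"))
    write_fasta(proteins, file.path(out_dir, "proteins.fasta"))
    write_tsv_base(annotation, file.path(out_dir, "annotation.tsv"))
    write_gmt(go_terms, file.path(out_dir, "go_terms.gmt"))
    write_tsv_base(truth, file.path(out_dir, "truth.tsv"))
    write_tsv_base(protein_map, file.path(out_dir, "protein_map.tsv"))
  }
  out
}

#' Generate a synthetic MS2 spectrum for an interpretation
#'
#' Places peaks at the theoretical b/y m/z values under the stated chemistry:
#' `"neutral_loss"` honours the interpretation's labile flags (sulfate lost
#' from all fragments), `"retained"` keeps every modification mass on the
#' fragments (true phosphorylation). Intensities are log-normal; optional
#' uniform noise peaks are added. `dropout` emulates the incompleteness of
#' real fragment series: each (ion type, index) fragment is absent — at all
#' charge states, since an unproduced fragment is absent everywhere — with
#' that probability. With `dropout = 0` and `n_noise = 0` the peak set equals
#' the theoretical fragment set exactly.
#'
#' @param interpretation A [spectrum_interpretation()].
#' @param hypothesis `"neutral_loss"` or `"retained"`.
#' @param n_noise Number of uniform random noise peaks.
#' @param dropout Per-fragment omission probability (default 0).
#' @param seed Seed for intensities, dropout and noise.
#' @return A spectrum list (`title`, `pepmass`, `charge`, `peaks`) writable
#'   by [write_mgf()].
#' @export
generate_spectrum <- function(interpretation,
                              hypothesis = c("neutral_loss", "retained"),
                              n_noise = 0L, dropout = 0, seed = 1L) {
  hypothesis <- match.arg(hypothesis)
  interp_true <- interpretation
  if (hypothesis == "retained" && nrow(interp_true$mods)) {
    interp_true$mods$labile <- FALSE
  }
  theo <- theoretical_fragments(interp_true)
  mc <- mass_constants()
  with_seed(seed, {
    if (dropout > 0) {
      frag <- unique(theo[, c("type", "index")])
      keep_frag <- frag[stats::runif(nrow(frag)) >= dropout, , drop = FALSE]
      keep <- paste(theo$type, theo$index) %in%
        paste(keep_frag$type, keep_frag$index)
      if (!any(keep)) keep[1] <- TRUE
      theo <- theo[keep, , drop = FALSE]
    }
    intensity <- stats::rlnorm(nrow(theo), meanlog = log(100), sdlog = 0.5)
    peaks <- data.frame(mz = theo$mz, intensity = intensity)
    if (n_noise > 0L) {
      noise <- data.frame(
        mz = stats::runif(n_noise, 100, max(theo$mz) + 100),
        intensity = stats::rlnorm(n_noise, meanlog = log(60), sdlog = 0.5)
      )
      peaks <- rbind(peaks, noise)
    }
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
    z <- interpretation$charge
    list(
      title = paste0(proforma(interpretation), "/", z, " [", hypothesis, "]"),
      pepmass = (precursor_neutral_mass(interpretation) + z * mc$proton_mass) / z,
      charge = z,
      peaks = peaks
    )
  })
}
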
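# Monoisotopic atomic masses (Da), AME2016/CODATA.
.atomic <- c(
  H   = 1.00782503224,
  C   = 12.0,
  C13 = 13.00335483507,
  N   = 14.00307400443,
  O   = 15.99491461957,
  P   = 30.97376199842,
  S   = 31.9720711744
)

# Monoisotopic residue masses for the 20 standard amino acids (Da).
.residues <- c(
  G =  57.02146372057, A =  71.03711378471, S =  87.03202840427,
  P =  97.05276384885, V =  99.06841391299, T = 101.04767846841,
  C = 103.00918478471, L = 113.08406397713, I = 113.08406397713,
  N = 114.04292744114, D = 115.02694302383, Q = 128.05857750528,
  K = 128.09496301399, E = 129.04259308797, M = 131.04048508847,
  H = 137.05891185845, F = 147.06841391299, R = 156.10111102359,
  Y = 163.06332853255, W = 186.07931294986
)

#' Monoisotopic mass constants for sulfation/phosphorylation discrimination
#'
#' All masses are computed from atomic monoisotopic masses rather than typed
#' in, so internal consistency (e.g. `sulfo_phospho_delta ==
#' phospho_mass - sulfo_mass`) holds by construction. Phosphorylation adds
#' HPO3 (+79.966331 Da) and sulfation adds SO3 (+79.956815 Da); the 0.009516
#' Da gap between them is the signal the whole pipeline chases. The
#' carbon-isotope spacing and the deamidation delta together explain the
#' positive-shift artifact class: selecting the +1 isotopomer (+1.003355 Da)
#' of a peptide wrongly searched with deamidation (+0.984016 Da) leaves an
#' apparent shift of about +0.0193 Da.
#'
#' @return A list with elements `phospho_mass`, `sulfo_mass`,
#'   `sulfo_phospho_delta`, `c13_c12_delta`, `deamidation_mass`,
#'   `oxidation_mass`, `carbamidomethyl_mass`, `proton_mass`, `water_mass`
#'   (all Da), and `residue_masses`, a named numeric vector over the 20
#'   standard one-letter amino-acid codes.
#' @examples
#' mc <- mass_constants()
#' mc$phospho_mass - mc$sulfo_mass   # ~0.009516 Da
#' @export
mass_constants <- function() {
  a <- .atomic
  phospho <- a[["H"]] + a[["P"]] + 3 * a[["O"]]
  sulfo <- a[["S"]] + 3 * a[["O"]]
  list(
    phospho_mass = phospho,
    sulfo_mass = sulfo,
    sulfo_phospho_delta = phospho - sulfo,
    c13_c12_delta = a[["C13"]] - a[["C"]],
    deamidation_mass = a[["O"]] - a[["N"]] - a[["H"]],
    oxidation_mass = a[["O"]],
    carbamidomethyl_mass = 2 * a[["C"]] + 3 * a[["H"]] + a[["N"]] + a[["O"]],
    proton_mass = 1.007276466621,
    water_mass = 2 * a[["H"]] + a[["O"]],
    residue_masses = .residues
  )
}

# Mass deltas for the controlled modification vocabulary.
.mod_masses <- function() {
  mc <- mass_constants()
  c(
    Phospho = mc$phospho_mass,
    Sulfo = mc$sulfo_mass,
    Oxidation = mc$oxidation_mass,
    Deamidated = mc$deamidation_mass,
    Carbamidomethyl = mc$carbamidomethyl_mass
  )
}

# Normalize a modification name against the controlled vocabulary
# (case-insensitive); unknown names are carried through unchanged.
.normalize_mod_name <- function(name) {
  vocab <- names(.mod_masses())
  idx <- match(tolower(name), tolower(vocab))
  ifelse(is.na(idx), name, vocab[idx])
}
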
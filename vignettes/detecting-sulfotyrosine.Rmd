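---
title: "Detecting sulfotyrosine misassigned as phosphotyrosine: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sulfotyrosine misassigned as phosphotyrosine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Protein tyrosine sulfation is deposited by the Golgi sulfotransferases
TPST1/2 on acidic substrate stretches and marks secreted and membrane
proteins. Its mass increment, +79.956815 Da (SO3), sits 0.009516 Da below
the phosphorylation increment, +79.966331 Da (HPO3). Database searches of
phospho-enriched data run with precursor tolerances far wider than that gap
and score MS² site localization on fragment ions — but the sulfoester bond
is fully labile under collisional activation, so fragments of a sulfopeptide
look exactly like fragments of the unmodified peptide. The net effect:
sulfopeptides enter phosphoproteome builds as phosphopeptides, and nothing in
the standard pipeline objects.

What *does* survive is the precursor mass itself. If a peptidoform is truly
sulfated but searched as phosphorylated, every one of its PSMs carries a
precursor mass error displaced by −0.0095 Da (or −0.019 Da for two
sulfations). One PSM proves nothing — instrument calibration drifts by more
than that — but the *distribution* of mass errors over dozens to hundreds of
PSMs, pooled across runs and recalibrated, is a sensitive detector. That
distributional reading is what this package implements.

## The procedure and its assumptions

1. **Quality filter.** PSMs with q-value ≥ 0.01 are removed (strict
   inequality). The q-values are consumed, not computed: the TSV contract is
   the package boundary.
2. **Per-run recalibration.** Within each raw file, the median mass error of
   all FDR-passing PSMs is subtracted from every PSM. The median is taken
   before the phospho filter, over the run's full PSM population, because
   the run-level offset is an instrument property, not a property of the
   phosphopeptides. Assumption: within a run the error offset is a constant
   plus symmetric noise, and genuinely shifted species are a minority, so
   the median estimates the offset robustly. A run with a single PSM is
   calibrated to exactly zero and flagged in the log.
3. **Nonstrict peptidoform aggregation.** PSMs are grouped by sequence plus
   the multiset of (modification, residue) pairs; positions are discarded
   (sulfation cannot be localized anyway), residues kept (phospho-S and
   phospho-Y variants of one peptide are different hypotheses). The id
   grammar `SEQ|Name@Residue:count|...` is package-defined.
4. **Robustness filter.** Only peptidoforms seen in ≥3 experiments with ≥90
   PSMs are modelled. Below that, a mixture fit chases noise, and a handful
   of chance mass-shifted PSMs can fake a sulfation signature.
5. **Mixture fitting and selection.** Univariate Gaussian mixtures with
   k = 1, 2, 3 components are fitted by EM; k is chosen by BIC with a ≥10
   point parsimony margin, scanning upward (1 vs 2, then winner vs 3).
   Three components suffice for the scenarios of interest (none/one/two
   sulfations, plus an occasional stray population).
6. **Bin assignment.** Nine half-open 0.005-Da bins tile [−0.0225, 0.0225):
   BOI3/BOI2/BOI1 on the sulfation side, TRUEp1–3 around zero, DECOY1–3
   mirroring the BOIs on the positive side. A peptidoform joins every bin
   holding ≥15% of its fitted probability mass; multiple and empty
   assignments are both legitimate.
7. **Calling, context, enrichment, flanks, MS².** Components are classed
   s/ss/p by proximity to the expected centers; Convincing calls require at
   least one s or ss component. Protein sets per bin are tested for
   over-representation of GO-style terms and of five custom
   sulfation-context terms (known_sY, Secreted, Transmembrane, Golgi,
   unlikely_sY) by one-sided hypergeometric tests with Benjamini–Hochberg
   adjustment within each category. Flanking ±7-residue windows around
   candidate Y sites are profiled for acidic/basic/neutral/polar content.
   Finally, for each candidate spectrum the original `Y[Phospho]`
   interpretation competes with a `Y{Sulfo}` interpretation under full
   neutral loss: fragments are predicted (b/y, charges 1–2, no phospho
   neutral-loss series), peaks matched at 0.05 Th (most intense within
   tolerance, ties by smallest m/z difference), and sulfation is favored
   only when it strictly wins on *both* bond coverage and %TIC annotated.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `q_threshold` | 0.01 | — | strict `<`; standard PSM-level FDR operating point |
| `min_experiments` | 3 | experiments | independence of observations across workflows |
| `min_psms` | 90 | PSMs | enough data for a stable 2–3 component fit |
| `delta_bic` | 10 | BIC points | "very strong evidence" scale for model upgrades |
| `auc_threshold` | 0.15 | fraction | keeps narrow near-boundary fits while rejecting broad smears |
| `center_tolerance` | 0.002 | Da | "centered near" for s/ss components: BOI half-width minus typical fit jitter |
| `p_tolerance` | 0.004 | Da | phospho component window around 0 |
| `undetermined_range` | (−0.006, −0.004) | Da | broad fits drifting toward sulfation without reaching it |
| `match_tolerance` | 0.05 | Th | fragment-peak matching half-window |
| `flank_width` | 7 | residues | sulfation substrate context window |
| `ora_q_cutoff` | 0.1 | adjusted p | reporting cutoff for the GO map; the 5 custom terms are always reported |

All of these live in `pipeline_config()` and serialize to YAML.

## What the synthetic generator emulates — and what it does not

`generate_build()` plants peptidoforms of seven classes: `p` (component at
0 Da), `s` (−δ, δ = 0.009516 Da), `ss` (−2δ), `s/p` and `ss/s/p` (mixtures
of those centers within one peptidoform), `deam_artifact` (+1.003355 −
0.984016 ≈ +0.0193 Da: a correct phosphopeptide whose +1 isotopomer was
selected while the search wrongly added deamidation) and `decoy_shift` (+δ,
a mirror control). Raw errors are a per-run Uniform(−0.01, 0.01) Da offset
plus Gaussian noise with σ = 0.002 Da — about 1 ppm at 2000 Da, a
well-calibrated Orbitrap. PSM counts are uniform on 90–500 per peptidoform
across 24 runs in 8 experiments; a 5% tranche of extra PSMs fails the
q-filter by construction. Default class proportions keep correct
phosphorylation dominant (55%) so the per-run median stays anchored in the
phospho population, as it is in real builds where sulfation is rare. Acidic
residues are planted around true sY sites with probability 0.6 per flank
position, and 80% of sulfated-class proteins are tagged known_sY in the
annotation (2% background mis-tag rate), giving the enrichment stage a
planted effect to find. The default build size, 120 peptidoforms
(~45,000 PSM rows), was chosen as a desk-scale problem on which every class
is represented by several peptidoforms; unit tests use a 24-peptidoform
build, and the MS² comparison uses 200 trials of 14–24-residue peptides.

The generator deliberately does **not** emulate: isotope envelopes and
chimeric spectra; heavy-tailed or asymmetric mass-error noise;
instrument-specific calibration drift within a run; peptides shared across
proteins; correlated modifications; retention time. Passing tests therefore
demonstrate that the *algorithmic chain* recovers planted signals under
clean Gaussian conditions at realistic spread — they do not certify
sensitivity or specificity on real builds, where error distributions have
heavier tails and the robust-peptidoform filters carry more of the burden.
Synthetic MS² spectra place log-normal intensities on theoretical b/y ions
with an optional per-fragment dropout; dropout (default 0 for exact
round-trips; 0.45 in the hypothesis-recovery trials) matters because with a
*complete* fragment series every backbone bond is covered by some
non-site-spanning ion under either hypothesis, so bond coverage alone cannot
discriminate — exactly as in real spectra, incomplete series are what make
the site-spanning ions decisive.

## Numerical choices

* **EM:** means initialized at k evenly spaced sample quantiles; 5 restarts
  with jittered means; convergence when the mean log-likelihood improves by
  < 1e-8; cap 500 iterations (hitting the cap is recorded, not an error);
  variance floor 1e-8 Da² (sd floor 0.1 mDa) against collapse on repeated
  values; all randomness under a caller-supplied seed recorded in the fit.
  For k = 1 the closed-form Gaussian MLE is used directly — tests assert the
  EM path and the closed form agree exactly.
* **BIC:** p = 3k − 1 free parameters (k means, k sds, k−1 weights).
* **Bins:** half-open `[lower, upper)` so the nine bins partition the span;
  the bin AUC denominator is the whole density (total mass 1), not the mass
  inside the span — the distinction only matters for pathologically broad
  fits, which should not be assigned anywhere anyway.
* **Peak matching:** every observed peak is treated as a monoisotopic
  candidate; ties within tolerance break by intensity first, then smallest
  |Δm/z|. The %TIC denominator is the full peak list (a configurable noise
  floor is exposed via prefiltering the peak data frame).
* **Degenerate inputs:** all-identical mass errors give a single floored
  component; empty bins report NA fractions, not zeros; empty foregrounds
  warn and return empty enrichment tables.

## Open design decisions and how they were settled

* The Undetermined criterion's published range of −0.06 to −0.04 Da is
  inconsistent with the ±0.0225 Da bin span and with the accompanying
  "less than −0.006 Da magnitude" description; the package treats it as a
  decimal slip and defaults to (−0.006, −0.004) Da, configurable.
* "Centered near" the s/ss shifts is quantified as ±0.002 Da; component
  width is reported (`wide_sd` flag) but not used as a gate, since no
  width threshold is published.
* Replacement of a non-tyrosine phosphorylation by a tyrosine sulfation
  picks the lowest-index site by default for reproducibility; a
  seeded-random mode reproduces a random-choice protocol.
* Peptides mapping to several proteins keep all accessions; enrichment
  deduplicates at the protein level. Flank windows are deduplicated by
  (accession, position) in both foreground and background — sites, not
  detections, carry the biology — and the central Y is excluded from
  composition counts (configurable).
* BH-adjusted p-values serve as the reported q-values throughout; no
  separate q-value estimator is used.
* Recalibration order is fixed as FDR → recalibrate → phospho-filter, and
  runs are recalibrated per raw file unconditionally, regardless of
  instrument or dataset pooling.

## Limitations

* Nonstrict peptidoforms cannot say *which* tyrosine is sulfated when a
  peptide has several; site-level claims need the MS² stage plus, for
  near-isobaric cases, orthogonal evidence.
* Mixtures are capped at three Gaussian components; exotic multi-artifact
  peptidoforms will fold into the `other` class.
* The enrichment stage performs no GO graph traversal; parent-term
  propagation must be pre-baked into the GMT input.
* The MS² verdict requires strict superiority on both metrics and reports
  `inconclusive` otherwise; this is conservative by design and will
  under-call sulfation on sparse spectra.
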
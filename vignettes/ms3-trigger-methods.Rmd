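---
title: "The xltrigger MS3-trigger algorithm: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The xltrigger MS3-trigger algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cross-linking mass spectrometry with MS-cleavable reagents such as DSSO
identifies pairs of peptides that were covalently linked in the sample. In
the mass spectrometer the linker cleaves preferentially, so an MS2 spectrum
of a cross-linked pair contains each constituent peptide as a *stub doublet*:
two peaks from the same peptide carrying two different cleavage remnants,
separated by a fixed neutral-mass difference divided by the charge. An
MS3-based acquisition isolates those stub peptides and fragments them
separately, which greatly simplifies identification — but only if the
instrument can decide, within an MS2 scan, *which* peaks are doublets worth
fragmenting. That decision is the trigger algorithm implemented here.

## The four-step decision

For each centroided MS2 scan, `decide()` runs:

1. **Deconvolution** (`deconvolute()`): isotope envelopes are detected as
   maximal runs of peaks spaced by 1.00335 Da / z (the averaged
   isotopologue gap) within a ppm tolerance, for charge hypotheses
   z = 1 … precursor charge. Each accepted envelope collapses to its
   lowest-m/z member with summed intensity and an assigned charge.
   Envelopes are ranked by their *maximum member* intensity (the
   "deisotoped max rank" convention), ties toward lower m/z.
2. **Doublet matching** (`match_doublets()`): for every deconvoluted peak
   with charge z and every active stub pair, the theoretical partner lies at
   `m/z + Δm/z`. Peaks of the same charge within the matching tolerance
   (default 5 ppm, relative to the theoretical partner position) form a
   doublet. Peaks may participate in several doublets; no exclusivity is
   imposed at this stage.
3. **Intensity-rank filter** (`apply_rank_filter()`): a doublet survives if
   at least one member ranks within the top `rank_cutoff` (default 20)
   deisotoped peaks, i.e. `min(rank_light, rank_heavy) <= cutoff`, boundary
   inclusive.
4. **Second-peptide-mass filter** (`apply_second_peptide_filter()`): the
   neutral mass the precursor leaves for the partner peptide,
   `precursor_neutral − stub_free_peptide_mass − linker_full_mass`, must be
   at least 500 Da (boundary kept). This vetoes doublets from
   linker-modified *linear* peptides (remaining mass ≈ 0), random matches,
   and partners too small to identify. Computed from the light member; the
   heavy member with its own stub subtracted gives the identical value, and
   the test suite asserts so.

Finally `select_targets()` nominates **both** members of every surviving
doublet as MS3 precursors — the ideal acquisition fragments each peptide once
per stub form — deduplicates by (m/z within 1 ppm, charge), orders by doublet
rank, then summed intensity, then m/z, and truncates to the cap (default 4).

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `ms2_tol_ppm` | 5 | ppm | doublet partner matching window |
| `rank_cutoff` | 20 | rank | intensity-rank filter |
| `cap` | 4 | targets/scan | MS3 budget per MS2 scan |
| `second_peptide_min_mass` | 500 | Da | partner-mass floor |
| `cluster_tol_ppm` | 7 | ppm | isotope-ladder spacing tolerance |

The first four are the standard DSSO operating point. The deconvolution
tolerance is this package's own choice (no canonical value exists): 7 ppm
comfortably exceeds high-resolution Orbitrap calibration error while staying
far below the smallest inter-charge spacing ambiguity. When synthetic data
carry mass jitter, use roughly 3× the jitter half-width: two independently
jittered envelope members can be displaced against each other by twice the
half-width.

### Chemistry

`dsso()` derives everything from elemental compositions against a single
atomic-mass table: alkene stub A = C3H2O (54.0106 Da), sulfenic-acid stub
S = C3H4O2S (103.9932 Da), thiol stub T = C3H2OS (85.9826 Da, = S − H2O).
The A/T doublet spacing is therefore exactly one sulfur atom, 31.9721 Da,
and the intact linker residual mass is A + S = 158.0038 Da, since a single
cleavage conserves the linker. Only the A/T pair is matched by default; A/S
is defined but inactive because sulfenic-acid stubs dehydrate rapidly and
are weak in practice. `load_crosslinker()` accepts arbitrary two-or-more
stub chemistries (e.g. DSBU) from YAML.

## Design choices where the design was open

* **Rank-filter semantics.** Two plausible readings exist: "discard
  doublets ranked worse than 20" applied to the min rank, or "keep doublets
  with at least one member in the top 20". These coincide; the operational
  rule implemented is `min(rank) <= cutoff`. The alternative reading based
  on the *higher* of the two ranks describes post-hoc evaluation of acquired
  data, not the trigger, and is not used for filtering.
* **Boundary conventions.** Both filters keep the exact boundary
  (`rank == cutoff`, `mass == min_mass`). Statements "less than 500 Da is
  rejected" and "more than 500 Da is required" are contradictory exactly at
  the boundary; one convention is fixed and documented.
* **Cap counts targets, not doublets**, and both doublet members are
  targeted. A cap of 4 therefore accommodates the ideal cross-link outcome:
  two stub forms × two peptides.
* **Unknown precursor charge** (encoded 0): steps 1–3 run, step 4 cannot
  (no neutral precursor mass), the scan is decided anyway and flagged
  `precursor_known = FALSE`. This is conservative: an on-instrument
  algorithm cannot always rely on the isolation charge.
* **Deconvolution** is a greedy spacing-ladder walk with a unimodal-envelope
  plausibility check, no averagine fitting, and no missing-monoisotopic
  correction (the envelope's lowest-m/z member *is* the mono peak).
  Competing charge hypotheses resolve highest-charge-first, then longest
  envelope, then lowest m/z, with claimed peaks leaving the pool. Leftover
  peaks persist as charge-ambiguous singletons: they rank and conserve
  intensity but never match doublets. This is deliberately simple — the
  doublet use case needs correct charges and mono positions, not envelope
  shapes — and its failure modes (overlapping envelopes, missing monos) are
  acknowledged limitations.

## The synthetic generator

`generate_spectra()` emulates the data regime the trigger faces, with ground
truth: per-scan class, peptides, link sites, planted doublet identities, and
the expected decision.

* **Cross-linked scans** model the dominant linker cleavage: each intact
  peptide appears as an intense A/T doublet (drawn ~6× above the median
  backbone intensity, as linker cleavage dominates CID), over the b/y series
  of both peptides; backbone fragments spanning the link site carry the
  alkene stub. Exactly two doublets per scan — the ideal of one doublet per
  peptide.
* **Linear-modified scans** plant the same intact-peptide doublet but the
  precursor accounts for one peptide plus the linker, so the remaining mass
  is exactly 0 and step 4 must veto.
* **Envelopes** use geometric intensity decay (default ratio 0.6, depth
  2–4); **noise** is uniform in m/z with log-normal intensity below the
  median fragment intensity; **jitter** is uniform ±`jitter_ppm` on every
  centroid (a bounded error model, so recovered mono errors are provably
  bounded by the jitter); **suppression** removes the heavy partner from a
  chosen fraction of doublets, emulating the observation that a minority of
  genuine cross-link spectra show no complete doublet.
* **Determinism**: one seed governs all draws; class counts follow
  largest-remainder rounding, not sampling.

Two guards keep the ground-truth labels exact. First, ~0.25% of random
tryptic peptides contain a b/y pair whose spacing happens to equal the A/T
delta within 5 ppm (residue swaps such as Cys→Ala or Met→Val differ by
exactly one sulfur); such peptides are rejected and redrawn, because they
would falsify the scan's `expected_trigger = FALSE` label. Second, backbone
fragments whose envelopes would collide with a planted doublet's isotope
ladder (or its ladder-start position) are dropped, and the two doublets are
redrawn if their ladders interleave. Real spectra enjoy no such guarantees
— chance doublet-spaced fragment pairs are precisely why real-data
specificity is imperfect — so the clean-scenario rates of exactly 1.0 and
0.0 demonstrate algorithmic correctness, not expected field performance.
The generator also does not model chromatography, co-isolated chimeric
spectra, deamidation-type near-isobars, or intensity distributions trained
on real data.

## Evaluation

`doublet_presence()` asks, per identified cross-link and per peptide,
whether a doublet surviving steps 1–4 matches a stub-bearing theoretical
fragment of that peptide at 15 ppm. `correctly_triggered()` scores an MS3
scan correct when its recorded precursor matches any stub-bearing fragment
of its parent's identification within 20 ppm. `specificity_rates()` reports
mean selected targets per MS2 scan by class with percentile-bootstrap 0.95
confidence intervals (the interval method is this package's choice; the
bootstrap is seeded and defaults to 10,000 resamples, reduced to ~2,000 in
the test suite where only coverage of a point estimate is needed).
`sweep_tolerance()` exposes the sensitivity/specificity trade-off that
motivates the 5 ppm default: planted-doublet recovery uses the real matcher
(monotone by construction), while spurious matches are counted by brute
force over raw peak pairs, with a tolerance-independent 30 ppm exclusion of
planted positions so the two curves are comparable across tolerances.

Problem sizes used in the shipped tests — 200 scans per class for the
end-to-end rates, 1,000 random spectra for the brute-force matcher
equivalence, 200 spectra × 8 envelopes for deconvolution accuracy, 100
scans for the tolerance sweep — were chosen as the smallest sets where the
checked proportions are stable to well under the asserted margins.

## Known limitations

* No averagine envelope fitting: heavily overlapping envelopes of different
  charges can steal each other's members.
* The monoisotopic peak must be present; high-mass peptides whose mono peak
  vanishes are mis-anchored by one isotope.
* The second-peptide filter needs a known precursor charge.
* The evaluation consumes a pre-filtered identification table and trusts it;
  FDR control belongs to the upstream search engine. The schema carries no
  protein coordinates, so only the peptide-length pre-filter (default 5
  residues) is applied.
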
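#' Trigger configuration
#'
#' Bundles the four tunable parameters of the MS3-trigger decision. The
#' defaults are the standard DSSO operating point: 5 ppm doublet-matching
#' tolerance, intensity-rank cutoff 20, at most 4 MS3 targets per MS2 scan,
#' and at least 500 Da left for the second peptide.
#'
#' @param ms2_tol_ppm doublet matching tolerance in ppm (> 0).
#' @param rank_cutoff keep doublets whose better-ranked member is within the
#'   top `rank_cutoff` deisotoped peaks (>= 1).
#' @param cap maximum number of MS3 targets per MS2 scan (>= 1).
#' @param second_peptide_min_mass minimum neutral mass (Da) that must remain
#'   for the partner peptide (> 0); doublets at exactly this mass are kept.
#' @return a list of class `trigger_config`.
#' @export
trigger_config <- function(ms2_tol_ppm = 5, rank_cutoff = 20L, cap = 4L,
                           second_peptide_min_mass = 500) {
  stopifnot(ms2_tol_ppm > 0, rank_cutoff >= 1, cap >= 1,
            second_peptide_min_mass > 0)
  structure(list(ms2_tol_ppm = ms2_tol_ppm,
                 rank_cutoff = as.integer(rank_cutoff),
                 cap = as.integer(cap),
                 second_peptide_min_mass = second_peptide_min_mass),
            class = "trigger_config")
}

#' Match stub doublets among deconvoluted peaks
#'
#' Step 2: for every deconvoluted peak with a known charge z and every active
#' doublet pair of the cross-linker, the theoretical heavy partner sits at
#' `mono_mz + delta_mass / z`. Every peak of the same charge within
#' `tol_ppm` of that position (ppm relative to the theoretical partner m/z)
#' yields one match; peaks may participate in several matches, and no
#' mutual-exclusion is applied.
#'
#' @param dpeaks ranked deconvoluted-peak tibble (see [deconvolute()]).
#'   Charge-0 (unknown) peaks are ignored.
#' @param xl a `crosslinker`.
#' @param tol_ppm matching tolerance in ppm.
#' @return tibble of matches with columns `scan_id`, `pair` (e.g. "A/T"),
#'   `charge`, `light_idx`, `heavy_idx` (row indices into `dpeaks`),
#'   `light_mz`, `heavy_mz`, `light_rank`, `heavy_rank`, `doublet_rank`
#'   (min of the two), `observed_delta_ppm` (heavy m/z deviation from
#'   theoretical), `light_summed`, `heavy_summed`, `peptide_stub_free_mass`
#'   (neutral mass of the doublet peptide with the light stub removed).
#' @export
match_doublets <- function(dpeaks, xl, tol_ppm = 5) {
  empty <- tibble::tibble(
    scan_id = character(), pair = character(), charge = integer(),
    light_idx = integer(), heavy_idx = integer(),
    light_mz = numeric(), heavy_mz = numeric(),
    light_rank = integer(), heavy_rank = integer(), doublet_rank = integer(),
    observed_delta_ppm = numeric(), light_summed = numeric(),
    heavy_summed = numeric(), peptide_stub_free_mass = numeric()
  )
  if (nrow(dpeaks) == 0L) return(empty)
  if (!"scan_id" %in% names(dpeaks)) dpeaks$scan_id <- ""
  pairs <- active_pairs(xl)
  if (nrow(pairs) == 0L) return(empty)
  out <- vector("list", 0L)
  charged <- which(dpeaks$charge >= 1L)
  for (g in unique(dpeaks$scan_id[charged])) {
    sel <- charged[dpeaks$scan_id[charged] == g]
    mz <- dpeaks$mono_mz[sel]
    z <- dpeaks$charge[sel]
    for (p in seq_len(nrow(pairs))) {
      delta <- pairs$delta_mass[p]
      for (i in seq_along(sel)) {
        theo <- mz[i] + delta / z[i]
        tol <- tol_ppm * 1e-6 * theo
        hit <- which(z == z[i] & abs(mz - theo) <= tol)
        hit <- hit[hit != i]
        if (!length(hit)) next
        li <- sel[i]
        for (j in hit) {
          hj <- sel[j]
          out[[length(out) + 1L]] <- tibble::tibble(
            scan_id = g, pair = paste0(pairs$light[p], "/", pairs$heavy[p]),
            charge = z[i], light_idx = li, heavy_idx = hj,
            light_mz = mz[i], heavy_mz = mz[j],
            light_rank = dpeaks$rank[li], heavy_rank = dpeaks$rank[hj],
            doublet_rank = min(dpeaks$rank[li], dpeaks$rank[hj]),
            observed_delta_ppm = ppm_error(mz[j], theo),
            light_summed = dpeaks$summed_intensity[li],
            heavy_summed = dpeaks$summed_intensity[hj],
            peptide_stub_free_mass = mz_to_neutral(mz[i], z[i]) - pairs$light_mass[p]
          )
        }
      }
    }
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

#' Intensity-rank filter
#'
#' Step 3: keep a doublet when at least one of its two peaks ranks within the
#' top `rank_cutoff` deisotoped peaks of the scan, i.e.
#' `min(light_rank, heavy_rank) <= rank_cutoff` (boundary inclusive).
#'
#' @param matches doublet-match tibble from [match_doublets()].
#' @param rank_cutoff integer cutoff.
#' @return filtered tibble.
#' @export
apply_rank_filter <- function(matches, rank_cutoff = 20L) {
  matches[matches$doublet_rank <= rank_cutoff, , drop = FALSE]
}

#' Mass remaining for the second peptide
#'
#' For each doublet, the neutral mass the precursor leaves for the partner
#' peptide once the doublet peptide and the intact linker are removed:
#' `precursor_neutral - peptide_stub_free_mass - full_mass`. Computed from
#' the light member; the heavy member with its own stub subtracted gives the
#' identical value by construction. `NA` when the precursor charge is
#' unknown.
#'
#' @param matches doublet-match tibble.
#' @param precursor_mz,precursor_charge precursor descriptor (scalars, or
#'   vectors aligned with `matches`); charge 0 means unknown.
#' @param xl the `crosslinker` (supplies `full_mass`).
#' @return numeric vector of remaining neutral masses in Da (NA = undefined).
#' @export
second_peptide_mass <- function(matches, precursor_mz, precursor_charge, xl) {
  prec_neutral <- ifelse(precursor_charge >= 1L,
                         mz_to_neutral(precursor_mz, precursor_charge),
                         NA_real_)
  prec_neutral - matches$peptide_stub_free_mass - xl$full_mass
}

#' Second-peptide-mass filter
#'
#' Step 4: drop doublets that leave less than `min_mass` Da for the partner
#' peptide — these stem from linker-modified linear peptides, random matches,
#' or partners too small to identify. The boundary is kept (`>= min_mass`).
#' Matches whose `second_peptide_mass` is `NA` (unknown precursor charge) are
#' kept and flagged via the `second_peptide_filtered` attribute of the
#' column, i.e. they pass unfiltered.
#'
#' @param matches doublet-match tibble carrying a `second_peptide_mass`
#'   column (add it with [second_peptide_mass()]).
#' @param min_mass minimum remaining mass in Da.
#' @return filtered tibble.
#' @export
apply_second_peptide_filter <- function(matches, min_mass = 500) {
  if (!"second_peptide_mass" %in% names(matches)) {
    stop("matches lack a second_peptide_mass column", call. = FALSE)
  }
  keep <- is.na(matches$second_peptide_mass) |
    matches$second_peptide_mass >= min_mass
  matches[keep, , drop = FALSE]
}

#' Select capped MS3 targets from surviving doublets
#'
#' Both members of every surviving doublet are candidate MS3 precursors (the
#' ideal acquisition fragments each peptide once per stub form). Candidates
#' are deduplicated by (m/z within 1 ppm, charge), ordered by doublet rank
#' ascending, then summed intensity descending, then m/z ascending, and
#' truncated to `cap`.
#'
#' @param matches filtered doublet-match tibble for one scan (must carry
#'   `second_peptide_mass`, possibly all-NA).
#' @param cap maximum target count.
#' @return tibble of targets: `target_mz`, `target_charge`, `doublet_rank`,
#'   `second_peptide_mass`, `member` ("light"/"heavy"), `pair`.
#' @export
select_targets <- function(matches, cap = 4L) {
  empty <- tibble::tibble(
    target_mz = numeric(), target_charge = integer(), doublet_rank = integer(),
    second_peptide_mass = numeric(), member = character(), pair = character()
  )
  if (nrow(matches) == 0L) return(empty)
  spm <- if ("second_peptide_mass" %in% names(matches)) {
    matches$second_peptide_mass
  } else rep(NA_real_, nrow(matches))
  cand <- tibble::tibble(
    target_mz = c(matches$light_mz, matches$heavy_mz),
    target_charge = rep(matches$charge, 2L),
    doublet_rank = rep(matches$doublet_rank, 2L),
    second_peptide_mass = rep(spm, 2L),
    member = rep(c("light", "heavy"), each = nrow(matches)),
    pair = rep(matches$pair, 2L),
    summed = c(matches$light_summed, matches$heavy_summed)
  )
  cand <- cand[order(cand$doublet_rank, -cand$summed, cand$target_mz), ]
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    dup <- FALSE
    for (k in kept) {
      if (cand$target_charge[i] == cand$target_charge[k] &&
          abs(cand$target_mz[i] - cand$target_mz[k]) <=
            1e-6 * cand$target_mz[k]) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- c(kept, i)
    if (length(kept) >= cap) break
  }
  out <- cand[kept, , drop = FALSE]
  out$summed <- NULL
  out
}

#' Decide MS3 triggering for MS2 spectra
#'
#' Runs the full four-step decision per MS2 scan: deconvolution and intensity
#' ranking, charge-aware doublet matching, intensity-rank filter,
#' second-peptide-mass filter, then capped target selection. Deterministic:
#' identical inputs give identical decisions.
#'
#' Scans with unknown precursor charge (0) run steps 1-3, skip the
#' second-peptide filter, and are flagged `precursor_known = FALSE`.
#'
#' @param spectra an `xl_spectra` tibble; only MS2 rows are decided.
#' @param xl a `crosslinker` (default [dsso()]).
#' @param config a [trigger_config()].
#' @param cluster_tol_ppm isotope-spacing tolerance forwarded to
#'   [deconvolute()].
#' @return a tibble of class `ms3_decisions`, one row per MS2 scan:
#'   `scan_id`, `trigger` (any target selected), `n_targets`,
#'   `precursor_known`, `targets` (list-column of target tibbles, see
#'   [select_targets()]). The resolved configuration is attached as the
#'   `config` attribute.
#' @examples
#' sc <- synthetic_scenario(n_scans = 3, seed = 1)
#' sim <- generate_spectra(sc)
#' decide(sim$spectra)
#' @export
decide <- function(spectra, xl = dsso(), config = trigger_config(),
                   cluster_tol_ppm = 7) {
  stopifnot(inherits(config, "trigger_config"))
  ms2 <- spectra[spectra$ms_level == 2L, , drop = FALSE]
  dpeaks <- deconvolute(ms2, cluster_tol_ppm = cluster_tol_ppm)
  matches <- match_doublets(dpeaks, xl, tol_ppm = config$ms2_tol_ppm)
  matches <- apply_rank_filter(matches, config$rank_cutoff)
  rows <- lapply(seq_len(nrow(ms2)), function(i) {
    m <- matches[matches$scan_id == ms2$scan_id[i], , drop = FALSE]
    known <- ms2$precursor_charge[i] >= 1L
    m$second_peptide_mass <- second_peptide_mass(
      m, ms2$precursor_mz[i], ms2$precursor_charge[i], xl)
    if (known) m <- apply_second_peptide_filter(m, config$second_peptide_min_mass)
    tg <- select_targets(m, config$cap)
    tibble::tibble(
      scan_id = ms2$scan_id[i], trigger = nrow(tg) > 0L,
      n_targets = nrow(tg), precursor_known = known, targets = list(tg)
    )
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    scan_id = character(), trigger = logical(), n_targets = integer(),
    precursor_known = logical(), targets = list()
  )
  attr(out, "config") <- unclass(config)
  attr(out, "crosslinker_name") <- xl$name
  class(out) <- c("ms3_decisions", class(out))
  out
}
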
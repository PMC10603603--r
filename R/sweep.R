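#' Sweep the doublet-matching tolerance
#'
#' Generates one seeded synthetic run, deconvolutes it once, and re-matches
#' doublets at each tolerance. Two quantities trade off: recovery of the
#' planted doublets (non-decreasing in tolerance, because the match window
#' only widens) and spurious matches (chance peak pairs at the doublet
#' spacing, counted by brute force over all raw centroided peak pairs at
#' every charge hypothesis, excluding pairs on planted doublet envelope
#' positions with a fixed 30 ppm window so the exclusion does not depend on
#' the swept tolerance).
#'
#' Give the scenario a nonzero `jitter_ppm`, otherwise recovery is 1 at every
#' tolerance above zero and the sweep is uninformative.
#'
#' @param scenario an [synthetic_scenario()].
#' @param tol_ppms tolerances to sweep (default `c(1, 2.5, 5, 10, 20)`).
#' @param xl a `crosslinker`.
#' @param cluster_tol_ppm isotope-spacing tolerance for deconvolution;
#'   default adapts to the scenario jitter (`max(7, 3 * jitter_ppm)`).
#' @return a tibble of class `xl_sweep`: `tol_ppm`, `n_planted`,
#'   `n_recovered`, `recovery`, `spurious`.
#' @export
sweep_tolerance <- function(scenario, tol_ppms = c(1, 2.5, 5, 10, 20),
                            xl = dsso(),
                            cluster_tol_ppm = max(7, 3 * scenario$jitter_ppm)) {
  sim <- generate_spectra(scenario, xl)
  dpeaks <- deconvolute(sim$spectra, cluster_tol_ppm = cluster_tol_ppm)
  planted <- sim$doublets[!sim$doublets$suppressed, , drop = FALSE]
  deltas <- active_pairs(xl)$delta_mass
  out <- lapply(sort(tol_ppms), function(tol) {
    matches <- match_doublets(dpeaks, xl, tol_ppm = tol)
    rec <- recovered_count(matches, planted)
    spur <- spurious_count(sim$spectra, planted, deltas, tol)
    tibble::tibble(tol_ppm = tol, n_planted = nrow(planted),
                   n_recovered = rec,
                   recovery = if (nrow(planted)) rec / nrow(planted) else NA_real_,
                   spurious = spur)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("xl_sweep", class(out))
  out
}

recovered_count <- function(matches, planted) {
  if (!nrow(planted)) return(0L)
  sum(vapply(seq_len(nrow(planted)), function(k) {
    m <- matches[matches$scan_id == planted$scan_id[k] &
                 matches$charge == planted$charge[k], , drop = FALSE]
    any(abs(m$light_mz - planted$light_mz[k]) <= 30e-6 * planted$light_mz[k] &
        abs(m$heavy_mz - planted$heavy_mz[k]) <= 30e-6 * planted$heavy_mz[k])
  }, logical(1)))
}

# brute-force count of doublet-spaced raw peak pairs that are not planted
spurious_count <- function(spectra, planted, deltas, tol_ppm) {
  total <- 0L
  for (i in seq_len(nrow(spectra))) {
    p <- spectra$peaks[[i]]
    if (nrow(p) < 2L) next
    mz <- p$mz
    zmax <- max(1L, spectra$precursor_charge[i])
    d <- planted[planted$scan_id == spectra$scan_id[i], , drop = FALSE]
    for (z in seq_len(zmax)) {
      for (delta in deltas) {
        theo <- mz + delta / z  # theoretical heavy partner of each peak
        hits <- outer(mz, theo, function(obs, th) abs(obs - th) <= tol_ppm * 1e-6 * th)
        if (!any(hits)) next
        idx <- which(hits, arr.ind = TRUE)  # (heavy obs, light origin)
        keep <- rep(TRUE, nrow(idx))
        if (nrow(d)) {
          for (k in seq_len(nrow(d))) {
            if (d$charge[k] != z) next
            onl <- abs(mz[idx[, 2]] - d$light_mz[k]) <= 30e-6 * d$light_mz[k]
            onh <- abs(mz[idx[, 1]] - d$heavy_mz[k]) <= 30e-6 * d$heavy_mz[k]
            keep <- keep & !(onl & onh)
          }
        }
        total <- total + sum(keep)
      }
    }
  }
  total
}
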
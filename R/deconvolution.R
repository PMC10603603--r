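#' Detect isotope clusters in one peak table
#'
#' Greedy spacing-ladder detection: for each charge hypothesis z in
#' `1:max_charge`, a candidate envelope is a maximal run of peaks spaced by
#' the averaged isotope gap (1.00335 Da / z) within `cluster_tol_ppm` of the
#' position predicted from the previous member, whose intensities rise then
#' fall at most once (a coarse unimodal-envelope plausibility check; the walk
#' stops when a member would rise again after a fall). No envelope-shape
#' fitting is attempted.
#'
#' @param peaks tibble with columns `mz`, `intensity`, sorted ascending.
#' @param max_charge highest charge hypothesis to consider.
#' @param cluster_tol_ppm spacing tolerance in ppm (default 7).
#' @param min_envelope_size minimum member count for a multi-peak envelope
#'   (default 2); shorter runs surface later as charge-ambiguous singletons.
#' @return list of candidates, each a list with `charge` and `idx` (indices
#'   into `peaks`).
#' @export
detect_isotope_clusters <- function(peaks, max_charge, cluster_tol_ppm = 7,
                                    min_envelope_size = 2L) {
  n <- nrow(peaks)
  if (n == 0L || max_charge < 1L) return(list())
  mz <- peaks$mz
  inten <- peaks$intensity
  gap <- xl_constants$isotope_gap
  candidates <- list()
  for (z in seq_len(max_charge)) {
    step <- gap / z
    # a start peak is one with no matching predecessor at -step
    for (i in seq_len(n)) {
      prev_pos <- mz[i] - step
      tol_prev <- cluster_tol_ppm * 1e-6 * prev_pos
      if (any(abs(mz - prev_pos) <= tol_prev)) next
      idx <- i
      repeat {
        last <- idx[length(idx)]
        expected <- mz[last] + step
        tol <- cluster_tol_ppm * 1e-6 * expected
        cand <- which(abs(mz - expected) <= tol)
        if (!length(cand)) break
        nxt <- cand[which.min(abs(mz[cand] - expected))]
        # unimodality: once intensities have fallen, a rise ends the envelope
        if (length(idx) >= 2L) {
          fell <- any(diff(inten[idx]) < 0)
          if (fell && inten[nxt] > inten[last]) break
        }
        idx <- c(idx, nxt)
      }
      if (length(idx) >= min_envelope_size) {
        candidates[[length(candidates) + 1L]] <- list(charge = z, idx = idx)
      }
    }
  }
  candidates
}

# resolve competing charge hypotheses for one peak table; returns a tibble of
# deconvoluted peaks (envelopes + leftover singletons, charge 0)
deconvolute_peaks <- function(peaks, max_charge, cluster_tol_ppm = 7,
                              min_envelope_size = 2L) {
  n <- nrow(peaks)
  empty <- tibble::tibble(
    mono_mz = numeric(), charge = integer(), summed_intensity = numeric(),
    max_member_intensity = numeric(), n_members = integer(), members = list()
  )
  if (n == 0L) return(empty)
  cands <- detect_isotope_clusters(peaks, max_charge, cluster_tol_ppm,
                                   min_envelope_size)
  accepted <- list()
  if (length(cands)) {
    charge <- vapply(cands, `[[`, integer(1), "charge")
    len <- vapply(cands, function(c) length(c$idx), integer(1))
    mono <- vapply(cands, function(c) peaks$mz[c$idx[1]], numeric(1))
    # highest charge first, then longest envelope, then lowest mono m/z
    ord <- order(-charge, -len, mono)
    used <- rep(FALSE, n)
    for (k in ord) {
      idx <- cands[[k]]$idx
      if (any(used[idx])) next
      used[idx] <- TRUE
      accepted[[length(accepted) + 1L]] <- cands[[k]]
    }
  } else {
    used <- rep(FALSE, n)
  }
  env_tbl <- if (length(accepted)) {
    tibble::tibble(
      mono_mz = vapply(accepted, function(c) peaks$mz[c$idx[1]], numeric(1)),
      charge = vapply(accepted, `[[`, integer(1), "charge"),
      summed_intensity = vapply(accepted, function(c) sum(peaks$intensity[c$idx]), numeric(1)),
      max_member_intensity = vapply(accepted, function(c) max(peaks$intensity[c$idx]), numeric(1)),
      n_members = vapply(accepted, function(c) length(c$idx), integer(1)),
      members = lapply(accepted, `[[`, "idx")
    )
  } else empty
  left <- which(!used)
  single_tbl <- if (length(left)) {
    tibble::tibble(
      mono_mz = peaks$mz[left], charge = 0L,
      summed_intensity = peaks$intensity[left],
      max_member_intensity = peaks$intensity[left],
      n_members = 1L, members = as.list(left)
    )
  } else empty
  out <- dplyr::bind_rows(env_tbl, single_tbl)
  out[order(out$mono_mz), ]
}

#' Deconvolute MS2 spectra to monoisotopic peaks
#'
#' Step 1 of the trigger algorithm: isotope envelopes are detected per scan
#' (see [detect_isotope_clusters()]), competing charge hypotheses are resolved
#' greedily (highest charge, then longest envelope, then lowest m/z; members
#' of an accepted envelope leave the pool), and each accepted envelope is
#' collapsed to its lowest-m/z member with the member intensities summed.
#' Unassigned peaks are retained as singletons with charge 0 (unknown); they
#' are excluded from doublet matching but participate in intensity ranking
#' and conserve total intensity.
#'
#' @param spectra an `xl_spectra` tibble (MS2 rows are processed; other
#'   levels are ignored).
#' @param cluster_tol_ppm isotope-spacing tolerance in ppm (default 7).
#' @param max_charge highest fragment charge hypothesis; default `NULL` uses
#'   the scan's precursor charge when known (fragments cannot out-charge
#'   their precursor), else 4.
#' @param min_envelope_size minimum envelope member count (default 2).
#' @return tibble with one row per deconvoluted peak: `scan_id`, `mono_mz`,
#'   `charge`, `summed_intensity`, `max_member_intensity`, `n_members`,
#'   `members` (list of source-peak indices), `rank` (see
#'   [assign_intensity_ranks()], already populated).
#' @export
deconvolute <- function(spectra, cluster_tol_ppm = 7, max_charge = NULL,
                        min_envelope_size = 2L) {
  ms2 <- spectra[spectra$ms_level == 2L, , drop = FALSE]
  per_scan <- lapply(seq_len(nrow(ms2)), function(i) {
    zmax <- if (!is.null(max_charge)) max_charge
            else if (ms2$precursor_charge[i] >= 1L) ms2$precursor_charge[i]
            else 4L
    d <- deconvolute_peaks(ms2$peaks[[i]], zmax, cluster_tol_ppm, min_envelope_size)
    if (nrow(d)) d$scan_id <- ms2$scan_id[i]
    d
  })
  out <- dplyr::bind_rows(per_scan)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      scan_id = character(), mono_mz = numeric(), charge = integer(),
      summed_intensity = numeric(), max_member_intensity = numeric(),
      n_members = integer(), members = list()
    )
  }
  out <- dplyr::relocate(out, "scan_id")
  assign_intensity_ranks(out)
}

#' Rank deconvoluted peaks by intensity
#'
#' Rank 1 is the most intense peak of the scan, judged by the maximum member
#' intensity of the isotope cluster (the "deisotoped max rank" convention);
#' ties break toward lower monoisotopic m/z. Ranks are contiguous from 1
#' within each scan.
#'
#' @param dpeaks deconvoluted-peak tibble (from [deconvolute()]); a `scan_id`
#'   column groups ranking, otherwise the whole table is one scan.
#' @return the same tibble with an integer `rank` column (re)populated.
#' @export
assign_intensity_ranks <- function(dpeaks) {
  if (nrow(dpeaks) == 0L) {
    dpeaks$rank <- integer()
    return(dpeaks)
  }
  grp <- if ("scan_id" %in% names(dpeaks)) dpeaks$scan_id else rep("", nrow(dpeaks))
  rank <- integer(nrow(dpeaks))
  for (g in unique(grp)) {
    sel <- which(grp == g)
    ord <- order(-dpeaks$max_member_intensity[sel], dpeaks$mono_mz[sel])
    rank[sel[ord]] <- seq_along(sel)
  }
  dpeaks$rank <- rank
  dpeaks
}
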
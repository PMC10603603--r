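#' Describe a synthetic acquisition scenario
#'
#' A scenario fixes everything about a simulated MS2 run: how many scans, the
#' mix of spectrum classes (cross-linked pairs, unmodified linear peptides,
#' cross-linker-modified linear peptides), peptide properties, isotope
#' envelope shape, noise, heavy-partner suppression, mass-error jitter, and
#' the seed. The seed fully determines the output of [generate_spectra()].
#'
#' Class counts are assigned deterministically (largest-remainder rounding of
#' the mix), not sampled, so small runs realize the mix exactly.
#'
#' @param n_scans number of MS2 scans.
#' @param class_mix named proportions over
#'   `c("crosslinked", "linear", "linear_modified")`; must sum to 1.
#' @param peptide_length integer range (min, max) of residues; C-terminal
#'   residue is K or R (tryptic).
#' @param min_peptide_mass peptides are resampled until their neutral mass
#'   reaches this many Da (default 500, the second-peptide filter floor).
#' @param precursor_charge_range integer range for cross-linked precursors;
#'   linear precursors use charge 2-3.
#' @param isotope_depth integer range of isotopologue peaks per planted
#'   fragment (envelope members).
#' @param isotope_ratio geometric decay ratio of successive envelope member
#'   intensities (default 0.6).
#' @param n_noise_peaks uniform-m/z noise peaks per scan (default 0).
#' @param suppress_fraction fraction of planted doublets whose heavy partner
#'   is removed, emulating incomplete linker cleavage (default 0).
#' @param jitter_ppm uniform mass-error half-width in ppm applied to every
#'   final centroid position (default 0).
#' @param mz_range m/z window for noise peaks.
#' @param seed integer RNG seed.
#' @return a list of class `xl_scenario`.
#' @export
synthetic_scenario <- function(n_scans = 100L,
                               class_mix = c(crosslinked = 0.5, linear = 0.3,
                                             linear_modified = 0.2),
                               peptide_length = c(6L, 18L),
                               min_peptide_mass = 500,
                               precursor_charge_range = c(3L, 4L),
                               isotope_depth = c(2L, 4L),
                               isotope_ratio = 0.6,
                               n_noise_peaks = 0L,
                               suppress_fraction = 0,
                               jitter_ppm = 0,
                               mz_range = c(150, 2000),
                               seed = 1L) {
  stopifnot(n_scans >= 1, abs(sum(class_mix) - 1) < 1e-8,
            all(names(class_mix) %in% c("crosslinked", "linear", "linear_modified")),
            peptide_length[1] >= 2, peptide_length[2] >= peptide_length[1],
            isotope_depth[1] >= 1, isotope_ratio > 0, isotope_ratio < 1,
            n_noise_peaks >= 0, suppress_fraction >= 0, suppress_fraction <= 1,
            jitter_ppm >= 0)
  structure(list(
    n_scans = as.integer(n_scans), class_mix = class_mix,
    peptide_length = as.integer(peptide_length),
    min_peptide_mass = min_peptide_mass,
    precursor_charge_range = as.integer(precursor_charge_range),
    isotope_depth = as.integer(isotope_depth), isotope_ratio = isotope_ratio,
    n_noise_peaks = as.integer(n_noise_peaks),
    suppress_fraction = suppress_fraction, jitter_ppm = jitter_ppm,
    mz_range = mz_range, seed = as.integer(seed)
  ), class = "xl_scenario")
}

# deterministic largest-remainder class assignment
class_counts <- function(mix, n) {
  classes <- c("crosslinked", "linear", "linear_modified")
  p <- stats::setNames(rep(0, 3), classes)
  p[names(mix)] <- mix
  base <- floor(p * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- p * n - base
    add <- order(-frac)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  base
}

random_tryptic_peptide <- function(len_range, min_mass) {
  aas <- names(.residue_masses)
  repeat {
    len <- sample(seq(len_range[1], len_range[2]), 1L)
    pep <- paste0(paste(sample(aas, len - 1L, replace = TRUE), collapse = ""),
                  sample(c("K", "R"), 1L))
    if (peptide_neutral_mass(pep) >= min_mass) return(pep)
  }
}

# TRUE when the planted fragment list contains an unintended pair whose
# spacing mimics an active doublet delta (equal planted charge, within
# guard_ppm); `allowed` is a 2-column matrix of intended light/heavy m/z
has_unintended_doublet <- function(mz, z, deltas, allowed = NULL,
                                   guard_ppm = 10) {
  for (zz in unique(z)) {
    m <- sort(mz[z == zz])
    for (delta in deltas) {
      theo <- m + delta / zz
      for (i in seq_along(m)) {
        hit <- abs(m - theo[i]) <= guard_ppm * 1e-6 * theo[i]
        if (!any(hit)) next
        if (is.null(allowed)) return(TRUE)
        intended <- any(abs(allowed[, 1] - m[i]) <= 30e-6 * m[i] &
                        abs(allowed[, 2] - m[hit][1]) <= 30e-6 * m[hit][1])
        if (!intended || sum(hit) > 1L) return(TRUE)
      }
    }
  }
  FALSE
}

#' Generate synthetic MS2 spectra with ground truth
#'
#' Emulates centroided CID MS2 spectra of a DSSO-style experiment. For
#' cross-linked scans the dominant linker cleavage is modelled: each intact
#' peptide appears as an intense A/T stub doublet (heavy partner optionally
#' suppressed), on top of the b/y backbone series of both peptides
#' (site-spanning backbone fragments carry the alkene stub). Linear-modified
#' scans plant the same intact-peptide doublet, but the precursor accounts
#' for a single peptide plus the linker, so the second-peptide filter should
#' veto them. Every planted fragment is expanded into an isotope envelope
#' with geometric intensity decay; uniform-m/z noise and uniform ppm jitter
#' are optional.
#'
#' So that the `expected_trigger` label in the ground truth is exact, the
#' generator rejects peptides whose unintended fragment pairs happen to be
#' doublet-spaced (chance sulfur-mass spacings occur in ~0.25% of random
#' peptides) and drops backbone fragments that would collide with a planted
#' doublet envelope. Real spectra carry no such guarantee; this is what makes
#' the clean-scenario trigger rates exactly 0 or 1.
#'
#' @param scenario an [synthetic_scenario()].
#' @param xl a `crosslinker` (default [dsso()]); its first active doublet
#'   pair is planted.
#' @return a list with elements:
#'   \describe{
#'     \item{spectra}{`xl_spectra` tibble of MS2 scans}
#'     \item{truth}{tibble: `scan_id`, `class`, `peptide1`, `peptide2`,
#'       `link_pos1`, `link_pos2`, `precursor_mz`, `precursor_charge`,
#'       `expected_trigger`}
#'     \item{doublets}{tibble of planted doublets: `scan_id`, `peptide`,
#'       `charge`, `light_mz`, `heavy_mz`, `suppressed`}
#'   }
#' @export
generate_spectra <- function(scenario, xl = dsso()) {
  stopifnot(inherits(scenario, "xl_scenario"))
  pairs <- active_pairs(xl)
  if (nrow(pairs) == 0L) stop("crosslinker has no active doublet pair", call. = FALSE)
  pair <- pairs[1L, ]
  withr::with_seed(scenario$seed, generate_spectra_impl(scenario, xl, pair))
}

generate_spectra_impl <- function(sc, xl, pair) {
  counts <- class_counts(sc$class_mix, sc$n_scans)
  classes <- rep(names(counts), counts)
  gap <- xl_constants$isotope_gap
  scan_rows <- vector("list", sc$n_scans)
  truth_rows <- vector("list", sc$n_scans)
  doublet_rows <- list()

  for (i in seq_len(sc$n_scans)) {
    cls <- classes[i]
    sid <- sprintf("synth_%04d", i)
    built <- NULL
    for (try in 1:50) {
      built <- build_scan(cls, sc, xl, pair)
      if (!is.null(built)) break
    }
    if (is.null(built)) stop("could not build a conflict-free scan", call. = FALSE)

    # expand planted fragments into isotope envelopes
    frag <- built$frag
    depth <- sample(seq(sc$isotope_depth[1], sc$isotope_depth[2]),
                    nrow(frag), replace = TRUE)
    mz <- unlist(lapply(seq_len(nrow(frag)), function(k) {
      frag$mz[k] + (seq_len(depth[k]) - 1L) * gap / frag$z[k]
    }))
    inten <- unlist(lapply(seq_len(nrow(frag)), function(k) {
      frag$intensity[k] * sc$isotope_ratio^(seq_len(depth[k]) - 1L)
    }))
    if (sc$n_noise_peaks > 0L) {
      nmz <- stats::runif(sc$n_noise_peaks, sc$mz_range[1], sc$mz_range[2])
      nint <- stats::rlnorm(sc$n_noise_peaks, meanlog = log(20), sdlog = 0.8)
      mz <- c(mz, nmz); inten <- c(inten, nint)
    }
    if (sc$jitter_ppm > 0) {
      mz <- mz * (1 + stats::runif(length(mz), -sc$jitter_ppm, sc$jitter_ppm) * 1e-6)
    }
    ord <- order(mz)
    scan_rows[[i]] <- list(
      scan_id = sid,
      precursor_mz = built$prec_mz, precursor_charge = built$prec_z,
      peaks = tibble::tibble(mz = mz[ord], intensity = inten[ord])
    )
    truth_rows[[i]] <- tibble::tibble(
      scan_id = sid, class = cls,
      peptide1 = built$pep1, peptide2 = built$pep2 %||% NA_character_,
      link_pos1 = built$pos1 %||% NA_integer_,
      link_pos2 = built$pos2 %||% NA_integer_,
      precursor_mz = built$prec_mz, precursor_charge = built$prec_z,
      expected_trigger = built$expected_trigger
    )
    if (nrow(built$doublets)) {
      d <- built$doublets
      d$scan_id <- sid
      doublet_rows[[length(doublet_rows) + 1L]] <- d
    }
  }

  spectra <- spectra_tbl(
    scan_id = vapply(scan_rows, `[[`, character(1), "scan_id"),
    ms_level = 2L,
    precursor_mz = vapply(scan_rows, `[[`, numeric(1), "precursor_mz"),
    precursor_charge = vapply(scan_rows, `[[`, integer(1), "precursor_charge"),
    peaks = lapply(scan_rows, `[[`, "peaks")
  )
  doublets <- if (length(doublet_rows)) {
    dplyr::relocate(dplyr::bind_rows(doublet_rows), "scan_id")
  } else {
    tibble::tibble(scan_id = character(), peptide = integer(),
                   charge = integer(), light_mz = numeric(),
                   heavy_mz = numeric(), suppressed = logical())
  }
  list(spectra = spectra, truth = dplyr::bind_rows(truth_rows),
       doublets = doublets)
}

# assemble the planted fragment list for one scan; returns NULL when the
# random peptides produce unintended doublet-spaced pairs or envelope
# collisions and a fresh draw is needed
build_scan <- function(cls, sc, xl, pair) {
  gap <- xl_constants$isotope_gap
  delta <- pair$delta_mass
  backbone <- function(pep, pos) {
    fr <- fragment_mzs(pep, c("b", "y"), max_charge = 1L,
                       stub_site = pos,
                       stubs = if (!is.null(pos))
                         xl$stubs[xl$stubs$label == pair$light, ])
    tibble::tibble(mz = fr$mz, z = fr$charge,
                   intensity = stats::rlnorm(nrow(fr), log(100), 0.5))
  }
  dom_intensity <- function(n) stats::rlnorm(n, log(600), 0.3)

  if (cls == "crosslinked") {
    pep1 <- random_tryptic_peptide(sc$peptide_length, sc$min_peptide_mass)
    pep2 <- random_tryptic_peptide(sc$peptide_length, sc$min_peptide_mass)
    pos1 <- sample(nchar(pep1) - 1L, 1L)
    pos2 <- sample(nchar(pep2) - 1L, 1L)
    prec_z <- sample(seq(sc$precursor_charge_range[1], sc$precursor_charge_range[2]), 1L)
    m1 <- peptide_neutral_mass(pep1); m2 <- peptide_neutral_mass(pep2)
    prec_mz <- neutral_to_mz(m1 + m2 + xl$full_mass, prec_z)
    zd <- sample(seq_len(max(1L, min(2L, prec_z - 1L))), 2L, replace = TRUE)
    light_mz <- c(neutral_to_mz(m1 + pair$light_mass, zd[1]),
                  neutral_to_mz(m2 + pair$light_mass, zd[2]))
    heavy_mz <- light_mz + delta / zd
    suppressed <- stats::runif(2) < sc$suppress_fraction
    dom <- tibble::tibble(
      mz = c(light_mz, heavy_mz[!suppressed]),
      z = c(zd, zd[!suppressed]),
      intensity = dom_intensity(2L + sum(!suppressed))
    )
    # the two doublets' isotope ladders must not interleave, or deconvolution
    # of one would corrupt the other's monoisotopic position
    if (doublets_conflict(light_mz, heavy_mz, zd, gap, sc$isotope_depth[2])) {
      return(NULL)
    }
    bb <- dplyr::bind_rows(backbone(pep1, pos1), backbone(pep2, pos2))
    bb <- drop_guarded(bb, light_mz, heavy_mz, zd, delta, gap,
                       sc$isotope_depth[2])
    frag <- dplyr::bind_rows(dom, bb)
    allowed <- cbind(light_mz, heavy_mz)
    if (has_unintended_doublet(frag$mz, frag$z, delta, allowed)) return(NULL)
    list(frag = frag, prec_mz = prec_mz, prec_z = prec_z,
         pep1 = pep1, pep2 = pep2, pos1 = pos1, pos2 = pos2,
         # one surviving doublet suffices; only full suppression kills it
         expected_trigger = !all(suppressed),
         doublets = tibble::tibble(
           peptide = 1:2, charge = zd, light_mz = light_mz,
           heavy_mz = heavy_mz, suppressed = suppressed))
  } else if (cls == "linear") {
    pep <- random_tryptic_peptide(sc$peptide_length, sc$min_peptide_mass)
    prec_z <- sample(2:3, 1L)
    prec_mz <- neutral_to_mz(peptide_neutral_mass(pep), prec_z)
    frag <- backbone(pep, NULL)
    if (has_unintended_doublet(frag$mz, frag$z, delta)) return(NULL)
    list(frag = frag, prec_mz = prec_mz, prec_z = prec_z,
         pep1 = pep, pep2 = NULL, pos1 = NULL, pos2 = NULL,
         expected_trigger = FALSE,
         doublets = tibble::tibble(peptide = integer(), charge = integer(),
                                   light_mz = numeric(), heavy_mz = numeric(),
                                   suppressed = logical()))
  } else {  # linear_modified: one peptide carrying the intact linker
    pep <- random_tryptic_peptide(sc$peptide_length, sc$min_peptide_mass)
    pos <- sample(nchar(pep) - 1L, 1L)
    prec_z <- sample(2:3, 1L)
    m <- peptide_neutral_mass(pep)
    prec_mz <- neutral_to_mz(m + xl$full_mass, prec_z)
    zd <- sample(seq_len(max(1L, min(2L, prec_z - 1L))), 1L)
    light_mz <- neutral_to_mz(m + pair$light_mass, zd)
    heavy_mz <- light_mz + delta / zd
    suppressed <- stats::runif(1) < sc$suppress_fraction
    dom <- tibble::tibble(
      mz = c(light_mz, if (!suppressed) heavy_mz),
      z = rep(zd, 2L - suppressed),
      intensity = dom_intensity(2L - suppressed)
    )
    bb <- backbone(pep, pos)
    bb <- drop_guarded(bb, light_mz, heavy_mz, zd, delta, gap,
                       sc$isotope_depth[2])
    frag <- dplyr::bind_rows(dom, bb)
    if (has_unintended_doublet(frag$mz, frag$z, delta,
                               cbind(light_mz, heavy_mz))) return(NULL)
    list(frag = frag, prec_mz = prec_mz, prec_z = prec_z,
         pep1 = pep, pep2 = NULL, pos1 = pos, pos2 = NULL,
         expected_trigger = FALSE,
         doublets = tibble::tibble(peptide = 1L, charge = zd,
                                   light_mz = light_mz, heavy_mz = heavy_mz,
                                   suppressed = suppressed))
  }
}

# TRUE when the isotope envelopes (or ladder-start guard positions) of the
# two planted doublets approach each other within 30 ppm
doublets_conflict <- function(light_mz, heavy_mz, zd, gap, max_depth) {
  positions <- lapply(seq_along(light_mz), function(k) {
    c(light_mz[k] + (-1:max_depth) * gap / zd[k],
      heavy_mz[k] + (-1:max_depth) * gap / zd[k])
  })
  for (a in seq_along(positions)) {
    for (b in seq_along(positions)) {
      if (a == b) next
      for (m in positions[[a]]) {
        if (any(abs(positions[[b]] - m) <= 30e-6 * m)) return(TRUE)
      }
    }
  }
  FALSE
}

# remove backbone fragments whose monoisotopic position would collide with a
# planted doublet envelope member, its ladder-start guard (one gap below the
# mono peak), or a position that would pair with a doublet peak at the
# doublet delta (30 ppm window); in a real spectrum such peaks would merge
# with or distort the doublet envelope
drop_guarded <- function(bb, light_mz, heavy_mz, zd, delta, gap, max_depth) {
  guard <- unlist(lapply(seq_along(light_mz), function(k) {
    members <- c(light_mz[k] + (0:max_depth) * gap / zd[k],
                 heavy_mz[k] + (0:max_depth) * gap / zd[k])
    c(members,
      light_mz[k] - gap / zd[k], heavy_mz[k] - gap / zd[k],
      light_mz[k] - delta / zd[k], heavy_mz[k] + delta / zd[k])
  }))
  keep <- vapply(seq_len(nrow(bb)), function(i) {
    # test the whole backbone envelope (members at 1.00335/z steps), not just
    # the monoisotopic peak: any member on a guard position can steal the
    # doublet's ladder start
    members <- bb$mz[i] + (0:max_depth) * gap / bb$z[i]
    all(vapply(members, function(m) all(abs(guard - m) > 30e-6 * m), logical(1)))
  }, logical(1))
  bb[keep, , drop = FALSE]
}
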
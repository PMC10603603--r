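# Independent oracles and fixture builders. The atomic masses here are typed
# from the NIST/CODATA tables independently of the package's constants so the
# chemistry tests compare two provenances.

nist_masses <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

nist_composition_mass <- function(formula) {
  # formula given as a named count vector, e.g. c(C = 3, H = 2, O = 1)
  sum(nist_masses[names(formula)] * formula)
}

PROTON <- 1.007276466

# build a deconvoluted-peak table directly (bypassing deconvolution) for
# matcher tests
make_dpeaks <- function(mz, charge, intensity = NULL, scan_id = "s1") {
  n <- length(mz)
  if (is.null(intensity)) intensity <- rep(100, n)
  d <- tibble::tibble(
    scan_id = rep(scan_id, length.out = n),
    mono_mz = mz, charge = as.integer(charge),
    summed_intensity = intensity, max_member_intensity = intensity,
    n_members = 2L, members = as.list(seq_len(n))
  )
  xltrigger::assign_intensity_ranks(d)
}

# all-pairs brute-force doublet matcher, written independently of
# match_doublets: straight double loop over ordered peak pairs
brute_force_doublets <- function(dpeaks, xl, tol_ppm) {
  pairs <- xl$doublet_pairs[xl$doublet_pairs$active, , drop = FALSE]
  out <- list()
  for (p in seq_len(nrow(pairs))) {
    delta <- pairs$delta_mass[p]
    lbl <- paste0(pairs$light[p], "/", pairs$heavy[p])
    for (i in seq_len(nrow(dpeaks))) {
      for (j in seq_len(nrow(dpeaks))) {
        if (i == j) next
        if (dpeaks$scan_id[i] != dpeaks$scan_id[j]) next
        zi <- dpeaks$charge[i]
        if (zi < 1L || dpeaks$charge[j] != zi) next
        theo <- dpeaks$mono_mz[i] + delta / zi
        if (abs(dpeaks$mono_mz[j] - theo) <= tol_ppm * 1e-6 * theo) {
          out[[length(out) + 1L]] <- c(lbl, i, j)
        }
      }
    }
  }
  if (!length(out)) return(character())
  sort(vapply(out, paste, character(1), collapse = ":"))
}

match_key <- function(matches) {
  if (!nrow(matches)) return(character())
  sort(paste(matches$pair, matches$light_idx, matches$heavy_idx, sep = ":"))
}

# minimal single-scan spectra table
one_scan <- function(mz, intensity, prec_mz = 600, prec_z = 2L, id = "s1") {
  xltrigger::spectra_tbl(id, 2L, prec_mz, prec_z,
                         list(tibble::tibble(mz = mz, intensity = intensity)))
}

# clean cross-linked simulation reused by several tests
clean_sim <- function(n = 10, seed = 11, mix = c(crosslinked = 1)) {
  sc <- xltrigger::synthetic_scenario(n_scans = n, class_mix = mix, seed = seed)
  xltrigger::generate_spectra(sc)
}

# CSM table derived from a generator truth table
truth_to_csms <- function(truth) {
  tibble::tibble(
    scan_id = truth$scan_id,
    peptide1 = truth$peptide1,
    peptide2 = truth$peptide2,
    link_pos1 = truth$link_pos1,
    link_pos2 = truth$link_pos2,
    precursor_charge = truth$precursor_charge,
    class = truth$class
  )
}
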
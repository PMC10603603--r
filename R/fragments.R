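#' Monoisotopic neutral mass of a peptide
#'
#' Sum of residue monoisotopic masses plus water, plus any modification mass
#' deltas. Modifications are plain deltas; no inference is done.
#'
#' @param sequence character vector of peptide sequences (20 canonical
#'   one-letter codes).
#' @param modifications for a single sequence, a numeric vector of mass
#'   deltas in Da (positions are irrelevant for the intact mass); ignored
#'   entries may be named by position.
#' @return numeric vector of neutral masses in Da.
#' @examples
#' peptide_neutral_mass("G")        # glycine residue + water
#' peptide_neutral_mass("ACDEFGK")
#' @export
peptide_neutral_mass <- function(sequence, modifications = NULL) {
  masses <- vapply(sequence, function(s) {
    if (!nzchar(s)) stop("empty peptide sequence", call. = FALSE)
    res <- strsplit(s, "")[[1]]
    m <- .residue_masses[res]
    if (anyNA(m)) {
      stop("unknown residue(s): ",
           paste(unique(res[is.na(m)]), collapse = ", "), call. = FALSE)
    }
    sum(m) + .water_mass
  }, numeric(1), USE.NAMES = FALSE)
  if (!is.null(modifications)) masses <- masses + sum(modifications)
  masses
}

#' Theoretical b/y fragment m/z values
#'
#' Standard singly-to-`max_charge` protonated b and y ions. When a
#' cross-link stub is present (`stub_site` plus `stubs`), fragments that span
#' the linked residue carry the stub mass; one fragment row is emitted per
#' stub variant. b ions are the N-terminal residue sums; y ions add water.
#' m/z = (neutral + z * proton) / z.
#'
#' @param sequence peptide sequence.
#' @param series subset of `c("b", "y")`.
#' @param max_charge highest fragment charge (>= 1).
#' @param stub_site 1-based residue index carrying the cross-linker stub, or
#'   `NULL` for an unmodified peptide.
#' @param stubs tibble with columns `label`, `mass` (e.g. `dsso()$stubs`);
#'   required when `stub_site` is given.
#' @param modifications optional numeric vector of fixed modification deltas,
#'   named or indexed by residue position, added to fragments containing
#'   those residues.
#' @return tibble: `ion` (e.g. "b3", "y5+A"), `series`, `index`, `stub`
#'   (label or NA), `charge`, `neutral_mass`, `mz`.
#' @export
fragment_mzs <- function(sequence, series = c("b", "y"), max_charge = 1L,
                         stub_site = NULL, stubs = NULL,
                         modifications = NULL) {
  stopifnot(max_charge >= 1L)
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n == 0L) stop("empty peptide sequence", call. = FALSE)
  if (!is.null(stub_site)) {
    if (stub_site < 1L || stub_site > n) {
      stop("stub position outside sequence", call. = FALSE)
    }
    if (is.null(stubs)) stop("stub_site given without stubs", call. = FALSE)
  }
  m <- unname(.residue_masses[res])
  if (anyNA(m)) stop("unknown residue in ", sequence, call. = FALSE)
  mod <- numeric(n)
  if (!is.null(modifications)) {
    pos <- if (!is.null(names(modifications))) as.integer(names(modifications))
           else seq_along(modifications)
    mod[pos] <- mod[pos] + as.numeric(modifications)
  }
  m <- m + mod
  cum <- cumsum(m)
  rows <- list()
  add <- function(ser, index, neutral, stub_lbl) {
    for (z in seq_len(max_charge)) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        ion = paste0(ser, index, if (!is.na(stub_lbl)) paste0("+", stub_lbl) else ""),
        series = ser, index = as.integer(index), stub = stub_lbl,
        charge = z, neutral_mass = neutral, mz = neutral_to_mz(neutral, z)
      )
    }
  }
  emit <- function(ser, index, base_neutral, covers_site) {
    if (is.null(stub_site) || !covers_site) {
      add(ser, index, base_neutral, NA_character_)
    } else {
      for (s in seq_len(nrow(stubs))) {
        add(ser, index, base_neutral + stubs$mass[s], stubs$label[s])
      }
    }
  }
  if ("b" %in% series) {
    for (i in seq_len(n - 1L)) {
      emit("b", i, cum[i], !is.null(stub_site) && stub_site <= i)
    }
  }
  if ("y" %in% series) {
    for (j in seq_len(n - 1L)) {
      neutral <- cum[n] - cum[n - j] + .water_mass
      emit("y", j, neutral, !is.null(stub_site) && stub_site > n - j)
    }
  }
  dplyr::bind_rows(rows)
}

#' Annotate a spectrum with b/y and stub fragments
#'
#' Generates the theoretical b/y series of one peptide or a cross-linked
#' peptide pair (cross-link-site-spanning fragments and the intact peptides
#' carry each stub variant of the cross-linker) and matches them to the
#' observed peaks at `tol_ppm`. A peak may carry several annotations.
#'
#' @param peaks tibble with `mz`, `intensity` (one scan, sorted).
#' @param peptide1 sequence of the first peptide.
#' @param link_pos1 cross-link site on peptide 1 (NULL for a linear peptide).
#' @param peptide2 optional partner peptide sequence.
#' @param link_pos2 cross-link site on peptide 2.
#' @param xl a `crosslinker`; its full stub set (e.g. A, S, T for DSSO) is
#'   used for site-spanning fragments.
#' @param tol_ppm annotation tolerance in ppm (default 15).
#' @param max_frag_charge highest fragment charge generated (default 2).
#' @param mods1,mods2 optional positional modification deltas per peptide.
#' @return tibble: `peak_index`, `mz`, `intensity`, `peptide` (1 or 2),
#'   `ion`, `series`, `index`, `stub`, `charge`, `theo_mz`, `error_ppm`.
#' @export
annotate_spectrum <- function(peaks, peptide1, link_pos1 = NULL,
                              peptide2 = NULL, link_pos2 = NULL,
                              xl = dsso(), tol_ppm = 15, max_frag_charge = 2L,
                              mods1 = NULL, mods2 = NULL) {
  theo <- theoretical_fragments(peptide1, link_pos1, peptide2, link_pos2, xl,
                                max_frag_charge, mods1, mods2)
  match_annotations(peaks, theo, tol_ppm)
}

# full theoretical fragment table for a CSM: b/y of each peptide plus the
# intact stub-carrying peptide forms ("p+A" etc.) that linker cleavage yields
theoretical_fragments <- function(peptide1, link_pos1 = NULL, peptide2 = NULL,
                                  link_pos2 = NULL, xl = dsso(),
                                  max_frag_charge = 2L,
                                  mods1 = NULL, mods2 = NULL) {
  one <- function(seq, pos, mods, which_pep) {
    if (!is.null(pos) && is.na(pos)) pos <- NULL  # linear peptide rows
    fr <- fragment_mzs(seq, c("b", "y"), max_frag_charge,
                       stub_site = pos, stubs = if (!is.null(pos)) xl$stubs,
                       modifications = mods)
    fr$peptide <- which_pep
    if (!is.null(pos)) {
      # intact peptide carrying each stub (product of linker cleavage)
      pmass <- peptide_neutral_mass(seq, mods)
      intact <- lapply(seq_len(nrow(xl$stubs)), function(s) {
        neutral <- pmass + xl$stubs$mass[s]
        tibble::tibble(
          ion = paste0("p+", xl$stubs$label[s]), series = "p",
          index = NA_integer_, stub = xl$stubs$label[s],
          charge = seq_len(max_frag_charge), neutral_mass = neutral,
          mz = neutral_to_mz(neutral, seq_len(max_frag_charge)),
          peptide = which_pep
        )
      })
      fr <- dplyr::bind_rows(fr, dplyr::bind_rows(intact))
    }
    fr
  }
  theo <- one(peptide1, link_pos1, mods1, 1L)
  if (!is.null(peptide2) && !is.na(peptide2) && nzchar(peptide2)) {
    theo <- dplyr::bind_rows(theo, one(peptide2, link_pos2, mods2, 2L))
  }
  theo
}

match_annotations <- function(peaks, theo, tol_ppm) {
  empty <- tibble::tibble(
    peak_index = integer(), mz = numeric(), intensity = numeric(),
    peptide = integer(), ion = character(), series = character(),
    index = integer(), stub = character(), charge = integer(),
    theo_mz = numeric(), error_ppm = numeric()
  )
  if (nrow(peaks) == 0L || nrow(theo) == 0L) return(empty)
  out <- list()
  for (t in seq_len(nrow(theo))) {
    tol <- tol_ppm * 1e-6 * theo$mz[t]
    hit <- which(abs(peaks$mz - theo$mz[t]) <= tol)
    if (!length(hit)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      peak_index = hit, mz = peaks$mz[hit], intensity = peaks$intensity[hit],
      peptide = theo$peptide[t], ion = theo$ion[t], series = theo$series[t],
      index = theo$index[t], stub = theo$stub[t], charge = theo$charge[t],
      theo_mz = theo$mz[t], error_ppm = ppm_error(peaks$mz[hit], theo$mz[t])
    )
  }
  if (!length(out)) return(empty)
  dplyr::arrange(dplyr::bind_rows(out), .data$peak_index, .data$theo_mz)
}
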
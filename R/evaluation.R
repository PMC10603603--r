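#' Read or validate a CSM/PSM table
#'
#' The evaluation functions consume a pre-filtered identification table (one
#' row per spectrum match) with columns `scan_id`, `peptide1`, `peptide2`
#' (empty/NA for linear matches), `link_pos1`, `link_pos2`,
#' `precursor_charge`, `class` (one of `crosslinked`, `linear`,
#' `linear_modified`). FDR control belongs to the upstream search engine and
#' is trusted here.
#'
#' @param path TSV file path.
#' @return tibble with the schema above.
#' @export
read_csm_table <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  req <- c("scan_id", "peptide1", "class")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("CSM table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tab$scan_id <- as.character(tab$scan_id)
  tab
}

#' Pre-filter a CSM table on peptide length
#'
#' Drops matches with any peptide shorter than `min_peptide_length` residues
#' (default 5, the conventional identifiability floor).
#'
#' @param csms CSM tibble.
#' @param min_peptide_length minimum residues per peptide.
#' @return filtered tibble.
#' @export
filter_csms <- function(csms, min_peptide_length = 5L) {
  len1 <- nchar(csms$peptide1)
  len2 <- ifelse(is.na(csms$peptide2) | !nzchar(csms$peptide2),
                 Inf, nchar(csms$peptide2))
  csms[len1 >= min_peptide_length & len2 >= min_peptide_length, , drop = FALSE]
}

#' Doublet presence per CSM
#'
#' For each cross-linked CSM, runs the doublet engine through the
#' second-peptide filter (no cap) and asks, per peptide, whether a surviving
#' doublet's light member matches a theoretical light-stub fragment of that
#' peptide (intact stub peptide or site-spanning b/y ion) within
#' `annotation_tol_ppm` at the doublet's charge.
#'
#' @param csms CSM tibble (rows with class `"crosslinked"` are evaluated).
#' @param spectra `xl_spectra` holding every CSM's scan; missing scans are
#'   skipped with a warning.
#' @param xl a `crosslinker`.
#' @param config a [trigger_config()].
#' @param annotation_tol_ppm fragment annotation tolerance (default 15).
#' @param cluster_tol_ppm forwarded to [deconvolute()].
#' @return tibble: `scan_id`, `peptide1_found`, `peptide2_found`,
#'   `presence` (`"none"`, `"one"`, `"both"`).
#' @export
doublet_presence <- function(csms, spectra, xl = dsso(),
                             config = trigger_config(),
                             annotation_tol_ppm = 15, cluster_tol_ppm = 7) {
  csms <- csms[csms$class == "crosslinked", , drop = FALSE]
  have <- csms$scan_id %in% spectra$scan_id
  if (any(!have)) {
    warning("skipping ", sum(!have), " CSM(s) without a spectrum", call. = FALSE)
    csms <- csms[have, , drop = FALSE]
  }
  pairs <- active_pairs(xl)
  rows <- lapply(seq_len(nrow(csms)), function(i) {
    sp <- spectra[spectra$scan_id == csms$scan_id[i], , drop = FALSE]
    m <- surviving_matches(sp, xl, config, cluster_tol_ppm)
    found <- vapply(1:2, function(pp) {
      pep <- if (pp == 1L) csms$peptide1[i] else csms$peptide2[i]
      pos <- if (pp == 1L) csms$link_pos1[i] else csms$link_pos2[i]
      if (is.na(pep) || !nzchar(pep)) return(FALSE)
      theo <- theoretical_fragments(pep, as.integer(pos), xl = xl,
                                    max_frag_charge = max(1L, sp$precursor_charge))
      any(vapply(seq_len(nrow(m)), function(k) {
        lbl <- sub("/.*$", "", m$pair[k])
        cand <- theo[!is.na(theo$stub) & theo$stub == lbl &
                     theo$charge == m$charge[k], , drop = FALSE]
        any(abs(cand$mz - m$light_mz[k]) <= annotation_tol_ppm * 1e-6 * cand$mz)
      }, logical(1)))
    }, logical(1))
    tibble::tibble(scan_id = csms$scan_id[i],
                   peptide1_found = found[1], peptide2_found = found[2],
                   presence = c("none", "one", "both")[1L + sum(found)])
  })
  if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(scan_id = character(), peptide1_found = logical(),
                   peptide2_found = logical(), presence = character())
  }
}

# steps 1-4 for one scan, returning the surviving match table (pre-cap)
surviving_matches <- function(sp, xl, config, cluster_tol_ppm = 7) {
  dpeaks <- deconvolute(sp, cluster_tol_ppm = cluster_tol_ppm)
  m <- match_doublets(dpeaks, xl, tol_ppm = config$ms2_tol_ppm)
  m <- apply_rank_filter(m, config$rank_cutoff)
  m$second_peptide_mass <- second_peptide_mass(
    m, sp$precursor_mz, sp$precursor_charge, xl)
  if (sp$precursor_charge >= 1L) {
    m <- apply_second_peptide_filter(m, config$second_peptide_min_mass)
  }
  m
}

#' Fraction of correctly triggered MS3 scans
#'
#' An MS3 scan is "correctly triggered" when its recorded precursor m/z
#' matches a stub-bearing theoretical fragment of the identified CSM of its
#' parent MS2 scan within `tol_ppm` (default 20). MS3 scans whose parent has
#' no CSM are excluded from the proportion and counted separately.
#'
#' @param ms3_map tibble with columns `ms3_scan_id`, `parent_ms2_scan_id`,
#'   `ms3_precursor_mz` (scan-lineage table).
#' @param csms CSM tibble (see [read_csm_table()]).
#' @param xl a `crosslinker`.
#' @param tol_ppm match tolerance in ppm.
#' @param max_frag_charge highest fragment charge considered.
#' @return list: `proportion` (correct / evaluable), `n` (evaluable MS3
#'   scans), `n_orphans` (MS3 scans without an identified parent),
#'   `per_scan` (tibble `ms3_scan_id`, `parent_ms2_scan_id`, `correct`).
#' @export
correctly_triggered <- function(ms3_map, csms, xl = dsso(), tol_ppm = 20,
                                max_frag_charge = 2L) {
  idx <- match(ms3_map$parent_ms2_scan_id, csms$scan_id)
  orphan <- is.na(idx)
  eval_rows <- which(!orphan)
  correct <- logical(length(eval_rows))
  stub_cache <- new.env(parent = emptyenv())
  for (r in seq_along(eval_rows)) {
    i <- eval_rows[r]
    ci <- idx[i]
    key <- csms$scan_id[ci]
    if (!exists(key, envir = stub_cache, inherits = FALSE)) {
      pep2 <- csms$peptide2[ci]
      if (is.na(pep2) || !nzchar(pep2)) pep2 <- NULL
      theo <- theoretical_fragments(
        csms$peptide1[ci], as.integer(csms$link_pos1[ci]),
        pep2, if (!is.null(pep2)) as.integer(csms$link_pos2[ci]),
        xl = xl, max_frag_charge = max_frag_charge)
      assign(key, theo$mz[!is.na(theo$stub)], envir = stub_cache)
    }
    smz <- get(key, envir = stub_cache, inherits = FALSE)
    obs <- ms3_map$ms3_precursor_mz[i]
    correct[r] <- any(abs(obs - smz) <= tol_ppm * 1e-6 * smz)
  }
  list(
    proportion = if (length(eval_rows)) mean(correct) else NA_real_,
    n = length(eval_rows),
    n_orphans = sum(orphan),
    per_scan = tibble::tibble(
      ms3_scan_id = ms3_map$ms3_scan_id[eval_rows],
      parent_ms2_scan_id = ms3_map$parent_ms2_scan_id[eval_rows],
      correct = correct)
  )
}

# percentile bootstrap CI of a mean; deterministic under the given seed
boot_ci <- function(x, n_boot = 10000L, conf = 0.95, seed = 1L) {
  if (!length(x)) return(c(NA_real_, NA_real_))
  if (length(unique(x)) == 1L) return(c(x[1], x[1]))
  means <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) mean(sample(x, replace = TRUE)),
           numeric(1))
  })
  unname(stats::quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
}

#' MS3-per-MS2 specificity rates by spectrum class
#'
#' Mean number of selected MS3 targets per MS2 scan, per identification
#' class, with percentile-bootstrap confidence intervals. The ideal
#' acquisition triggers per cross-link on each of the two peptides and never
#' on linear or linker-modified linear peptides.
#'
#' @param decisions an `ms3_decisions` tibble from [decide()].
#' @param classes tibble with `scan_id`, `class`; scans absent from it are
#'   reported as class `"unidentified"`.
#' @param n_boot bootstrap resamples (default 10000).
#' @param conf confidence level (default 0.95).
#' @param seed seed for the bootstrap.
#' @return tibble: `class`, `n_scans`, `rate`, `ci_lo`, `ci_hi`.
#' @export
specificity_rates <- function(decisions, classes, n_boot = 10000L,
                              conf = 0.95, seed = 1L) {
  cls <- classes$class[match(decisions$scan_id, classes$scan_id)]
  cls[is.na(cls)] <- "unidentified"
  out <- lapply(unique(cls), function(g) {
    x <- decisions$n_targets[cls == g]
    ci <- boot_ci(x, n_boot, conf, seed)
    tibble::tibble(class = g, n_scans = length(x), rate = mean(x),
                   ci_lo = ci[1], ci_hi = ci[2])
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$class)
}

#' Evaluate trigger sensitivity and specificity end to end
#'
#' Combines [doublet_presence()], [decide()]/[specificity_rates()] and
#' optionally [correctly_triggered()] into one report.
#'
#' @param spectra `xl_spectra` with the MS2 scans.
#' @param csms CSM tibble (pre-filtered; see [filter_csms()]).
#' @param xl a `crosslinker`.
#' @param config a [trigger_config()].
#' @param ms3_map optional MS3 scan-lineage tibble (see
#'   [correctly_triggered()]).
#' @param n_boot,conf,seed bootstrap settings for the confidence intervals.
#' @param min_peptide_length forwarded to [filter_csms()] (default 5).
#' @return a list of class `xl_evaluation`: `n_csms`, `frac_one_doublet`
#'   (at least one peptide's doublet found), `frac_both_doublets`,
#'   `frac_correctly_triggered` (NA without `ms3_map`), `rates`
#'   (specificity tibble), `confidence_intervals` (per-metric lo/hi),
#'   `presence` and `decisions` (the underlying tables).
#' @export
evaluate_triggering <- function(spectra, csms, xl = dsso(),
                                config = trigger_config(), ms3_map = NULL,
                                n_boot = 10000L, conf = 0.95, seed = 1L,
                                min_peptide_length = 5L) {
  csms <- filter_csms(csms, min_peptide_length)
  pres <- doublet_presence(csms, spectra, xl, config)
  decisions <- decide(spectra, xl, config)
  rates <- specificity_rates(decisions, csms[, c("scan_id", "class")],
                             n_boot, conf, seed)
  frac_one <- if (nrow(pres)) mean(pres$presence %in% c("one", "both")) else NA_real_
  frac_both <- if (nrow(pres)) mean(pres$presence == "both") else NA_real_
  ct <- if (!is.null(ms3_map)) correctly_triggered(ms3_map, csms, xl) else NULL
  cis <- list(
    frac_one_doublet = boot_ci(as.numeric(pres$presence %in% c("one", "both")),
                               n_boot, conf, seed),
    frac_both_doublets = boot_ci(as.numeric(pres$presence == "both"),
                                 n_boot, conf, seed)
  )
  if (!is.null(ct)) {
    cis$frac_correctly_triggered <-
      boot_ci(as.numeric(ct$per_scan$correct), n_boot, conf, seed)
  }
  structure(list(
    n_csms = nrow(pres),
    frac_one_doublet = frac_one,
    frac_both_doublets = frac_both,
    frac_correctly_triggered = if (!is.null(ct)) ct$proportion else NA_real_,
    rates = rates,
    confidence_intervals = cis,
    presence = pres,
    decisions = decisions
  ), class = "xl_evaluation")
}

#' @export
print.xl_evaluation <- function(x, ...) {
  cat("<xl_evaluation>\n")
  cat("  CSMs evaluated:          ", x$n_csms, "\n")
  cat("  >=1 peptide doublet:     ", format(x$frac_one_doublet, digits = 4), "\n")
  cat("  both peptide doublets:   ", format(x$frac_both_doublets, digits = 4), "\n")
  cat("  correctly triggered MS3: ",
      format(x$frac_correctly_triggered, digits = 4), "\n")
  cat("  MS3-per-MS2 by class:\n")
  print(x$rates)
  invisible(x)
}
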
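#' Build a spectra table
#'
#' The package represents a run of centroided scans as a tibble with one row
#' per scan and a `peaks` list-column; each element of `peaks` is itself a
#' tibble with columns `mz` (Th) and `intensity`. Peak tables are sorted
#' ascending by m/z on construction (stably, so ties keep input order).
#' Precursor charge `0` means "unknown"; such MS2 scans are still processed by
#' [decide()] but skip the second-peptide-mass filter.
#'
#' @param scan_id character vector of scan identifiers (unique).
#' @param ms_level integer vector, 2 or 3.
#' @param precursor_mz numeric vector, precursor m/z in Th (NA allowed for
#'   MS3-less bookkeeping rows, but MS2 rows should carry one).
#' @param precursor_charge integer vector; 0 encodes unknown charge.
#' @param peaks list of data frames with columns `mz`, `intensity`.
#' @return a tibble of class `xl_spectra`.
#' @examples
#' sp <- spectra_tbl("s1", 2L, 500.25, 2L,
#'                   list(data.frame(mz = c(501, 500), intensity = c(1, 2))))
#' sp$peaks[[1]]  # sorted ascending by mz
#' @export
spectra_tbl <- function(scan_id, ms_level, precursor_mz, precursor_charge, peaks) {
  stopifnot(length(scan_id) == length(peaks))
  ms_level <- as.integer(ms_level)
  if (!all(ms_level %in% c(2L, 3L))) {
    stop("ms_level must be 2 or 3", call. = FALSE)
  }
  precursor_charge <- as.integer(precursor_charge)
  if (any(precursor_charge < 0L, na.rm = TRUE)) {
    stop("precursor_charge must be >= 0 (0 = unknown)", call. = FALSE)
  }
  peaks <- lapply(peaks, function(p) {
    p <- tibble::as_tibble(p[, c("mz", "intensity")])
    if (any(p$mz <= 0)) stop("peak m/z must be positive", call. = FALSE)
    if (any(p$intensity < 0)) stop("peak intensity must be non-negative", call. = FALSE)
    if (is.unsorted(p$mz)) p <- p[order(p$mz), ]  # order() is stable
    p
  })
  out <- tibble::tibble(
    scan_id = as.character(scan_id),
    ms_level = ms_level,
    precursor_mz = as.numeric(precursor_mz),
    precursor_charge = precursor_charge,
    peaks = peaks
  )
  class(out) <- c("xl_spectra", class(out))
  out
}

#' Precursor neutral mass of each scan
#'
#' `(precursor_mz - proton) * charge`; NA where the charge is unknown (0).
#'
#' @param spectra an `xl_spectra` tibble.
#' @return numeric vector of neutral masses in Da.
#' @export
precursor_neutral_mass <- function(spectra) {
  ifelse(spectra$precursor_charge >= 1L,
         mz_to_neutral(spectra$precursor_mz, spectra$precursor_charge),
         NA_real_)
}

#' Read centroided spectra from MGF or mzML
#'
#' MGF is parsed directly (BEGIN IONS / END IONS blocks with PEPMASS, CHARGE,
#' TITLE, SCANS); mzML is read through the `mzR` package. MS2 scans without a
#' precursor m/z are skipped with a warning; a missing precursor charge is
#' recorded as 0 (unknown).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"mgf"` or `"mzml"`.
#' @return an `xl_spectra` tibble in file order.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mgf = "mgf", mzml = "mzml",
                     stop("cannot infer format from extension: ", ext, call. = FALSE))
  }
  switch(format, mgf = read_mgf(path), mzml = read_mzml(path))
}

read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS", call. = FALSE)
  }
  if (length(begins) == 0L) {
    return(spectra_tbl(character(), integer(), numeric(), integer(), list()))
  }
  recs <- Map(function(b, e) lines[(b + 1L):(e - 1L)], begins, ends)
  parsed <- lapply(seq_along(recs), function(i) {
    body <- recs[[i]]
    is_kv <- grepl("=", body, fixed = TRUE)
    kv <- body[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    getv <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    pepmass <- getv("PEPMASS")
    prec_mz <- if (is.na(pepmass)) NA_real_ else as.numeric(strsplit(trimws(pepmass), "[ \t]+")[[1]][1])
    chg <- getv("CHARGE")
    prec_z <- if (is.na(chg)) 0L else {
      z <- suppressWarnings(as.integer(sub("\\+$", "", trimws(chg))))
      if (is.na(z)) 0L else z
    }
    title <- getv("TITLE")
    scans <- getv("SCANS")
    id <- if (!is.na(title)) title else if (!is.na(scans)) scans else paste0("index=", i)
    lvl <- getv("MSLEVEL")
    lvl <- if (is.na(lvl)) 2L else as.integer(lvl)
    pk_lines <- body[!is_kv & nzchar(trimws(body))]
    if (length(pk_lines)) {
      mat <- do.call(rbind, lapply(strsplit(trimws(pk_lines), "[ \t]+"), function(x) as.numeric(x[1:2])))
      pk <- tibble::tibble(mz = mat[, 1], intensity = mat[, 2])
    } else {
      pk <- tibble::tibble(mz = numeric(), intensity = numeric())
    }
    list(id = id, lvl = lvl, mz = prec_mz, z = prec_z, peaks = pk)
  })
  keep <- vapply(parsed, function(p) {
    ok <- !(p$lvl == 2L && is.na(p$mz))
    if (!ok) warning("skipping MS2 record without precursor: ", p$id, call. = FALSE)
    ok
  }, logical(1))
  parsed <- parsed[keep]
  spectra_tbl(
    scan_id = vapply(parsed, `[[`, character(1), "id"),
    ms_level = vapply(parsed, `[[`, integer(1), "lvl"),
    precursor_mz = vapply(parsed, `[[`, numeric(1), "mz"),
    precursor_charge = vapply(parsed, `[[`, integer(1), "z"),
    peaks = lapply(parsed, `[[`, "peaks")
  )
}

read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package", call. = FALSE)
  }
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  keep <- !(hdr$msLevel == 2L & (is.na(hdr$precursorMZ) | hdr$precursorMZ <= 0))
  if (any(!keep)) warning("skipping ", sum(!keep), " MS2 scan(s) without precursor", call. = FALSE)
  ids <- hdr$spectrumId
  # recover writer scan ids of the form "scan=<id>"
  ids <- sub("^.*scan=", "", ids)
  z <- hdr$precursorCharge
  z[is.na(z) | z < 0L] <- 0L
  spectra_tbl(
    scan_id = ids[keep],
    ms_level = hdr$msLevel[keep],
    precursor_mz = hdr$precursorMZ[keep],
    precursor_charge = z[keep],
    peaks = lapply(pk[keep], function(m) tibble::tibble(mz = m[, 1], intensity = m[, 2]))
  )
}

#' Write spectra to MGF
#'
#' @param spectra an `xl_spectra` tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(nrow(spectra))) {
    p <- spectra$peaks[[i]]
    z <- spectra$precursor_charge[i]
    lines <- c(
      "BEGIN IONS",
      paste0("TITLE=", spectra$scan_id[i]),
      paste0("MSLEVEL=", spectra$ms_level[i]),
      paste0("PEPMASS=", format(spectra$precursor_mz[i], digits = 12)),
      if (z >= 1L) paste0("CHARGE=", z, "+"),
      if (nrow(p)) paste(format(p$mz, digits = 12, trim = TRUE),
                         format(p$intensity, digits = 10, trim = TRUE)),
      "END IONS", ""
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write spectra to mzML (via mzR)
#'
#' @inheritParams write_mgf
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("writing mzML requires the 'mzR' package", call. = FALSE)
  }
  n <- nrow(spectra)
  pk <- lapply(spectra$peaks, function(p) cbind(mz = p$mz, intensity = p$intensity))
  npk <- vapply(pk, nrow, integer(1))
  tic <- vapply(spectra$peaks, function(p) sum(p$intensity), numeric(1))
  bp <- lapply(spectra$peaks, function(p) {
    if (nrow(p)) p[which.max(p$intensity), ] else list(mz = 0, intensity = 0)
  })
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = spectra$ms_level, polarity = 1L, peaksCount = npk,
    totIonCurrent = tic, retentionTime = as.numeric(seq_len(n)),
    basePeakMZ = vapply(bp, function(b) as.numeric(b$mz), numeric(1)),
    basePeakIntensity = vapply(bp, function(b) as.numeric(b$intensity), numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(spectra$peaks, function(p) if (nrow(p)) min(p$mz) else 0, numeric(1)),
    highMZ = vapply(spectra$peaks, function(p) if (nrow(p)) max(p$mz) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = spectra$precursor_mz,
    precursorCharge = spectra$precursor_charge, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0,
    filterString = NA_character_,
    # a "scan=<id>" form would force integer parsing of the id downstream
    spectrumId = spectra$scan_id,
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = spectra$precursor_mz,
    isolationWindowLowerOffset = 1, isolationWindowUpperOffset = 1,
    scanWindowLowerLimit = 0, scanWindowUpperLimit = 1e5,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Write MS3 target lists to TSV
#'
#' One row per selected MS3 target, ordered by scan (input order) then by
#' within-scan selection order. Column layout: `scan_id`, `target_mz`,
#' `target_charge`, `doublet_rank`, `second_peptide_mass`. The resolved
#' trigger configuration is echoed into `#`-prefixed header lines so the file
#' is self-describing.
#'
#' @param decisions an `ms3_decisions` tibble from [decide()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ms3_targets <- function(decisions, path) {
  tab <- tidy_targets(decisions)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  cfg <- attr(decisions, "config")
  if (!is.null(cfg)) {
    writeLines(paste0("# ", names(cfg), " = ", unlist(cfg)), con)
  }
  xl <- attr(decisions, "crosslinker_name")
  if (!is.null(xl)) writeLines(paste0("# crosslinker = ", xl), con)
  close(con)
  on.exit()
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read an MS3 target list written by [write_ms3_targets()]
#'
#' @param path TSV path.
#' @return tibble with one row per target.
#' @export
read_ms3_targets <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    scan_id = readr::col_character(),
                    target_mz = readr::col_double(),
                    target_charge = readr::col_integer(),
                    doublet_rank = readr::col_integer(),
                    second_peptide_mass = readr::col_double()
                  ))
}

tidy_targets <- function(decisions) {
  rows <- lapply(seq_len(nrow(decisions)), function(i) {
    tg <- decisions$targets[[i]]
    if (is.null(tg) || nrow(tg) == 0L) return(NULL)
    tibble::tibble(
      scan_id = decisions$scan_id[i],
      target_mz = tg$target_mz,
      target_charge = as.integer(tg$target_charge),
      doublet_rank = as.integer(tg$doublet_rank),
      second_peptide_mass = tg$second_peptide_mass
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) {
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(scan_id = character(), target_mz = numeric(),
                   target_charge = integer(), doublet_rank = integer(),
                   second_peptide_mass = numeric())
  }
}
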
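# helper: strip peaks near given m/z values from one scan of a spectra table
strip_peaks <- function(spectra, scan, mzs, window_ppm = 50) {
  i <- which(spectra$scan_id == scan)
  p <- spectra$peaks[[i]]
  keep <- rep(TRUE, nrow(p))
  for (m in mzs) {
    # remove the whole envelope (five isotopologues is plenty)
    for (k in 0:5) {
      pos <- m + k * xl_constants$isotope_gap
      keep <- keep & abs(p$mz - pos) > window_ppm * 1e-6 * pos
    }
  }
  spectra$peaks[[i]] <- p[keep, ]
  spectra
}

test_that("doublet presence flags both / one / none as planted", {
  sim <- clean_sim(n = 4, seed = 41)
  csms <- truth_to_csms(sim$truth)
  pres <- doublet_presence(csms, sim$spectra)
  expect_true(all(pres$presence == "both"))

  # strip peptide 2's doublet envelope from the first scan -> "one"
  sid <- sim$truth$scan_id[1]
  d2 <- sim$doublets[sim$doublets$scan_id == sid & sim$doublets$peptide == 2, ]
  sp1 <- strip_peaks(sim$spectra, sid, c(d2$light_mz, d2$heavy_mz))
  pres1 <- doublet_presence(csms[csms$scan_id == sid, ], sp1)
  expect_equal(pres1$presence, "one")

  # strip both doublets -> "none"
  dall <- sim$doublets[sim$doublets$scan_id == sid, ]
  sp0 <- strip_peaks(sim$spectra, sid, c(dall$light_mz, dall$heavy_mz))
  pres0 <- doublet_presence(csms[csms$scan_id == sid, ], sp0)
  expect_equal(pres0$presence, "none")
})

test_that("missing spectra are skipped with a warning", {
  sim <- clean_sim(n = 3, seed = 42)
  csms <- truth_to_csms(sim$truth)
  csms$scan_id[1] <- "not_present"
  expect_warning(pres <- doublet_presence(csms, sim$spectra), "without a spectrum")
  expect_equal(nrow(pres), 2L)
})

test_that("correctly_triggered matches MS3 precursors to stub fragments", {
  sim <- clean_sim(n = 5, seed = 43)
  csms <- truth_to_csms(sim$truth)
  # stub fragment m/z of peptide 1: intact peptide + alkene stub, at the
  # planted doublet charge
  d1 <- sim$doublets[sim$doublets$peptide == 1, ]
  stopifnot(nrow(d1) == 5)
  good <- tibble::tibble(
    ms3_scan_id = paste0("ms3_", 1:5),
    parent_ms2_scan_id = d1$scan_id,
    ms3_precursor_mz = d1$light_mz
  )
  res <- correctly_triggered(good, csms)
  expect_equal(res$proportion, 1.0)
  expect_equal(res$n, 5L)

  # 25 ppm off every stub fragment -> incorrect
  bad <- good
  bad$ms3_precursor_mz <- bad$ms3_precursor_mz * (1 + 25e-6)
  expect_equal(correctly_triggered(bad, csms)$proportion, 0.0)

  # 8 of 10 correct -> 0.8; orphans excluded and counted
  mixed <- dplyr::bind_rows(good, good, bad[1:2, ])
  mixed$ms3_scan_id <- paste0("m", 1:12)
  mixed$parent_ms2_scan_id[11:12] <- c(d1$scan_id[1], "orphan_scan")
  # rows 1..10 = correct twice over minus none; row 11 bad with parent, 12 orphan
  res2 <- correctly_triggered(mixed, csms)
  expect_equal(res2$n, 11L)
  expect_equal(res2$n_orphans, 1L)
  expect_equal(res2$proportion, 10 / 11)
})

test_that("specificity rates report per-class means with sane intervals", {
  dec <- tibble::tibble(
    scan_id = paste0("s", 1:9),
    trigger = c(rep(TRUE, 4), rep(FALSE, 3), TRUE, TRUE),
    n_targets = c(2L, 2L, 2L, 2L, 0L, 0L, 0L, 1L, 3L),
    precursor_known = TRUE,
    targets = replicate(9, tibble::tibble(), simplify = FALSE)
  )
  classes <- tibble::tibble(
    scan_id = paste0("s", 1:9),
    class = c(rep("crosslinked", 4), rep("linear", 3), "linear_modified",
              "linear_modified")
  )
  rates <- specificity_rates(dec, classes, n_boot = 500, seed = 2)
  xlr <- rates[rates$class == "crosslinked", ]
  expect_equal(xlr$rate, 2.0)        # the ideal: one MS3 per peptide
  expect_equal(c(xlr$ci_lo, xlr$ci_hi), c(2, 2))  # degenerate distribution
  expect_equal(rates$rate[rates$class == "linear"], 0.0)
  expect_equal(rates$rate[rates$class == "linear_modified"], 2.0)  # mean(1,3)
  # CI brackets the point estimate
  expect_true(all(rates$ci_lo <= rates$rate & rates$rate <= rates$ci_hi))
})

test_that("bootstrap intervals cover the mean and shrink with sample size", {
  set.seed(5)
  x50 <- stats::rbinom(50, 4, 0.4)
  x500 <- stats::rbinom(500, 4, 0.4)
  dec_of <- function(x) tibble::tibble(
    scan_id = paste0("s", seq_along(x)), trigger = x > 0,
    n_targets = as.integer(x), precursor_known = TRUE,
    targets = replicate(length(x), tibble::tibble(), simplify = FALSE))
  cls_of <- function(x) tibble::tibble(scan_id = paste0("s", seq_along(x)),
                                       class = "crosslinked")
  r50 <- specificity_rates(dec_of(x50), cls_of(x50), n_boot = 2000, seed = 3)
  r500 <- specificity_rates(dec_of(x500), cls_of(x500), n_boot = 2000, seed = 3)
  expect_true(r50$ci_lo <= r50$rate && r50$rate <= r50$ci_hi)
  expect_true(r500$ci_lo <= r500$rate && r500$rate <= r500$ci_hi)
  expect_lt(r500$ci_hi - r500$ci_lo, r50$ci_hi - r50$ci_lo)
})

test_that("evaluate_triggering composes a coherent report", {
  sc <- synthetic_scenario(
    n_scans = 12, seed = 44, suppress_fraction = 0.3,
    class_mix = c(crosslinked = 0.5, linear = 0.25, linear_modified = 0.25))
  sim <- generate_spectra(sc)
  csms <- truth_to_csms(sim$truth)
  ev <- evaluate_triggering(sim$spectra, csms, n_boot = 300, seed = 4)
  expect_s3_class(ev, "xl_evaluation")
  expect_lte(ev$frac_both_doublets, ev$frac_one_doublet)
  expect_true(all(ev$rates$rate >= 0))
  expect_equal(ev$n_csms, sum(sim$truth$class == "crosslinked"))
  td <- tidy(ev)
  expect_true(all(c("metric", "estimate") %in% names(td)))
  gl <- glance(ev)
  expect_equal(gl$frac_both_doublets, ev$frac_both_doublets)
})

test_that("short peptides are dropped by the CSM length pre-filter", {
  csms <- tibble::tibble(
    scan_id = c("a", "b", "c"),
    peptide1 = c("PEPTIDEK", "GGK", "PEPTIDEK"),
    peptide2 = c("ELVISLIVESK", NA, "GGK"),
    link_pos1 = 1L, link_pos2 = 1L, precursor_charge = 3L,
    class = c("crosslinked", "linear", "crosslinked")
  )
  expect_equal(filter_csms(csms)$scan_id, "a")
  expect_equal(nrow(filter_csms(csms, min_peptide_length = 3)), 3L)
})
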
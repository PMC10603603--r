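test_that("peptide masses follow residue + water arithmetic", {
  gly <- nist_composition_mass(c(C = 2, H = 3, N = 1, O = 1))
  water <- nist_composition_mass(c(H = 2, O = 1))
  expect_equal(peptide_neutral_mass("G"), gly + water, tolerance = 1e-9)
  expect_equal(peptide_neutral_mass("GG"), 2 * gly + water, tolerance = 1e-9)
  # modifications are plain additive deltas
  expect_equal(peptide_neutral_mass("GG", modifications = 57.02146),
               peptide_neutral_mass("GG") + 57.02146)
  expect_error(peptide_neutral_mass(""), "empty")
  expect_error(peptide_neutral_mass("GZ"), "unknown residue")
})

test_that("y1 and b ions follow standard fragment arithmetic", {
  fr <- fragment_mzs("AK", series = "y", max_charge = 1)
  y1 <- fr[fr$ion == "y1", ]
  lys <- nist_composition_mass(c(C = 6, H = 12, N = 2, O = 1))
  water <- nist_composition_mass(c(H = 2, O = 1))
  expect_equal(y1$mz, lys + water + PROTON, tolerance = 1e-9)

  # b2 of GAK = G + A residues, protonated
  fr2 <- fragment_mzs("GAK", series = "b", max_charge = 2)
  b2 <- fr2[fr2$ion == "b2" & fr2$charge == 1, ]
  expect_equal(b2$neutral_mass,
               peptide_neutral_mass("GA") - water, tolerance = 1e-9)
  # doubly charged ion: (neutral + 2 protons) / 2
  b2z2 <- fr2[fr2$ion == "b2" & fr2$charge == 2, ]
  expect_equal(b2z2$mz, (b2$neutral_mass + 2 * PROTON) / 2, tolerance = 1e-12)
})

test_that("stub-site fragments shift by exactly the stub mass", {
  xl <- dsso()
  plain <- fragment_mzs("PEPTIDEK", series = "b", max_charge = 1)
  stubbed <- fragment_mzs("PEPTIDEK", series = "b", max_charge = 1,
                          stub_site = 3, stubs = xl$stubs)
  for (lbl in xl$stubs$label) {
    sm <- xl$stubs$mass[xl$stubs$label == lbl]
    for (i in 3:7) {
      b_plain <- plain$mz[plain$index == i]
      b_stub <- stubbed$mz[stubbed$index == i & stubbed$stub == lbl]
      expect_equal(b_stub, b_plain + sm, tolerance = 1e-9)
    }
  }
  # fragments before the site are unshifted and carry no stub
  expect_true(all(is.na(stubbed$stub[stubbed$index < 3 & stubbed$series == "b"])))
  expect_error(fragment_mzs("GK", stub_site = 5, stubs = xl$stubs),
               "outside sequence")
})

test_that("b/y complementarity holds at every cleavage position", {
  set.seed(7)
  aas <- names(residue_masses())
  for (rep in 1:30) {
    len <- sample(5:20, 1)
    pep <- paste(sample(aas, len, replace = TRUE), collapse = "")
    total <- peptide_neutral_mass(pep)
    fr <- fragment_mzs(pep, c("b", "y"), max_charge = 1)
    b <- fr[fr$series == "b", ]
    y <- fr[fr$series == "y", ]
    for (i in seq_len(len - 1)) {
      bi <- b$neutral_mass[b$index == i]
      yni <- y$neutral_mass[y$index == len - i]
      # b_i + y_(n-i) = intact neutral mass (the water already sits in y)
      expect_equal(bi + yni, total, tolerance = 1e-9)
    }
  }
})

test_that("fragment masses and linker chemistry share one mass table", {
  xl <- dsso()
  shift <- fragment_mzs("GAK", "b", 1, stub_site = 1, stubs = xl$stubs)
  plain <- fragment_mzs("GAK", "b", 1)
  got <- shift$mz[shift$ion == "b1+A"] - plain$mz[plain$ion == "b1"]
  expect_equal(got, composition_mass("C3H2O"), tolerance = 1e-12)
})

test_that("self-built spectra annotate completely with zero error", {
  xl <- dsso()
  fr <- fragment_mzs("ELVISK", c("b", "y"), max_charge = 1)
  peaks <- tibble::tibble(mz = sort(fr$mz), intensity = 10)
  ann <- annotate_spectrum(peaks, "ELVISK", xl = xl, max_frag_charge = 1)
  expect_true(all(seq_len(nrow(peaks)) %in% ann$peak_index))
  expect_true(all(abs(ann$error_ppm) < 1e-6))
})

test_that("peaks outside the annotation tolerance stay unannotated", {
  fr <- fragment_mzs("ELVISK", "y", max_charge = 1)
  target <- fr$mz[fr$ion == "y3"]
  peaks <- tibble::tibble(mz = target * (1 + 16e-6), intensity = 5)
  ann <- annotate_spectrum(peaks, "ELVISK", tol_ppm = 15, max_frag_charge = 1)
  expect_equal(nrow(ann[ann$ion == "y3", ]), 0L)
  ann2 <- annotate_spectrum(peaks, "ELVISK", tol_ppm = 20, max_frag_charge = 1)
  expect_equal(nrow(ann2[ann2$ion == "y3", ]), 1L)
})

test_that("cross-linked pair spectra annotate both peptides' stub fragments", {
  sim <- clean_sim(n = 3, seed = 31)
  xl <- dsso()
  for (i in seq_len(nrow(sim$spectra))) {
    tr <- sim$truth[i, ]
    ann <- annotate_spectrum(sim$spectra$peaks[[i]],
                             tr$peptide1, tr$link_pos1,
                             tr$peptide2, tr$link_pos2, xl = xl)
    stub_ann <- ann[!is.na(ann$stub), ]
    # the planted intact-peptide doublets carry A and T for both peptides
    for (p in 1:2) {
      dp <- sim$doublets[sim$doublets$scan_id == tr$scan_id &
                         sim$doublets$peptide == p, ]
      pa <- stub_ann[stub_ann$peptide == p & stub_ann$ion == "p+A", ]
      pt <- stub_ann[stub_ann$peptide == p & stub_ann$ion == "p+T", ]
      expect_true(any(abs(pa$mz - dp$light_mz) <= 1e-5 * dp$light_mz))
      expect_true(any(abs(pt$mz - dp$heavy_mz) <= 1e-5 * dp$heavy_mz))
    }
  }
})
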
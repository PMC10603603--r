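xl <- dsso()
d_at <- xl$doublet_pairs$delta_mass[xl$doublet_pairs$light == "A" &
                                    xl$doublet_pairs$heavy == "T"]

test_that("doublets match by delta mass and shared charge at ppm tolerance", {
  # z=1 pair exactly one sulfur apart
  d1 <- make_dpeaks(c(500, 500 + d_at), c(1, 1))
  m1 <- match_doublets(d1, xl, 5)
  expect_equal(nrow(m1), 1L)
  expect_lt(abs(m1$observed_delta_ppm), 1e-6)
  expect_equal(m1$charge, 1L)

  # charge mismatch: delta/2 spacing but charges 1 and 2
  d2 <- make_dpeaks(c(500, 500 + d_at / 2), c(1, 2))
  expect_equal(nrow(match_doublets(d2, xl, 5)), 0L)

  # z=2 doublet: delta divided by the charge state
  d3 <- make_dpeaks(c(400, 400 + d_at / 2), c(2, 2))
  m3 <- match_doublets(d3, xl, 5)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$charge, 2L)

  # partner offset by 10 ppm is outside a 5 ppm window
  theo <- 500 + d_at
  d4 <- make_dpeaks(c(500, theo * (1 + 10e-6)), c(1, 1))
  expect_equal(nrow(match_doublets(d4, xl, 5)), 0L)
  expect_equal(nrow(match_doublets(d4, xl, 11)), 1L)
})

test_that("rank filter keeps doublets with one member in the top N", {
  base <- make_dpeaks(c(500, 500 + d_at), c(1, 1))
  m <- match_doublets(base, xl, 5)
  m$light_rank <- 3L; m$heavy_rank <- 50L; m$doublet_rank <- 3L
  expect_equal(nrow(apply_rank_filter(m, 20)), 1L)
  m$light_rank <- 25L; m$heavy_rank <- 40L; m$doublet_rank <- 25L
  expect_equal(nrow(apply_rank_filter(m, 20)), 0L)
  # boundary: rank exactly at the cutoff is kept
  m$doublet_rank <- 20L
  expect_equal(nrow(apply_rank_filter(m, 20)), 1L)
  # vacuous cutoff is the identity
  expect_equal(apply_rank_filter(m, 1000), m)
})

test_that("second peptide mass recovers the planted partner peptide", {
  sim <- clean_sim(n = 6, seed = 14)
  sp <- sim$spectra
  dec_peaks <- deconvolute(sp)
  m <- match_doublets(dec_peaks, xl, 5)
  for (i in seq_len(nrow(sp))) {
    tr <- sim$truth[i, ]
    mi <- m[m$scan_id == tr$scan_id, ]
    mi$spm <- second_peptide_mass(mi, tr$precursor_mz, tr$precursor_charge, xl)
    m1 <- peptide_neutral_mass(tr$peptide1)
    m2 <- peptide_neutral_mass(tr$peptide2)
    # the doublet on peptide 1 leaves exactly peptide 2, and vice versa
    expect_true(any(abs(mi$spm - m2) < 1e-4))
    expect_true(any(abs(mi$spm - m1) < 1e-4))
  }
})

test_that("light- and heavy-member routes give the same stub-free mass", {
  sim <- clean_sim(n = 4, seed = 15)
  dpk <- deconvolute(sim$spectra)
  m <- match_doublets(dpk, xl, 5)
  heavy_mass <- xl$stubs$mass[xl$stubs$label == "T"]
  alt <- (m$heavy_mz - xl_constants$proton_mass) * m$charge - heavy_mass
  expect_equal(alt, m$peptide_stub_free_mass, tolerance = 1e-9)
})

test_that("a linker-modified linear peptide leaves ~0 Da and is filtered", {
  sc <- synthetic_scenario(n_scans = 4, class_mix = c(linear_modified = 1),
                           seed = 16)
  sim <- generate_spectra(sc)
  dpk <- deconvolute(sim$spectra)
  m <- match_doublets(dpk, xl, 5)
  expect_gt(nrow(m), 0L)  # the doublet is present in the spectrum
  for (i in seq_len(nrow(sim$spectra))) {
    mi <- m[m$scan_id == sim$spectra$scan_id[i], ]
    mi$second_peptide_mass <- second_peptide_mass(
      mi, sim$spectra$precursor_mz[i], sim$spectra$precursor_charge[i], xl)
    planted <- mi[abs(mi$second_peptide_mass) < 1e-4, ]
    expect_gt(nrow(planted), 0L)  # remaining mass ~ 0 for the planted doublet
    expect_equal(nrow(apply_second_peptide_filter(mi, 500)), 0L)
  }
})

test_that("second-peptide filter boundary keeps exactly min_mass", {
  m <- make_dpeaks(c(500, 500 + d_at), c(1, 1))
  m <- match_doublets(m, xl, 5)
  for (spm in c(499.9999, 500, 500.0001)) {
    m$second_peptide_mass <- spm
    expect_equal(nrow(apply_second_peptide_filter(m, 500)), as.integer(spm >= 500))
  }
  # unknown precursor: NA mass passes unfiltered
  m$second_peptide_mass <- NA_real_
  expect_equal(nrow(apply_second_peptide_filter(m, 500)), 1L)
})

test_that("both filters are idempotent", {
  sim <- clean_sim(n = 5, seed = 17)
  dpk <- deconvolute(sim$spectra)
  m <- match_doublets(dpk, xl, 5)
  m$second_peptide_mass <- 600
  r1 <- apply_rank_filter(m, 20)
  expect_equal(apply_rank_filter(r1, 20), r1)
  s1 <- apply_second_peptide_filter(m, 500)
  expect_equal(apply_second_peptide_filter(s1, 500), s1)
})

test_that("match_doublets equals the brute-force all-pairs oracle", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    dpk <- make_dpeaks(
      mz = stats::runif(n, 200, 1200),
      charge = sample(0:3, n, replace = TRUE),
      intensity = stats::runif(n, 1, 100)
    )
    for (tol in c(5, 50, 5000)) {
      got <- match_key(match_doublets(dpk, xl, tol))
      want <- brute_force_doublets(dpk, xl, tol)
      expect_identical(got, want)
    }
  }
})

test_that("survivor counts are monotone in cutoff, tolerance and min mass", {
  sc <- synthetic_scenario(n_scans = 10, n_noise_peaks = 80, jitter_ppm = 3,
                           seed = 18)
  sim <- generate_spectra(sc)
  dpk <- deconvolute(sim$spectra, cluster_tol_ppm = 9)
  count_surviving <- function(tol, cutoff, minmass) {
    m <- match_doublets(dpk, xl, tol)
    m <- apply_rank_filter(m, cutoff)
    idx <- match(m$scan_id, sim$spectra$scan_id)
    m$second_peptide_mass <- second_peptide_mass(
      m, sim$spectra$precursor_mz[idx], sim$spectra$precursor_charge[idx], xl)
    nrow(apply_second_peptide_filter(m, minmass))
  }
  for (tol in c(2, 8)) {
    for (cutoff in c(10, 30)) {
      for (minmass in c(800, 400)) {
        base <- count_surviving(tol, cutoff, minmass)
        expect_gte(count_surviving(tol * 2, cutoff, minmass), base)
        expect_gte(count_surviving(tol, cutoff + 20, minmass), base)
        expect_gte(count_surviving(tol, cutoff, minmass / 2), base)
      }
    }
  }
})

test_that("target selection pairs, dedups, orders and caps candidates", {
  # one surviving doublet -> both members targeted
  m1 <- match_doublets(make_dpeaks(c(500, 500 + d_at), c(1, 1)), xl, 5)
  m1$second_peptide_mass <- 900
  t1 <- select_targets(m1, cap = 4)
  expect_equal(nrow(t1), 2L)
  expect_setequal(round(t1$target_mz, 4), round(c(500, 500 + d_at), 4))

  # three doublets (six candidates) with distinct ranks, cap 4
  mk <- function(lmz, rank, summed) {
    m <- match_doublets(make_dpeaks(c(lmz, lmz + d_at), c(1, 1),
                                    intensity = c(summed, summed)), xl, 5)
    m$doublet_rank <- rank
    m$second_peptide_mass <- 900
    m
  }
  m3 <- dplyr::bind_rows(mk(400, 1L, 50), mk(600, 2L, 80), mk(800, 3L, 10))
  t3 <- select_targets(m3, cap = 4)
  expect_equal(nrow(t3), 4L)
  # ordered by doublet rank, then the two members of each doublet by
  # summed intensity (equal here) then m/z ascending
  expect_equal(round(t3$target_mz, 3),
               round(c(400, 400 + d_at, 600, 600 + d_at), 3))

  # duplicate m/z (within 1 ppm) and charge collapse to one target
  dup <- dplyr::bind_rows(m1, m1)
  expect_equal(nrow(select_targets(dup, cap = 4)), 2L)

  # no survivors
  expect_equal(nrow(select_targets(m1[0, ], cap = 4)), 0L)
})

test_that("cap obedience: targets never exceed cap", {
  sc <- synthetic_scenario(n_scans = 12, seed = 19, n_noise_peaks = 40)
  sim <- generate_spectra(sc)
  for (cap in c(1L, 2L, 4L)) {
    dec <- decide(sim$spectra, xl, trigger_config(cap = cap))
    expect_true(all(dec$n_targets <= cap))
  }
})

test_that("decide: cross-linked spectra trigger on both planted peptides", {
  sim <- clean_sim(n = 8, seed = 20)
  dec <- decide(sim$spectra)
  expect_true(all(dec$trigger))
  for (i in seq_len(nrow(dec))) {
    tg <- dec$targets[[i]]
    dbl <- sim$doublets[sim$doublets$scan_id == dec$scan_id[i], ]
    for (p in 1:2) {
      dp <- dbl[dbl$peptide == p, ]
      hit <- any(abs(tg$target_mz - dp$light_mz) <= 1e-5 * dp$light_mz |
                 abs(tg$target_mz - dp$heavy_mz) <= 1e-5 * dp$heavy_mz)
      expect_true(hit)
    }
  }
})

test_that("decide: linear and linker-modified spectra do not trigger", {
  sc <- synthetic_scenario(n_scans = 10, seed = 22,
                           class_mix = c(linear = 0.5, linear_modified = 0.5))
  sim <- generate_spectra(sc)
  dec <- decide(sim$spectra)
  expect_false(any(dec$trigger))
})

test_that("unknown precursor charge skips step 4 but still decides", {
  sc <- synthetic_scenario(n_scans = 2, class_mix = c(linear_modified = 1),
                           seed = 23)
  sim <- generate_spectra(sc)
  sp <- sim$spectra
  sp$precursor_charge <- 0L  # strip charge: the filter cannot run
  dec <- decide(sp)
  expect_false(any(dec$precursor_known))
  # without the second-peptide filter the planted doublet now triggers
  expect_true(all(dec$trigger))
})
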
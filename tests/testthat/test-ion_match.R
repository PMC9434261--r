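# Negative-mode ion enumeration and ppm matching.

glcnac_mass <- build_ladder("DAP")$mass[1]

test_that("mz_of reproduces the printed expected values for UDP-GlcNAc", {
  expect_equal(mz_of(glcnac_mass, 1, 0), 606.0738, tolerance = 1e-3)
  expect_equal(mz_of(glcnac_mass, 2, 0), 302.5330, tolerance = 1e-3)
  expect_equal(mz_of(glcnac_mass, 1, 1), 628.0557, tolerance = 1e-3)
  expect_error(mz_of(glcnac_mass, 0, 0), "non-zero")
  expect_error(mz_of(glcnac_mass, 1, -1), ">= 0")
})

test_that("proton convention differs from hydrogen-atom convention by ~1 ppm/charge", {
  atom <- mz_of(glcnac_mass, 1, 0, convention = "atom")
  prot <- mz_of(glcnac_mass, 1, 0, convention = "proton")
  expect_gt(prot, atom)  # removing a lighter particle leaves more mass
  expect_equal((prot - atom) / atom * 1e6, 0.9, tolerance = 0.2)
})

test_that("ion enumeration covers the species x z x k grid, sorted by m/z", {
  lad <- build_ladder("DAP")
  ions <- enumerate_ions(lad, match_config(z_range = 1:3, k_range = 0:3))
  expect_equal(nrow(ions), 5 * 3 * 4)
  expect_true(!is.unsorted(ions$mz))
  penta_na2 <- ions[ions$species == "UDP-MurNAc-Ala-Glu-DAP-Ala-Ala" &
                      ions$z == 2 & ions$k == 1, ]
  expect_equal(penta_na2$mz, 606.6539, tolerance = 1e-3)
  expect_equal(penta_na2$label, "(m+Na+-2)/2")
})

test_that("consecutive sodium exchanges are spaced 21.9819/z apart", {
  ions <- enumerate_ions(build_ladder("DAP"), match_config())
  for (z in 1:3) {
    for (sp in unique(ions$species)) {
      sub <- ions[ions$species == sp & ions$z == z, ]
      sub <- sub[order(sub$k), ]
      expect_equal(diff(sub$mz), rep(21.9819 / z, 3), tolerance = 1e-4)
    }
  }
})

test_that("at fixed k, higher charge gives strictly smaller m/z", {
  ions <- enumerate_ions(build_ladder("DAP"), match_config())
  for (sp in unique(ions$species)) {
    sub <- ions[ions$species == sp & ions$k == 0, ]
    expect_true(all(diff(sub$mz[order(sub$z)]) < 0))
  }
})

test_that("a single peak matches with the expected signed ppm error", {
  lad <- build_ladder("DAP")
  ions <- enumerate_ions(lad, match_config())
  rep <- match_peaks(606.0814, ions, match_config(tolerance_ppm = 30))
  expect_equal(nrow(rep$matches), 1)
  expect_equal(rep$matches$species, "UDP-GlcNAc")
  expect_equal(rep$matches$ppm_error, 12.7, tolerance = 0.2)
})

test_that("zero tolerance admits only exact coincidences", {
  ions <- enumerate_ions(build_ladder("DAP"), match_config())
  cfg0 <- match_config(tolerance_ppm = 0)
  exact <- match_peaks(ions$mz[7], ions, cfg0)
  expect_equal(nrow(exact$matches), 1)
  off <- match_peaks(ions$mz[7] * (1 + 1e-6), ions, cfg0)
  expect_equal(nrow(off$matches), 0)
  expect_equal(nrow(off$unassigned), 1)
})

test_that("empty inputs behave per contract", {
  ions <- enumerate_ions(build_ladder("DAP"), match_config())
  expect_error(match_peaks(numeric(0), ions[0, ], match_config()), "non-empty")
  rep <- match_peaks(numeric(0), ions, match_config())
  expect_equal(nrow(rep$matches), 0)
  expect_equal(nrow(identify_intermediates(rep)), 0)
})

test_that("ppm error is antisymmetric to first order and bounded by tolerance", {
  o <- 606.0814; t <- 606.0737
  expect_equal(ppm_error(o, t), -ppm_error(t, o), tolerance = 1e-3)
  rep <- reproduce_table1("both")$report
  expect_true(all(abs(rep$matches$ppm_error) <= rep$config$tolerance_ppm))
})

test_that("match_peaks agrees exactly with the brute-force all-pairs oracle", {
  set.seed(21)
  lad <- combine_ladders(build_ladder("DAP"), build_ladder("Lys"))
  cfg <- match_config(tolerance_ppm = 30)
  ions <- enumerate_ions(lad, cfg)
  for (rep in 1:5) {
    n <- sample(5:100, 1)
    base <- sample(ions$mz, n, replace = TRUE)
    peaks <- base * (1 + rnorm(n, 0, 25) * 1e-6)  # some beyond tolerance
    got <- match_peaks(peaks, ions, cfg)
    want <- oracle_match(peaks, ions, 30)
    hit <- !is.na(want)
    expect_equal(nrow(got$matches), sum(hit))
    expect_equal(got$matches$theoretical_mz, ions$mz[want[hit]])
    expect_equal(got$matches$species, ions$species[want[hit]])
  }
})

test_that("exact ppm ties break to lower charge then lower sodium count", {
  # two synthetic species engineered so that two ions coincide exactly
  lad <- build_ladder("DAP")
  ions <- enumerate_ions(lad, match_config())
  dup <- ions[c(1, 1), ]
  dup$z <- c(2L, 1L); dup$k <- c(0L, 0L); dup$mz <- c(500, 500)
  class(dup) <- class(ions)
  rep <- match_peaks(500, dup, match_config())
  expect_equal(rep$matches$z, 1L)
})

test_that("species simulated into a peak list are recovered exactly (round trip)", {
  lad <- build_ladder("DAP")[c(1, 3, 5), ]
  class(lad) <- c("precursor_ladder", "data.frame")
  peaks <- simulate_peaklist(lad, seed = 7, ppm_bias = 0, ppm_sd = 5,
                             ion_prob = 0.5, n_decoys = 10)
  ions <- enumerate_ions(build_ladder("DAP"), match_config())
  rep <- match_peaks(peaks$mz, ions, match_config(tolerance_ppm = 30))
  ided <- identify_intermediates(rep)
  expect_setequal(ided$species, lad$species)
})
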
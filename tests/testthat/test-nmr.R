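test_that("uniform intensity integrates proportionally to region widths", {
  grid <- seq(-15, 215, by = 0.1)
  s <- spectrum(grid, rep(1, length(grid)), kind = "chemical_shift_ppm")
  ints <- integrate_regions(s)
  expect_equal(ints$relative[["alkyl"]], 100 * 55 / 220, tolerance = 1e-9)
  expect_equal(ints$relative[["carbonyl"]], 100 * 45 / 220, tolerance = 1e-9)
  expect_equal(ints$relative[["o_alkyl"]], 100 * 35 / 220, tolerance = 1e-9)
  expect_equal(sum(ints$relative), 100, tolerance = 1e-9)
})

test_that("region integrals recover generator truth and scale invariance", {
  targets <- nmr_row_targets("A", "initial")
  g <- make_nmr_spectrum(targets, noise_sd = 0.002, seed = 13)
  ints <- integrate_regions(g$spec)
  expect_lt(max(abs(ints$relative[names(targets)] - targets)), 0.5)
  # positive scaling leaves percentages unchanged
  scaled <- spectrum(g$spec$axis, g$spec$intensity * 11,
                     kind = "chemical_shift_ppm")
  expect_equal(integrate_regions(scaled)$relative, ints$relative,
               tolerance = 1e-12)
  # zero-noise round trip at quadrature accuracy
  g0 <- make_nmr_spectrum(targets)
  ints0 <- integrate_regions(g0$spec)
  expect_lt(max(abs(ints0$relative[names(targets)] - targets)), 0.05)
})

test_that("region integrals are additive when regions are merged", {
  g <- make_nmr_spectrum(nmr_row_targets("B", "maturity"))
  full <- integrate_regions(g$spec)
  merged <- tibble::tribble(
    ~label, ~high_ppm, ~low_ppm,
    "carbonyl", 210, 165,
    "aromatic_all", 165, 110,   # o_aromatic + aromatic merged
    "o2_alkyl", 110, 95,
    "o_alkyl", 95, 60,
    "n_alkyl_methoxy", 60, 45,
    "alkyl", 45, -10)
  m <- integrate_regions(g$spec, scheme = merged)
  expect_equal(m$raw[["aromatic_all"]],
               full$raw[["o_aromatic"]] + full$raw[["aromatic"]],
               tolerance = 1e-9)
})

test_that("baseline offset changes raw but not badly the percentages", {
  targets <- nmr_row_targets("C", "maturity")
  g <- make_nmr_spectrum(targets)
  lifted <- spectrum(g$spec$axis, g$spec$intensity + 0.02,
                     kind = "chemical_shift_ppm")
  ints <- integrate_regions(lifted,
                            baseline_offset = "median_of_signal_free_region")
  expect_lt(max(abs(ints$relative[names(targets)] - targets)), 0.5)
  expect_equal(sum(ints$relative), 100, tolerance = 1e-9)
})

test_that("alkyl/O-alkyl ratio matches published rows and rises with age", {
  expect_equal(round(alkyl_oalkyl_ratio(c(alkyl = 30.7, o_alkyl = 31.7)), 2),
               0.97)
  expect_equal(round(alkyl_oalkyl_ratio(c(alkyl = 34.3, o_alkyl = 23.6)), 2),
               1.45)
  expect_equal(alkyl_oalkyl_ratio(c(alkyl = 20, o_alkyl = 20)), 1)
  expect_error(alkyl_oalkyl_ratio(c(alkyl = 20, o_alkyl = 0)), "zero")
  # maturation sequence: ratio strictly increases initial -> maturity
  for (p in c("A", "B", "C")) {
    r <- sapply(c("initial", "maturity"), function(ph) {
      g <- make_nmr_spectrum(nmr_row_targets(p, ph), noise_sd = 0.002,
                             seed = 3)
      alkyl_oalkyl_ratio(integrate_regions(g$spec))
    })
    expect_lt(r[["initial"]], r[["maturity"]])
  }
})

test_that("spin counting is a normalised intensity ratio", {
  expect_equal(spin_count(100, 2, 1000, 100, 2, 1000)$cobs, 100)
  # 63 % of the standard's per-mg-per-scan intensity
  expect_equal(spin_count(63, 1, 1, 100, 1, 1)$cobs, 63)
  # doubling scans at fixed total intensity halves Cobs
  a <- spin_count(80, 2, 2000, 100, 2, 1000)
  b <- suppressWarnings(spin_count(80, 2, 4000, 100, 2, 1000))
  expect_equal(b$cobs, a$cobs / 2)
  expect_error(spin_count(0, 1, 1, 1, 1, 1), "positive")
  expect_warning(spin_count(20, 1, 1, 100, 1, 1), "40-110")
})

test_that("scheme validation rejects gaps and overlaps", {
  bad <- default_nmr_regions()
  bad$low_ppm[2] <- 140
  expect_error(integrate_regions(
    make_nmr_spectrum(nmr_row_targets("A", "initial"))$spec, scheme = bad),
    "contiguous")
  short <- spectrum(seq(0, 100, 0.2), rep(1, 501),
                    kind = "chemical_shift_ppm")
  expect_error(integrate_regions(short), "cover")
})
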
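test_that("humification indices reproduce hand and back-solved values", {
  expect_equal(humification_ratio(13, 100), 13)
  expect_equal(humification_ratio(0, 40), 0)
  # CT back-solved from the published HR of pile A initial (Cext = Cfa+Cha)
  ct <- 100 * 6.52 / 12.99
  expect_equal(humification_ratio(6.52, ct), 12.99, tolerance = 1e-10)
  expect_equal(humification_index(2.98, ct), 5.94, tolerance = 0.01 / 5.94)
  expect_equal(humification_index(0, 50), 0)
  expect_equal(humification_index(50, 50), 100)
  expect_equal(percentage_humic_acids(2.98, 6.52), 45.71, tolerance = 1e-3)
  expect_equal(percentage_humic_acids(1, 2), 50)
  expect_equal(percentage_humic_acids(1.43, 4.34), 32.95, tolerance = 1e-3)
  expect_equal(polymerisation_rate(2.98, 3.54), 0.84, tolerance = 0.005)
  expect_equal(polymerisation_rate(1.43, 2.91), 0.49, tolerance = 0.005)
  expect_equal(polymerisation_rate(0, 1), 0)
})

test_that("index domain errors are raised", {
  expect_error(humification_ratio(5, 0), "positive")
  expect_error(humification_ratio(6, 5), "exceeds")
  expect_error(humification_index(-1, 5), "non-negative")
  expect_error(percentage_humic_acids(1, 0), "positive")
  expect_error(polymerisation_rate(1, 0), "positive")
  expect_error(elemental_ratio(1, 0), "positive")
  expect_error(percent_decrease(0, 1), "positive")
})

test_that("om_loss follows the ash balance and flags anomalies", {
  expect_equal(om_loss(10, 10), 0)
  expect_equal(om_loss(20, 40), 62.5)
  expect_warning(neg <- om_loss(30, 15), "anomaly")
  expect_lt(neg, 0)
  expect_error(om_loss(0, 50))
  expect_error(om_loss(50, 100))
  # strict monotonicity in each argument
  x2 <- seq(5, 95, by = 5)
  expect_true(all(diff(suppressWarnings(om_loss(20, x2))) > 0))
  expect_true(all(diff(suppressWarnings(om_loss(x2, 50))) < 0))
  # zero on the diagonal
  expect_true(all(abs(om_loss(x2, x2)) < 1e-12))
})

test_that("Pha * HR / 100 == HI and indices are scale invariant", {
  set.seed(11)
  for (i in 1:50) {
    cfa <- runif(1, 0.5, 5); cha <- runif(1, 0.5, 5)
    fr <- humic_fractions(cfa, cha)
    ct <- fr$cext + runif(1, 10, 60)
    hr <- humification_ratio(fr$cext, ct)
    hi <- humification_index(fr$cha, ct)
    pha <- percentage_humic_acids(fr$cha, fr$cext)
    expect_equal(pha * hr / 100, hi, tolerance = 1e-9)
    s <- runif(1, 0.1, 10)  # common rescaling leaves all indices unchanged
    expect_equal(humification_ratio(s * fr$cext, s * ct), hr, tolerance = 1e-12)
    expect_equal(humification_index(s * fr$cha, s * ct), hi, tolerance = 1e-12)
    expect_equal(percentage_humic_acids(s * fr$cha, s * fr$cext), pha,
                 tolerance = 1e-12)
    expect_equal(polymerisation_rate(s * cha, s * cfa),
                 polymerisation_rate(cha, cfa), tolerance = 1e-12)
  }
})

test_that("humic_fractions enforces consistency of Cext", {
  expect_equal(humic_fractions(3.54, 2.98)$cext, 6.52)
  expect_error(humic_fractions(3, 2, cext = 1), ">=")
  expect_error(humic_fractions(3, 2, cext = 5.2), "tolerance")
  expect_equal(humic_fractions(3, 2, cext = 5.04)$cext, 5.04)
})

test_that("percent decreases in WSC/TN match the published integers", {
  chem <- winery_compost_chemical()
  dec <- sapply(c("A", "B", "C"), function(p) {
    rows <- chem[chem$pile_id == p, ]
    percent_decrease(rows$wsc_tn[rows$phase == "initial"],
                     rows$wsc_tn[rows$phase == "maturity"])
  })
  expect_equal(round(dec), c(A = 70, B = 62, C = 73))
  expect_equal(percent_decrease(5, 5), 0)
})

test_that("maturity flags use the field thresholds and NA for missing", {
  f <- maturity_flags(toc_tn = 17.4, wsc = 1.10, gi = 78.2)
  expect_true(all(f))
  f2 <- maturity_flags(toc_tn = 21.9)
  expect_false(f2[["tocn_mature"]])
  expect_true(is.na(f2[["wsc_mature"]]) && is.na(f2[["gi_nonphytotoxic"]]))
  expect_true(maturity_flags(wsc = 1.7)[["wsc_mature"]])  # inclusive bound
  expect_false(maturity_flags(gi = 50)[["gi_nonphytotoxic"]])  # strict
})

test_that("chem_index_table derives the full index set and round-trips CSV", {
  chem <- winery_compost_chemical()
  samples <- tibble::tibble(
    pile_id = chem$pile_id, phase = chem$phase, day = chem$day,
    toc = chem$toc_tn * 2.5, tn = 2.5, wsc = chem$wsc,
    cfa = chem$cfa, cha = chem$cha,
    gi = ifelse(chem$phase == "maturity", 70, NA_real_))
  tab <- chem_index_table(samples)
  expect_equal(tab$toc_tn, chem$toc_tn, tolerance = 1e-12)
  expect_equal(tab$cha_cfa, chem$cha / chem$cfa, tolerance = 1e-12)
  expect_equal(tab$pha, 100 * chem$cha / (chem$cfa + chem$cha),
               tolerance = 1e-12)
  expect_true(all(is.na(tab$gi_nonphytotoxic[samples$phase != "maturity"])))
  p <- tempfile(fileext = ".csv")
  utils::write.csv(samples, p, row.names = FALSE)
  rt <- read_compost_samples(p)
  expect_equal(rt$cha, samples$cha)
  unlink(p)
})
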
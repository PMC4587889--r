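test_that("generators are bit-identical under a fixed seed", {
  sc <- pile_scenario("B")
  a <- make_temperature_series(sc, noise_sd = 0.5, seed = 7)
  b <- make_temperature_series(sc, noise_sd = 0.5, seed = 7)
  expect_identical(a$series$pile_temp, b$series$pile_temp)
  o1 <- make_om_loss_series(sc, noise_sd = 2, seed = 7)
  o2 <- make_om_loss_series(sc, noise_sd = 2, seed = 7)
  expect_identical(o1$losses, o2$losses)
  t1 <- make_pile_thermogram(sc, "initial", noise_sd = 0.05, seed = 7)
  t2 <- make_pile_thermogram(sc, "initial", noise_sd = 0.05, seed = 7)
  expect_identical(t1$gram$mass, t2$gram$mass)
  f1 <- make_ftir_spectrum(ftir_row_heights("B", "initial"),
                           noise_sd = 1e-3, seed = 7)
  f2 <- make_ftir_spectrum(ftir_row_heights("B", "initial"),
                           noise_sd = 1e-3, seed = 7)
  expect_identical(f1$spec$intensity, f2$spec$intensity)
  n1 <- make_nmr_spectrum(nmr_row_targets("B", "initial"), noise_sd = 0.01,
                          seed = 7)
  n2 <- make_nmr_spectrum(nmr_row_targets("B", "initial"), noise_sd = 0.01,
                          seed = 7)
  expect_identical(n1$spec$intensity, n2$spec$intensity)
  # generators do not disturb the session RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(make_om_loss_series(sc, noise_sd = 1, seed = 99))
  expect_identical(runif(1), r1)
})

test_that("temperature generator truth gives EXI a closed form", {
  sc <- pile_scenario("A")
  g <- make_temperature_series(sc, days = 60)
  expect_equal(exothermic_index(g$series, 60), sum(g$truth$offsets),
               tolerance = 1e-9)
  # zero heating amplitude -> pile == ambient, EXI truth 0
  sc0 <- sc; sc0$heating_amplitude <- 0
  g0 <- make_temperature_series(sc0, days = 40)
  expect_equal(g0$series$pile_temp, g0$series$ambient_temp)
  expect_equal(g0$truth$exi_full, 0)
  # higher labile fraction alone raises the EXI truth
  lo <- sc; lo$labile_fraction <- 0.2
  hi <- sc; hi$labile_fraction <- 0.7
  expect_lt(make_temperature_series(lo, days = 80)$truth$exi_full,
            make_temperature_series(hi, days = 80)$truth$exi_full)
})

test_that("OM-loss generator matches the model exactly at zero noise", {
  sc <- pile_scenario("A")
  g <- make_om_loss_series(sc, sample_days = c(0, 28, 105, 168))
  expect_equal(g$losses, predict_om_loss(49.6, 0.0131, c(0, 28, 105, 168)))
})

test_that("thermogram generator enforces a physical total loss", {
  expect_error(make_thermogram(data.frame(center = c(300, 480),
                                          sigma = c(10, 10),
                                          loss = c(60, 45))), "< 100")
  flat <- make_thermogram(data.frame(center = numeric(), sigma = numeric(),
                                     loss = numeric())[0, ])
  expect_equal(flat$gram$mass, rep(100, 501))
})

test_that("pile thermogram targets are hit by the closed-form truth", {
  for (p in c("A", "C")) {
    sc <- pile_scenario(p)
    for (ph in c("initial", "maturity")) {
      mk <- make_pile_thermogram(sc, ph)
      expect_equal(mk$truth$mass_loss(c(250, 400)),
                   sc$tg_targets[[ph]][["p1"]], tolerance = 1e-6)
      expect_equal(mk$truth$mass_loss(c(400, 580)),
                   sc$tg_targets[[ph]][["p2"]], tolerance = 1e-6)
      expect_equal(mk$truth$dta_area(c(250, 400)),
                   sc$dta_targets[[ph]][["p1"]], tolerance = 1e-6)
    }
  }
})

test_that("nmr generator rejects malformed targets", {
  t <- nmr_row_targets("A", "initial")
  expect_error(make_nmr_spectrum(t * 1.1), "sum to 100")
  expect_error(make_nmr_spectrum(t[-1]), "every scheme region")
})

test_that("scenario ordering properties hold across a seed sweep", {
  scA <- pile_scenario("A"); scB <- pile_scenario("B"); scC <- pile_scenario("C")
  for (seed in 1:20) {
    exi <- sapply(list(scA, scB, scC), function(sc) {
      g <- make_temperature_series(sc, noise_sd = 0.3, seed = seed)
      end <- suppressWarnings(detect_bio_oxidative_end(g$series))
      exothermic_index(g$series, end)
    })
    expect_true(exi[2] > exi[1] && exi[2] > exi[3])  # B most exothermic
    expect_lt(abs(exi[1] - exi[3]) / exi[1], 0.2)    # A and C similar
  }
})
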
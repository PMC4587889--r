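test_that("DTG of exact shapes: line, constant, Gaussian event", {
  grid <- seq(150, 650, by = 1)
  lin <- thermogram(grid, 100 - 0.1 * (grid - 150))
  d <- compute_dtg(lin)
  expect_equal(d$dtg, rep(0.1, length(grid)), tolerance = 1e-10)
  flat <- thermogram(grid, rep(90, length(grid)))
  expect_equal(max(abs(compute_dtg(flat)$dtg)), 0, tolerance = 1e-12)
  # mass curve whose DTG is a Gaussian (center 320, sigma 25, area 30 %)
  mk <- make_thermogram(data.frame(center = 320, sigma = 25, loss = 30))
  d2 <- compute_dtg(mk$gram)
  expect_lt(abs(d2$temperature[which.max(d2$dtg)] - 320), 2)
  sel <- d2$temperature >= 250 & d2$temperature <= 400
  area <- pracma::trapz(d2$temperature[sel], d2$dtg[sel])
  expect_equal(area, mk$truth$mass_loss(c(250, 400)), tolerance = 0.01)
  expect_error(compute_dtg(mk$gram, smooth_window = 2), "3 grid points")
})

test_that("DTG peak detection finds peaks per window", {
  mk <- make_thermogram(data.frame(center = c(300, 480),
                                   sigma = c(10, 10), loss = c(20, 15)))
  pks <- detect_dtg_peaks(compute_dtg(mk$gram),
                          windows = list(c(250, 400), c(400, 580)))
  expect_equal(nrow(pks), 2)
  expect_lt(abs(pks$temperature[1] - 300), 2)
  expect_lt(abs(pks$temperature[2] - 480), 2)
  # three components, two windows: {280, 360} then {480}
  mk3 <- make_thermogram(data.frame(center = c(280, 360, 480),
                                    sigma = c(9, 9, 10),
                                    loss = c(15, 20, 12)))
  pks3 <- detect_dtg_peaks(compute_dtg(mk3$gram),
                           windows = list(c(250, 400), c(450, 500)))
  expect_equal(pks3$window, c(1L, 1L, 2L))
  expect_equal(pks3$temperature, c(280, 360, 480), tolerance = 2 / 280)
  # flat trace -> empty (with warning for empty windows)
  flat <- thermogram(seq(150, 650, 1), rep(90, 501))
  expect_warning(none <- detect_dtg_peaks(compute_dtg(flat),
                                          windows = list(c(250, 400))))
  expect_equal(nrow(none), 0)
  expect_error(detect_dtg_peaks(compute_dtg(mk$gram),
                                windows = list(c(700, 800))), "overlap")
})

test_that("region mass loss matches the Gaussian-CDF closed form", {
  mk <- make_thermogram(data.frame(center = 320, sigma = 15, loss = 30))
  expect_equal(region_mass_loss(mk$gram, c(250, 400)),
               mk$truth$mass_loss(c(250, 400)), tolerance = 0.5 / 30)
  expect_equal(region_mass_loss(mk$gram, c(250, 400)), 30, tolerance = 0.5 / 30)
  # plateau region
  expect_equal(region_mass_loss(mk$gram, c(500, 600)), 0, tolerance = 1e-6)
  # full-span on a 70 % two-component curve
  mk2 <- make_thermogram(data.frame(center = c(300, 480),
                                    sigma = c(15, 15), loss = c(40, 30)))
  expect_equal(region_mass_loss(mk2$gram, c(150, 650)), 70, tolerance = 0.5 / 70)
  # additive over adjacent regions (exact under linear interpolation)
  expect_equal(region_mass_loss(mk2$gram, c(200, 380)) +
                 region_mass_loss(mk2$gram, c(380, 560)),
               region_mass_loss(mk2$gram, c(200, 560)), tolerance = 1e-12)
  expect_error(region_mass_loss(mk$gram, c(100, 300)), "outside")
})

test_that("DTA peak areas are baseline-corrected and drift-invariant", {
  base <- data.frame(center = 320, sigma = 15, loss = 30)
  exo <- data.frame(center = 320, sigma = 12, area = 500)
  mk <- make_thermogram(base, exo)
  expect_equal(dta_peak_area(mk$gram, c(250, 400)), 500, tolerance = 0.01)
  # zero heat flow
  mk0 <- make_thermogram(base)
  expect_equal(dta_peak_area(mk0$gram, c(250, 400)), 0, tolerance = 1e-9)
  # Gaussian on sloped baseline, linear-endpoint correction
  mks <- make_thermogram(base, exo, drift = c(5, 0.01))
  expect_equal(dta_peak_area(mks$gram, c(250, 400)), 500, tolerance = 0.02)
  # invariant to adding a constant (linear_endpoints baseline)
  mkc <- make_thermogram(base, exo, drift = c(42, 0))
  expect_equal(dta_peak_area(mkc$gram, c(250, 400)),
               dta_peak_area(mk$gram, c(250, 400)), tolerance = 1e-9)
})

test_that("thermal indices reproduce printed ratios and rise with maturation", {
  # ratio arithmetic on published P1/P2 values
  th <- winery_compost_thermal()
  expect_equal(round(th$p2_mass / th$p1_mass, 2), th$r1)
  expect_equal(round(th$p2_area / th$p1_area, 2), th$r2)
  # synthetic maturation sequence: r1 and r2 strictly increase per pile
  for (p in c("A", "B", "C")) {
    sc <- pile_scenario(p)
    ti_i <- thermal_indices(make_pile_thermogram(sc, "initial")$gram)
    ti_m <- thermal_indices(make_pile_thermogram(sc, "maturity")$gram)
    expect_lt(ti_i$r1, ti_m$r1)
    expect_lt(ti_i$r2, ti_m$r2)
  }
  # symmetry: identical signal in both regions gives r1 = r2 = 1
  sym <- make_thermogram(
    data.frame(center = c(325, 490), sigma = c(10, 10), loss = c(20, 20)),
    data.frame(center = c(325, 490), sigma = c(10, 10), area = c(300, 300)))
  ti <- thermal_indices(sym$gram)
  expect_equal(ti$r1, 1, tolerance = 1e-6)
  expect_equal(ti$r2, 1, tolerance = 1e-6)
  expect_error(thermal_indices(sym$gram, p1 = c(400, 580), p2 = c(250, 400)),
               "precede")
})

test_that("thermograms read from delimited text, absolute mass normalised", {
  mk <- make_pile_thermogram(pile_scenario("B"), "initial", noise_sd = 0.01,
                             seed = 4)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(temperature_c = mk$gram$temperature,
                              mass_mg = mk$gram$mass * 0.05,  # 5 mg sample
                              heat_flow = mk$gram$heat_flow),
                   p, row.names = FALSE)
  rt <- read_thermogram(p)
  expect_equal(rt$mass, mk$gram$mass, tolerance = 1e-9)
  unlink(p)
  expect_error(thermogram(seq(200, 650, 1), rep(50, 451)), "150")
  expect_error(thermogram(seq(150, 650, 10), rep(50, 51)), "100 grid points")
})
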
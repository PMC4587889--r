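# Seeded generators for the five input kinds. Every generator is
# deterministic under a fixed seed and returns its exact generating
# parameters ("truth") alongside the data, so each analysis stage can be
# tested against a closed-form oracle without instrument files.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Pile scenario presets
#'
#' Parameter bundles emulating the three co-composting piles: A (exhausted
#' grape marc + cattle manure), B (grape marc + cattle manure, richer in
#' water-soluble easily degradable compounds, hence the largest labile
#' fraction and the most exothermic behaviour) and C (exhausted grape marc
#' + poultry manure, initially inhibited by polyphenols). Kinetic
#' parameters are the published first-order fits; TG/DTA targets are the
#' published region mass losses and peak areas.
#'
#' @param pile_id `"A"`, `"B"` or `"C"`.
#' @return A list of class `pile_scenario`: `pile_id`, `labile_fraction`,
#'   `recalcitrant_fraction`, `a_max_true`, `k_true`, `heating_amplitude`
#'   (degC), `turning_days`, `tg_targets` (per-phase P1/P2 mass losses, %),
#'   `dta_targets` (per-phase P1/P2 areas).
#' @export
pile_scenario <- function(pile_id = c("A", "B", "C")) {
  pile_id <- match.arg(pile_id)
  kin <- winery_compost_kinetics()
  kin <- kin[kin$pile_id == pile_id, ]
  th <- winery_compost_thermal()
  th_i <- th[th$pile_id == pile_id & th$phase == "initial", ]
  th_m <- th[th$pile_id == pile_id & th$phase == "maturity", ]
  labile <- c(A = 0.35, B = 0.60, C = 0.30)[[pile_id]]
  structure(list(
    pile_id = pile_id,
    labile_fraction = labile,
    recalcitrant_fraction = 0.25,
    a_max_true = kin$a_max,
    k_true = kin$k_rate,
    heating_amplitude = 30,
    turning_days = c(14, 28, 42, 56, 70, 84),
    tg_targets = list(
      initial = c(p1 = th_i$p1_mass, p2 = th_i$p2_mass),
      maturity = c(p1 = th_m$p1_mass, p2 = th_m$p2_mass)),
    dta_targets = list(
      initial = c(p1 = th_i$p1_area, p2 = th_i$p2_area),
      maturity = c(p1 = th_m$p1_area, p2 = th_m$p2_area))),
    class = "pile_scenario")
}

#' Synthetic pile/ambient temperature series
#'
#' Daily series over `days` days: sinusoidal ambient plus a pile offset
#' built from a double-exponential heating curve (fast microbial rise, slow
#' decay) scaled by `heating_amplitude * (0.5 + labile_fraction)`, with
#' re-heating spikes after each turning day whose size decays as the labile
#' pool is exhausted. The exact per-day offsets are returned as truth, so
#' the exothermic index has a closed-form expected value
#' (`sum(truth$offsets)` over the bio-oxidative window).
#'
#' @param scenario A `pile_scenario`.
#' @param days Number of days (>= 30).
#' @param noise_sd Gaussian noise sd (degC) added to pile and ambient
#'   readings (0 = noiseless).
#' @param seed Random seed.
#' @param rise_days,decay_days Time constants of the heating curve, days.
#' @return List with `series` (a [temperature_series()]) and `truth`
#'   (`offsets`, `ambient_base`, `exi_full` = sum of all offsets).
#' @export
make_temperature_series <- function(scenario, days = 110, noise_sd = 0,
                                    seed = 1, rise_days = 3,
                                    decay_days = 30) {
  stopifnot(inherits(scenario, "pile_scenario"), days >= 30)
  d <- 0:(days - 1)
  amp <- scenario$heating_amplitude * (0.5 + scenario$labile_fraction)
  shape <- exp(-d / decay_days) - exp(-d / rise_days)
  shape <- shape / max(shape)
  offsets <- amp * shape
  for (j in seq_along(scenario$turning_days)) {
    t0 <- scenario$turning_days[j]
    if (t0 >= days) next
    spike <- 0.45 * amp * exp(-t0 / (2 * decay_days)) *
      ifelse(d >= t0, exp(-(d - t0) / 4), 0)
    offsets <- offsets + spike
  }
  ambient_base <- 16 + 4 * sin(2 * pi * d / 90)
  noise_p <- if (noise_sd > 0) with_seed(seed, stats::rnorm(days, 0, noise_sd)) else 0
  noise_a <- if (noise_sd > 0) with_seed(seed + 1L, stats::rnorm(days, 0, noise_sd)) else 0
  series <- temperature_series(
    times = d, pile_temp = ambient_base + offsets + noise_p,
    ambient_temp = ambient_base + noise_a,
    turning_days = scenario$turning_days)
  list(series = series,
       truth = list(offsets = offsets, ambient_base = ambient_base,
                    exi_full = sum(offsets)))
}

#' Synthetic OM-loss time series from the first-order model
#'
#' @param scenario A `pile_scenario` (supplies `a_max_true`, `k_true`).
#' @param sample_days Sampling days; default 16 evenly spaced samplings
#'   across the 168-day composting trial (bio-oxidative phase plus
#'   maturation).
#' @param noise_sd Gaussian noise sd on the losses, in percentage points
#'   (values clipped to \[0, 100\]).
#' @param seed Random seed.
#' @return List with `times`, `losses`, `truth` (`a_max`, `k_rate`).
#' @export
make_om_loss_series <- function(scenario, sample_days = seq(0, 165, by = 11),
                                noise_sd = 0, seed = 1) {
  stopifnot(inherits(scenario, "pile_scenario"))
  mu <- predict_om_loss(scenario$a_max_true, scenario$k_true, sample_days)
  y <- if (noise_sd > 0)
    with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd)) else mu
  list(times = sample_days, losses = pmin(pmax(y, 0), 100),
       truth = list(a_max = scenario$a_max_true, k_rate = scenario$k_true))
}

#' Synthetic thermogram from Gaussian mass-loss and exotherm components
#'
#' Mass is 100 % minus a sum of cumulative-Gaussian losses (each component
#' a `(center, sigma, loss)` triple); the DTA signal is a sum of Gaussian
#' exotherms (`(center, sigma, area)` triples) plus an optional linear
#' drift. The truth carries closed-form per-region losses/areas (Gaussian
#' CDF differences), usable as an exact oracle for [region_mass_loss()] and
#' [dta_peak_area()].
#'
#' @param components Matrix/data.frame with columns `center`, `sigma`,
#'   `loss` (degC, degC, %); total loss must stay below 100 %.
#' @param dta_components Columns `center`, `sigma`, `area`.
#' @param noise_sd Gaussian ordinate noise sd (mass %, and signal units on
#'   the DTA trace).
#' @param seed Random seed.
#' @param drift `c(intercept, slope)` linear baseline added to the DTA
#'   signal.
#' @param grid Temperature grid, degC.
#' @return List with `gram` (a [thermogram()]) and `truth` (functions
#'   `mass_loss(region)` and `dta_area(region)` plus the component tables).
#' @export
make_thermogram <- function(components, dta_components = NULL, noise_sd = 0,
                            seed = 1, drift = c(0, 0),
                            grid = seq(150, 650, by = 1)) {
  cp <- as.data.frame(components)
  stopifnot(all(c("center", "sigma", "loss") %in% names(cp)))
  if (sum(cp$loss) >= 100)
    stop("make_thermogram: total mass loss must be < 100 %")
  mass <- rep(100, length(grid))
  for (i in seq_len(nrow(cp)))
    mass <- mass - cp$loss[i] * stats::pnorm(grid, cp$center[i], cp$sigma[i])
  heat <- rep(0, length(grid))
  dp <- NULL
  if (!is.null(dta_components)) {
    dp <- as.data.frame(dta_components)
    stopifnot(all(c("center", "sigma", "area") %in% names(dp)))
    heat <- Reduce(`+`, lapply(seq_len(nrow(dp)), function(i)
      dp$area[i] * stats::dnorm(grid, dp$center[i], dp$sigma[i])))
  }
  heat <- heat + drift[1] + drift[2] * (grid - grid[1])
  if (noise_sd > 0) {
    mass <- with_seed(seed, mass + stats::rnorm(length(grid), 0, noise_sd))
    mass <- cummin(pmin(mass, 100))  # keep physically non-increasing
    heat <- with_seed(seed + 1L,
                      heat + stats::rnorm(length(grid), 0, noise_sd))
  }
  truth <- list(
    components = cp, dta_components = dp,
    mass_loss = function(region) sum(cp$loss *
      (stats::pnorm(region[2], cp$center, cp$sigma) -
       stats::pnorm(region[1], cp$center, cp$sigma))),
    dta_area = function(region) if (is.null(dp)) 0 else sum(dp$area *
      (stats::pnorm(region[2], dp$center, dp$sigma) -
       stats::pnorm(region[1], dp$center, dp$sigma))))
  list(gram = thermogram(grid, mass, heat), truth = truth)
}

#' Synthetic thermogram for a pile scenario and composting phase
#'
#' Places the scenario's target P1 mass loss across two labile components
#' (carbohydrate-type combustion near 300 and 355 degC) and the P2 loss in
#' a recalcitrant aromatic component near 490 degC, with matching DTA
#' exotherms scaled to the scenario's target peak areas. Components are
#' tight enough (+/- 5 sigma inside each window) that the closed-form
#' region truths essentially equal the targets.
#'
#' @param scenario A `pile_scenario`.
#' @param phase `"initial"` or `"maturity"`.
#' @param ... Passed to [make_thermogram()] (`noise_sd`, `seed`, `drift`).
#' @return As [make_thermogram()].
#' @export
make_pile_thermogram <- function(scenario, phase = c("initial", "maturity"),
                                 ...) {
  phase <- match.arg(phase)
  tg <- scenario$tg_targets[[phase]]
  da <- scenario$dta_targets[[phase]]
  components <- data.frame(
    center = c(300, 355, 490),
    sigma = c(9, 8, 16),
    loss = c(0.6 * tg[["p1"]], 0.4 * tg[["p1"]], tg[["p2"]]))
  dta_components <- data.frame(
    center = c(320, 490),
    sigma = c(12, 16),
    area = c(da[["p1"]], da[["p2"]]))
  make_thermogram(components, dta_components, ...)
}

#' Synthetic FT-IR spectrum with known band heights
#'
#' Gaussian bands of width `band_sigma` at the named positions on a
#' 4000-400 cm-1 grid (2 cm-1 spacing), plus an optional linear baseline
#' and seeded ordinate noise. The truth is the exact relative-absorbance
#' profile of the generating heights.
#'
#' @param band_heights Named numeric vector: names are band positions
#'   (cm-1), values peak heights (absorbance units, >= 0).
#' @param baseline_slope Linear baseline slope, absorbance per cm-1.
#' @param baseline_intercept Baseline value at 400 cm-1.
#' @param noise_sd Gaussian ordinate noise sd (absorbance units).
#' @param seed Random seed.
#' @param band_sigma Gaussian band sd, cm-1 (default 6, i.e. ~14 cm-1
#'   FWHM, typical of sharp mid-IR bands such as the 1384 cm-1 nitrate
#'   band).
#' @return List with `spec` (a [spectrum()]) and `truth` (`heights`, `ra`,
#'   `ratio_1037_1384`).
#' @export
make_ftir_spectrum <- function(band_heights, baseline_slope = 0,
                               baseline_intercept = 0, noise_sd = 0,
                               seed = 1, band_sigma = 6) {
  stopifnot(!is.null(names(band_heights)), all(band_heights >= 0))
  pos <- as.numeric(names(band_heights))
  grid <- seq(4000, 400, by = -2)
  y <- baseline_intercept + baseline_slope * (grid - 400)
  for (i in seq_along(pos))
    y <- y + band_heights[i] * exp(-(grid - pos[i])^2 / (2 * band_sigma^2))
  if (noise_sd > 0)
    y <- with_seed(seed, y + stats::rnorm(length(grid), 0, noise_sd))
  truth <- if (length(band_heights) >= 2) relative_absorbance(band_heights)
    else list(ra = NULL, ratio_1037_1384 = NA_real_)
  list(spec = spectrum(grid, y, kind = "wavenumber_cm-1"),
       truth = list(heights = band_heights, ra = truth$ra,
                    ratio_1037_1384 = truth$ratio_1037_1384))
}

#' Synthetic CPMAS 13C NMR spectrum with known region percentages
#'
#' One Gaussian per region, centred mid-region with sd one tenth of the
#' region width, scaled so its integral matches the requested percentage
#' of the total area. Grid: -20 to 220 ppm at 0.2 ppm.
#'
#' @param region_targets Named percentages (names matching the scheme
#'   labels) summing to 100.
#' @param scheme Region scheme (see [default_nmr_regions()]).
#' @param noise_sd Gaussian ordinate noise sd, in units of the maximum
#'   noiseless intensity (e.g. 0.005 = 0.5 %).
#' @param seed Random seed.
#' @param total_area Total spectral area, arbitrary units.
#' @return List with `spec` (a [spectrum()]) and `truth`
#'   (`region_targets`).
#' @export
make_nmr_spectrum <- function(region_targets, scheme = default_nmr_regions(),
                              noise_sd = 0, seed = 1, total_area = 100) {
  scheme <- validate_region_scheme(scheme)
  if (!setequal(names(region_targets), scheme$label))
    stop("make_nmr_spectrum: targets must name every scheme region")
  if (abs(sum(region_targets) - 100) > 1e-6)
    stop("make_nmr_spectrum: region targets must sum to 100")
  grid <- seq(-20, 220, by = 0.2)
  y <- rep(0, length(grid))
  for (i in seq_len(nrow(scheme))) {
    lab <- scheme$label[i]
    width <- scheme$high_ppm[i] - scheme$low_ppm[i]
    center <- (scheme$high_ppm[i] + scheme$low_ppm[i]) / 2
    area <- total_area * region_targets[[lab]] / 100
    y <- y + area * stats::dnorm(grid, center, width / 10)
  }
  if (noise_sd > 0)
    y <- with_seed(seed, y + stats::rnorm(length(grid), 0, noise_sd * max(y)))
  list(spec = spectrum(grid, y, kind = "chemical_shift_ppm"),
       truth = list(region_targets = region_targets))
}
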
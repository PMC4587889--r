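#' Thermogram constructor
#'
#' A single TG/DTA run: sample mass (% of initial) and heat-flow signal
#' (positive = exothermic, arbitrary consistent units) on a strictly
#' increasing temperature grid spanning at least 150-600 degC with spacing
#' at most 5 degC. A mass trace supplied in absolute units (e.g. mg) is
#' auto-normalised to percent of its initial value.
#'
#' @param temperature Temperature grid, degC.
#' @param mass Sample mass, % of initial (or absolute units, normalised).
#' @param heat_flow DTA signal; defaults to zero if not recorded.
#' @return An object of class `thermogram` (a tibble).
#' @export
thermogram <- function(temperature, mass, heat_flow = NULL) {
  stopifnot(length(temperature) == length(mass))
  if (length(temperature) < 100)
    stop("thermogram: at least 100 grid points are required")
  if (any(diff(temperature) <= 0))
    stop("thermogram: temperature must be strictly increasing")
  if (max(diff(temperature)) > 5)
    stop("thermogram: temperature spacing must be <= 5 degC")
  if (min(temperature) > 150 || max(temperature) < 600)
    stop("thermogram: grid must span at least [150, 600] degC")
  if (mass[1] > 100 + 1e-9) mass <- 100 * mass / mass[1]  # absolute units
  if (any(mass <= 0) || any(mass > 100 + 1e-9))
    stop("thermogram: mass values must lie in (0, 100] % of initial")
  if (is.null(heat_flow)) heat_flow <- rep(0, length(temperature))
  stopifnot(length(heat_flow) == length(temperature))
  out <- tibble::tibble(temperature = temperature, mass = mass,
                        heat_flow = heat_flow)
  class(out) <- c("thermogram", class(out))
  out
}

#' Derivative thermogravimetry (DTG) trace
#'
#' Smoothed first derivative of the mass-loss curve, -d(mass)/dT in %/degC
#' (positive = mass loss), by local polynomial (Savitzky-Golay) filtering.
#' Endpoints are handled by window truncation within the filter. A slightly
#' non-uniform grid is resampled internally onto a uniform grid of the same
#' span and point count.
#'
#' @param gram A `thermogram`.
#' @param smooth_window Smoothing window width in degC (default 15, i.e.
#'   15 points on a 1 degC grid).
#' @param smooth_order Local polynomial order (default 2).
#' @return A tibble with columns `temperature` and `dtg`.
#' @export
compute_dtg <- function(gram, smooth_window = 15, smooth_order = 2) {
  tt <- gram$temperature
  mm <- gram$mass
  dT <- diff(tt)
  if ((max(dT) - min(dT)) / mean(dT) > 1e-8) {
    grid <- seq(tt[1], tt[length(tt)], length.out = length(tt))
    mm <- stats::approx(tt, mm, xout = grid)$y
    tt <- grid
    dT <- diff(tt)
  }
  h <- dT[1]
  n_pts <- round(smooth_window / h)
  if (n_pts < 3)
    stop("compute_dtg: smoothing window covers fewer than 3 grid points")
  if (n_pts %% 2 == 0) n_pts <- n_pts + 1
  n_pts <- max(n_pts, smooth_order + 2 + (smooth_order %% 2 == 1))
  if (n_pts %% 2 == 0) n_pts <- n_pts + 1
  deriv <- signal::sgolayfilt(mm, p = smooth_order, n = n_pts, m = 1, ts = h)
  tibble::tibble(temperature = tt, dtg = -deriv)
}

#' Detect DTG peaks within temperature windows
#'
#' Finds local maxima of a DTG trace inside each requested window whose
#' height is at least `min_prominence` times the trace maximum. Returns
#' fewer peaks than windows (with a warning) when a window holds none.
#'
#' @param dtg A tibble from [compute_dtg()] (columns `temperature`, `dtg`).
#' @param windows List of `c(t_low, t_high)` windows in degC.
#' @param min_prominence Minimum peak height as a fraction of the global
#'   trace maximum.
#' @return A tibble with columns `window`, `temperature`, `height`, sorted
#'   by temperature.
#' @export
detect_dtg_peaks <- function(dtg, windows = list(c(250, 400), c(400, 580)),
                             min_prominence = 0.05) {
  stopifnot(length(windows) >= 1)
  thr <- min_prominence * max(dtg$dtg)
  out <- list()
  for (w in seq_along(windows)) {
    win <- windows[[w]]
    sel <- dtg$temperature >= win[1] & dtg$temperature <= win[2]
    if (!any(sel))
      stop("detect_dtg_peaks: window [", win[1], ", ", win[2],
           "] does not overlap the grid")
    y <- dtg$dtg[sel]; x <- dtg$temperature[sel]
    pk <- pracma::findpeaks(y, minpeakheight = thr)
    if (is.null(pk)) {
      warning("detect_dtg_peaks: no peak found in window [", win[1], ", ",
              win[2], "]")
      next
    }
    out[[length(out) + 1]] <- tibble::tibble(
      window = w, temperature = x[pk[, 2]], height = pk[, 1])
  }
  if (length(out) == 0)
    return(tibble::tibble(window = integer(), temperature = numeric(),
                          height = numeric()))
  res <- do.call(rbind, out)
  res[order(res$temperature), ]
}

#' Mass loss over a temperature region
#'
#' Mass at `t_low` minus mass at `t_high`, with linear interpolation at the
#' region boundaries; additive over adjacent regions by construction. A
#' (noise-induced) negative loss is clamped at 0 with a warning.
#'
#' @param gram A `thermogram`.
#' @param region `c(t_low, t_high)` in degC, within the grid span.
#' @return Mass loss, % of initial sample mass.
#' @export
region_mass_loss <- function(gram, region) {
  region <- check_region(gram, region)
  m <- stats::approx(gram$temperature, gram$mass, xout = region)$y
  loss <- m[1] - m[2]
  if (loss < 0) {
    warning("region_mass_loss: negative mass loss clamped at 0")
    loss <- 0
  }
  loss
}

#' DTA peak area over a temperature region
#'
#' Trapezoidal integral of the baseline-corrected heat-flow signal over the
#' region. The default `linear_endpoints` baseline is the straight line
#' joining the signal values at the region boundaries (making the area
#' invariant to any constant or linear drift added to the signal);
#' `horizontal_min` subtracts the minimum signal within the region.
#'
#' @param gram A `thermogram`.
#' @param region `c(t_low, t_high)` in degC, within the grid span.
#' @param baseline `"linear_endpoints"` (default) or `"horizontal_min"`.
#' @return Peak area in signal x degC units.
#' @export
dta_peak_area <- function(gram, region,
                          baseline = c("linear_endpoints", "horizontal_min")) {
  baseline <- match.arg(baseline)
  region <- check_region(gram, region)
  inside <- gram$temperature > region[1] & gram$temperature < region[2]
  x <- c(region[1], gram$temperature[inside], region[2])
  y <- stats::approx(gram$temperature, gram$heat_flow, xout = x)$y
  base <- switch(baseline,
    linear_endpoints = y[1] + (y[length(y)] - y[1]) *
      (x - x[1]) / (x[length(x)] - x[1]),
    horizontal_min = rep(min(y), length(y)))
  pracma::trapz(x, y - base)
}

#' Thermal stability indices R1 and R2
#'
#' Assembles region mass losses and DTA peak areas for the two main
#' exothermic regions (P1 preceding P2) and forms the stability indices
#' R1 = P2/P1 mass loss and R2 = P2/P1 DTA peak area. Both ratios rise as
#' the labile fraction burns away and recalcitrant, aromatic organic matter
#' accumulates during composting.
#'
#' @param gram A `thermogram`.
#' @param p1,p2 Regions `c(t_low, t_high)` in degC; defaults 250-400 and
#'   400-580 (the two main exothermic DTA windows).
#' @param baseline Baseline mode passed to [dta_peak_area()].
#' @return List with `p1_mass_loss`, `p2_mass_loss`, `r1`, `p1_area`,
#'   `p2_area`, `r2`, and the regions used.
#' @export
thermal_indices <- function(gram, p1 = c(250, 400), p2 = c(400, 580),
                            baseline = "linear_endpoints") {
  if (p1[2] > p2[1] + 1e-9)
    stop("thermal_indices: p1 must precede p2")
  p1_mass <- region_mass_loss(gram, p1)
  p2_mass <- region_mass_loss(gram, p2)
  p1_area <- dta_peak_area(gram, p1, baseline)
  p2_area <- dta_peak_area(gram, p2, baseline)
  if (p1_mass <= 0) stop("thermal_indices: zero P1 mass loss; R1 undefined")
  if (p1_area <= 0) stop("thermal_indices: zero P1 DTA area; R2 undefined")
  list(p1_mass_loss = p1_mass, p2_mass_loss = p2_mass, r1 = p2_mass / p1_mass,
       p1_area = p1_area, p2_area = p2_area, r2 = p2_area / p1_area,
       p1_region = p1, p2_region = p2)
}

#' Read a thermogram from 3-column delimited text
#'
#' @param path Delimited text with columns `temperature_c`, `mass_pct` (or
#'   absolute `mass_mg`, auto-normalised) and optional `heat_flow`.
#' @return A `thermogram`.
#' @export
read_thermogram <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  masscol <- intersect(c("mass_pct", "mass_mg", "mass"), names(df))[1]
  if (!("temperature_c" %in% names(df)) || is.na(masscol))
    stop("read_thermogram: need columns temperature_c and mass_pct/mass_mg")
  hf <- if ("heat_flow" %in% names(df)) df$heat_flow else NULL
  m <- df[[masscol]]
  if (masscol == "mass_mg") m <- 100 * m / m[1]  # absolute -> % of initial
  thermogram(df$temperature_c, m, hf)
}

check_region <- function(gram, region) {
  stopifnot(length(region) == 2)
  region <- sort(as.numeric(region))
  if (region[1] < min(gram$temperature) || region[2] > max(gram$temperature))
    stop("region [", region[1], ", ", region[2], "] outside the grid span")
  region
}
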
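#' Standard seven-region chemical-shift scheme for CPMAS 13C NMR
#'
#' Contiguous, non-overlapping integration regions covering -10 to 210 ppm:
#' carbonyl (210-165), O-aromatic (165-145), aromatic (145-110), O2-alkyl
#' (110-95), O-alkyl (95-60), N-alkyl/methoxy (60-45) and alkyl
#' (45 to -10). Labels indicate the dominant carbon type in each region.
#'
#' @return A tibble with columns `label`, `high_ppm`, `low_ppm`.
#' @export
default_nmr_regions <- function() {
  tibble::tribble(
    ~label, ~high_ppm, ~low_ppm,
    "carbonyl", 210, 165,
    "o_aromatic", 165, 145,
    "aromatic", 145, 110,
    "o2_alkyl", 110, 95,
    "o_alkyl", 95, 60,
    "n_alkyl_methoxy", 60, 45,
    "alkyl", 45, -10)
}

validate_region_scheme <- function(scheme) {
  stopifnot(is.data.frame(scheme),
            all(c("label", "high_ppm", "low_ppm") %in% names(scheme)))
  if (any(scheme$high_ppm <= scheme$low_ppm))
    stop("region scheme: high_ppm must exceed low_ppm in every region")
  o <- order(-scheme$high_ppm)
  s <- scheme[o, ]
  if (any(abs(s$low_ppm[-nrow(s)] - s$high_ppm[-1]) > 1e-9))
    stop("region scheme: regions must be contiguous and non-overlapping")
  s
}

#' Integrate an NMR spectrum over chemical-shift regions
#'
#' Trapezoidal integration of signal intensity within each region of the
#' scheme (boundaries interpolated on the ppm grid), after an optional
#' constant baseline offset estimated as the median intensity over a
#' signal-free window. Negative region integrals are floored at 0 with a
#' warning, then the set is normalised to sum to 100.
#'
#' @param spec A `compost_spectrum` with a chemical-shift (ppm) axis
#'   spanning at least the scheme's range.
#' @param scheme Region scheme (see [default_nmr_regions()]).
#' @param baseline_offset `"none"` or `"median_of_signal_free_region"`.
#' @param signal_free_window `c(low, high)` ppm window used for the median
#'   offset (default 215-230 ppm); ignored when absent from the spectrum.
#' @return List with `relative` (named %, summing to 100), `raw`
#'   (uncorrected integrals) and `scheme`.
#' @export
integrate_regions <- function(spec, scheme = default_nmr_regions(),
                              baseline_offset = c("none",
                                "median_of_signal_free_region"),
                              signal_free_window = c(215, 230)) {
  baseline_offset <- match.arg(baseline_offset)
  stopifnot(inherits(spec, "compost_spectrum"),
            spec$kind == "chemical_shift_ppm")
  scheme <- validate_region_scheme(scheme)
  rng <- range(spec$axis)
  if (rng[1] > min(scheme$low_ppm) || rng[2] < max(scheme$high_ppm))
    stop("integrate_regions: spectrum does not cover the region scheme span")
  y <- spec$intensity
  if (baseline_offset == "median_of_signal_free_region") {
    sel <- spec$axis >= signal_free_window[1] &
      spec$axis <= signal_free_window[2]
    if (sum(sel) >= 3) y <- y - stats::median(y[sel])
  }
  x_asc <- rev(spec$axis)   # ascending for integration
  y_asc <- rev(y)
  one <- function(lo, hi) {
    inside <- x_asc > lo & x_asc < hi
    xs <- c(lo, x_asc[inside], hi)
    ys <- stats::approx(x_asc, y_asc, xout = xs)$y
    pracma::trapz(xs, ys)
  }
  raw <- mapply(one, scheme$low_ppm, scheme$high_ppm)
  names(raw) <- scheme$label
  vals <- raw
  if (any(vals < 0)) {
    warning("integrate_regions: negative region integral floored at 0")
    vals <- pmax(vals, 0)
  }
  if (sum(vals) <= 0) stop("integrate_regions: no positive signal")
  list(relative = 100 * vals / sum(vals), raw = raw, scheme = scheme)
}

#' Alkyl / O-Alkyl ratio
#'
#' Ratio of the alkyl (45 to -10 ppm) to O-alkyl (95-60 ppm) relative
#' intensities: a recalcitrant-vs-labile carbon indicator that rises as
#' carbohydrates are preferentially degraded during composting.
#'
#' @param integrals Result of [integrate_regions()], or a named numeric
#'   vector holding `alkyl` and `o_alkyl` percentages.
#' @return Dimensionless ratio.
#' @export
alkyl_oalkyl_ratio <- function(integrals) {
  v <- if (is.list(integrals) && !is.null(integrals$relative))
    integrals$relative else integrals
  if (!all(c("alkyl", "o_alkyl") %in% names(v)))
    stop("alkyl_oalkyl_ratio: need 'alkyl' and 'o_alkyl' entries")
  if (v[["o_alkyl"]] <= 0) stop("alkyl_oalkyl_ratio: zero O-alkyl intensity")
  v[["alkyl"]] / v[["o_alkyl"]]
}

#' Spin-counting observability (Cobs)
#'
#' Fraction of the potential 13C NMR signal actually observed, referenced
#' to an external intensity standard (conventionally glycine): the sample's
#' total integral per mg carbon per scan divided by the standard's, times
#' 100. Cross-polarisation is non-quantitative; values around 60-66 % are
#' typical for compost samples. A warning is raised outside 40-110 %.
#'
#' @param sample_intensity,standard_intensity Total spectral integrals.
#' @param sample_mass_c,standard_mass_c Carbon masses in the rotor, mg.
#' @param sample_scans,standard_scans Number of accumulated scans.
#' @return List with `cobs` (%), `sample_signal_per_mg_c`,
#'   `standard_signal_per_mg_c`.
#' @export
spin_count <- function(sample_intensity, sample_mass_c, sample_scans,
                       standard_intensity, standard_mass_c, standard_scans) {
  vals <- c(sample_intensity, sample_mass_c, sample_scans,
            standard_intensity, standard_mass_c, standard_scans)
  if (any(vals <= 0)) stop("spin_count: all inputs must be positive")
  s <- sample_intensity / (sample_mass_c * sample_scans)
  r <- standard_intensity / (standard_mass_c * standard_scans)
  cobs <- 100 * s / r
  if (cobs < 40 || cobs > 110)
    warning("spin_count: Cobs = ", round(cobs, 1),
            " % outside the plausible 40-110 % range")
  list(cobs = cobs, sample_signal_per_mg_c = s, standard_signal_per_mg_c = r)
}
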
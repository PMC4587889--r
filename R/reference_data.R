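#' Worked-example chemical data: winery-distillery waste co-composting
#'
#' Reference measurements from a co-composting study of winery-distillery
#' wastes (grape marc, exhausted grape marc) with animal manures, three
#' piles (A, B, C) sampled at four phases: initial (I, day 0), thermophilic
#' (T, day 28), end of the bio-oxidative phase (E, day 105) and maturity
#' (M, day 168). Columns hold the measured inputs (TOC/TN, WSC, WSC/TN,
#' Cfa, Cha, all % dry matter or dimensionless ratios) and the published
#' derived indices (HR, HI, Pha, Cha/Cfa) for cross-checking.
#'
#' The pile C initial row's published derived columns (HR, Pha, Cha/Cfa)
#' are inconsistent with its own Cfa/Cha inputs (they duplicate the pile B
#' initial row); `roundtrip_ok` marks rows whose derived columns are
#' reproducible from the printed inputs.
#'
#' @return A tibble with one row per pile x phase.
#' @export
winery_compost_chemical <- function() {
  tb <- tibble::tribble(
    ~pile_id, ~phase, ~day, ~toc_tn, ~wsc, ~wsc_tn, ~cfa, ~cha, ~hr, ~hi, ~pha, ~cha_cfa,
    "A", "initial", 0L, 21.9, 3.14, 1.42, 3.54, 2.98, 12.99, 5.94, 45.72, 0.84,
    "A", "thermophilic", 28L, 18.4, 2.80, 1.10, 3.14, 3.02, 12.89, 6.32, 49.01, 0.96,
    "A", "end_bio_oxidative", 105L, 17.9, 2.70, 1.05, 2.77, 1.60, 9.33, 3.41, 36.58, 0.58,
    "A", "maturity", 168L, 17.4, 1.10, 0.42, 1.24, 1.16, 5.23, 2.52, 48.15, 0.93,
    "B", "initial", 0L, 21.1, 4.27, 1.82, 3.86, 4.59, 17.24, 9.20, 54.46, 1.20,
    "B", "thermophilic", 28L, 19.2, 3.72, 1.54, 4.08, 4.61, 18.04, 9.57, 53.06, 1.13,
    "B", "end_bio_oxidative", 105L, 17.6, 3.51, 1.35, 3.13, 4.00, 15.43, 8.65, 56.06, 1.28,
    "B", "maturity", 168L, 17.1, 1.86, 0.69, 2.91, 1.43, 9.44, 3.11, 32.97, 0.49,
    "C", "initial", 0L, 14.8, 3.29, 1.15, 3.53, 2.69, 17.24, 5.96, 54.46, 1.20,
    "C", "thermophilic", 28L, 12.7, 2.84, 1.05, 2.95, 3.35, 13.87, 7.37, 53.14, 1.13,
    "C", "end_bio_oxidative", 105L, 13.9, 2.68, 0.85, 3.05, 1.84, 11.09, 4.18, 37.66, 0.60,
    "C", "maturity", 168L, 13.5, 0.98, 0.31, 1.43, 0.81, 5.34, 1.93, 36.20, 0.57)
  tb$roundtrip_ok <- !(tb$pile_id == "C" & tb$phase == "initial")
  tb
}

#' Published first-order kinetic parameters for the three composting piles
#'
#' Fitted parameters of the organic-matter degradation model
#' OM loss (%) = A * (1 - exp(-k * t)) for piles A, B, C, with the reported
#' fit statistics (F, SEE; the published "RMS" column resembles a
#' normalised statistic rather than SEE squared and is retained verbatim
#' as `rms_printed`).
#'
#' @return A tibble with columns `pile_id`, `a_max`, `a_sd`, `k_rate`,
#'   `k_sd`, `rms_printed`, `f_value`, `see`.
#' @export
winery_compost_kinetics <- function() {
  tibble::tribble(
    ~pile_id, ~a_max, ~a_sd, ~k_rate, ~k_sd, ~rms_printed, ~f_value, ~see,
    "A", 49.6, 8.1, 0.0131, 0.0040, 0.878, 65.8, 4.89,
    "B", 44.2, 6.7, 0.0215, 0.0072, 0.769, 31.0, 6.45,
    "C", 50.4, 9.1, 0.0091, 0.0030, 0.880, 95.8, 5.99)
}

#' Published thermal stability indices (TG mass losses and DTA peak areas)
#'
#' Mass losses (%) in the two main exothermic regions of the TG curve
#' (P1, P2) and the DTA peak areas for the initial (I) and maturity (M)
#' samples of each pile, together with the published R1 = P2/P1 (mass) and
#' R2 = P2/P1 (area) indices.
#'
#' @return A tibble with one row per pile x phase.
#' @export
winery_compost_thermal <- function() {
  tibble::tribble(
    ~pile_id, ~phase, ~p1_mass, ~p2_mass, ~r1, ~p1_area, ~p2_area, ~r2,
    "A", "initial", 51.9, 19.8, 0.38, 572, 76, 0.13,
    "A", "maturity", 42.2, 26.7, 0.63, 576, 902, 1.57,
    "B", "initial", 57.6, 22.3, 0.39, 752, 137, 0.18,
    "B", "maturity", 39.9, 27.8, 0.70, 891, 1425, 1.60,
    "C", "initial", 49.6, 18.0, 0.36, 804, 114, 0.14,
    "C", "maturity", 36.0, 22.5, 0.62, 699, 696, 1.00)
}

#' Published FT-IR relative absorbance profiles
#'
#' Relative absorbance (% of the sum of the eight measured band heights) at
#' the standard band set (2927, 2854, 1640, 1548, 1420, 1384, 1037,
#' 875 cm-1) for each pile and phase, plus the published 1037/1384 ratio.
#'
#' @return A tibble; band columns named `ra_<wavenumber>`.
#' @export
winery_compost_ftir <- function() {
  tibble::tribble(
    ~pile_id, ~phase, ~day, ~ra_2927, ~ra_2854, ~ra_1640, ~ra_1548, ~ra_1420, ~ra_1384, ~ra_1037, ~ra_875, ~ratio_1037_1384,
    "A", "initial", 0L, 10.4, 12.9, 9.9, 12.6, 10.7, 12.5, 11.4, 19.6, 0.91,
    "A", "thermophilic", 28L, 12.7, 15.5, 8.8, 11.3, 11.5, 12.0, 9.8, 18.5, 0.81,
    "A", "end_bio_oxidative", 105L, 13.2, 16.3, 8.5, 10.5, 11.0, 11.4, 10.2, 19.0, 0.89,
    "A", "maturity", 168L, 13.8, 16.3, 8.9, 10.2, 10.8, 11.3, 10.4, 18.2, 0.92,
    "B", "initial", 0L, 11.8, 14.7, 9.3, 12.0, 11.9, 12.2, 10.0, 18.2, 0.82,
    "B", "thermophilic", 28L, 12.4, 15.2, 9.2, 11.5, 11.6, 12.0, 10.3, 17.9, 0.86,
    "B", "end_bio_oxidative", 105L, 12.4, 14.7, 10.1, 11.5, 11.8, 11.9, 10.7, 17.1, 0.89,
    "B", "maturity", 168L, 11.9, 15.2, 9.5, 10.2, 10.7, 11.8, 11.3, 19.3, 0.96,
    "C", "initial", 0L, 13.6, 16.7, 9.2, 12.3, 9.1, 10.9, 10.8, 17.5, 0.99,
    "C", "thermophilic", 28L, 13.4, 15.7, 10.1, 12.3, 9.9, 11.1, 11.3, 16.2, 1.02,
    "C", "end_bio_oxidative", 105L, 13.6, 15.9, 10.5, 12.1, 9.5, 10.6, 11.2, 16.6, 1.06,
    "C", "maturity", 168L, 14.9, 17.6, 10.0, 10.6, 8.5, 10.0, 10.8, 17.5, 1.08)
}

#' Published CPMAS 13C NMR spectral distributions
#'
#' Relative intensity (%) of each carbon type by integration over the seven
#' standard chemical-shift regions -- alkyl (45 to -10 ppm),
#' N-alkyl/methoxy (60-45), O-alkyl (95-60), O2-alkyl (110-95), aromatic
#' (145-110), O-aromatic (165-145), carbonyl (210-165) -- with the
#' published Alkyl/O-Alkyl ratio.
#'
#' @return A tibble; region columns named by carbon type.
#' @export
winery_compost_nmr <- function() {
  tibble::tribble(
    ~pile_id, ~phase, ~day, ~alkyl, ~n_alkyl_methoxy, ~o_alkyl, ~o2_alkyl, ~aromatic, ~o_aromatic, ~carbonyl, ~alkyl_oalkyl,
    "A", "initial", 0L, 30.7, 17.0, 31.7, 7.8, 3.3, 3.5, 6.1, 0.97,
    "A", "thermophilic", 28L, 36.4, 15.9, 23.2, 8.0, 5.7, 3.7, 7.3, 1.60,
    "A", "end_bio_oxidative", 105L, 37.9, 16.1, 21.2, 7.7, 6.3, 3.9, 6.9, 1.79,
    "A", "maturity", 168L, 37.3, 14.3, 15.5, 6.9, 7.1, 4.8, 14.2, 2.40,
    "B", "initial", 0L, 33.6, 15.3, 28.6, 8.5, 2.9, 3.7, 7.4, 1.18,
    "B", "thermophilic", 28L, 34.3, 13.7, 28.1, 9.2, 3.6, 3.6, 7.5, 1.22,
    "B", "end_bio_oxidative", 105L, 33.3, 14.8, 29.1, 9.5, 3.8, 3.0, 6.6, 1.14,
    "B", "maturity", 168L, 34.9, 15.2, 25.9, 8.5, 3.3, 4.0, 8.2, 1.35,
    "C", "initial", 0L, 30.8, 14.2, 30.5, 10.5, 3.5, 3.5, 7.0, 1.01,
    "C", "thermophilic", 28L, 34.4, 14.6, 26.9, 8.5, 3.2, 4.0, 8.5, 1.28,
    "C", "end_bio_oxidative", 105L, 33.9, 15.5, 26.8, 8.9, 3.7, 3.9, 7.5, 1.27,
    "C", "maturity", 168L, 34.3, 15.5, 23.6, 7.9, 3.4, 5.0, 10.2, 1.45)
}
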
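#' Default FT-IR band set for compost maturity work
#'
#' Eight diagnostic mid-infrared bands: 2927 and 2854 cm-1 (aliphatic C-H,
#' fats/waxes/cutin), 1640 (aromatic C=C / amide I), 1548 (amide II,
#' lignin-related), 1420 (carboxylate / aliphatic CH2), 1384 (nitrate),
#' 1037 (polysaccharide C-O), 875 (carbonate) cm-1.
#'
#' @return Numeric vector of nominal band positions, cm-1.
#' @export
default_ftir_bands <- function() {
  c(2927, 2854, 1640, 1548, 1420, 1384, 1037, 875)
}

#' Default FT-IR band definitions with baseline anchors
#'
#' Per-band search windows and baseline anchor positions for the standard
#' band set. Anchors default to nominal +/- 30 cm-1 except for the
#' overlapping 1420/1384 cm-1 doublet, whose inner anchors share the
#' inter-band valley at 1402 cm-1 (a +/- 30 anchor would sit on the
#' neighbouring band's flank and over-subtract the baseline).
#'
#' @return A tibble with columns `nominal`, `search_halfwidth`,
#'   `anchor_low`, `anchor_high` (cm-1).
#' @export
ftir_band_table <- function() {
  nominal <- default_ftir_bands()
  tb <- tibble::tibble(nominal = nominal, search_halfwidth = 10,
                       anchor_low = nominal - 30, anchor_high = nominal + 30)
  tb$anchor_low[tb$nominal == 1420] <- 1402
  tb$anchor_high[tb$nominal == 1384] <- 1402
  tb
}

#' Baseline-corrected FT-IR band height
#'
#' The band height is the maximum intensity within
#' `nominal +/- search_halfwidth` minus a local linear baseline through two
#' anchor points, evaluated at the peak position. By default the anchors
#' sit at the fixed positions `nominal +/- anchor_offset` (intensity read
#' by linear interpolation), which makes the height exactly invariant to
#' adding any linear function of wavenumber. With `snap_to_valley = TRUE`
#' each anchor moves to the deepest interior local minimum within
#' `valley_halfwidth` of its nominal position, when one exists.
#'
#' @param spec A `compost_spectrum` with a wavenumber axis.
#' @param nominal Nominal band position, cm-1.
#' @param search_halfwidth Half-width of the peak search window, cm-1.
#' @param anchor_offset Distance of the two baseline anchors from
#'   `nominal`, cm-1; alternatively supply explicit `anchors`.
#' @param anchors Optional explicit anchor positions `c(low, high)`, cm-1.
#' @param snap_to_valley Move anchors to nearby local minima?
#' @param valley_halfwidth Search half-width for valley snapping, cm-1.
#' @return Corrected height (absorbance units); negative heights are
#'   clamped at 0 with a warning.
#' @export
band_height <- function(spec, nominal, search_halfwidth = 10,
                        anchor_offset = 30, anchors = NULL,
                        snap_to_valley = FALSE, valley_halfwidth = 8) {
  stopifnot(inherits(spec, "compost_spectrum"),
            spec$kind == "wavenumber_cm-1", search_halfwidth > 0)
  rng <- range(spec$axis)
  if (nominal - search_halfwidth < rng[1] || nominal + search_halfwidth > rng[2])
    stop("band_height: search window for ", nominal,
         " cm-1 outside the spectrum")
  if (is.null(anchors)) anchors <- c(nominal - anchor_offset,
                                     nominal + anchor_offset)
  anchors <- sort(anchors)
  if (anchors[1] < rng[1] || anchors[2] > rng[2])
    stop("band_height: baseline anchors for ", nominal,
         " cm-1 outside the spectrum")
  if (snap_to_valley) anchors <- vapply(anchors, snap_anchor, numeric(1),
                                        spec = spec, hw = valley_halfwidth)
  sel <- spec$axis >= nominal - search_halfwidth &
    spec$axis <= nominal + search_halfwidth
  i_pk <- which(sel)[which.max(spec$intensity[sel])]
  x_pk <- spec$axis[i_pk]
  y_pk <- spec$intensity[i_pk]
  ya <- spectrum_at(spec, anchors)
  base_at_pk <- ya[1] + (ya[2] - ya[1]) * (x_pk - anchors[1]) /
    (anchors[2] - anchors[1])
  h <- y_pk - base_at_pk
  if (h < 0) {
    warning("band_height: negative corrected height at ", nominal,
            " cm-1 clamped at 0")
    h <- 0
  }
  h
}

snap_anchor <- function(a, spec, hw) {
  sel <- which(spec$axis >= a - hw & spec$axis <= a + hw)
  if (length(sel) < 3) return(a)
  y <- spec$intensity[sel]
  interior <- which(diff(sign(diff(y))) > 0) + 1  # strict local minima
  if (!length(interior)) return(a)
  spec$axis[sel][interior[which.min(y[interior])]]
}

#' Relative absorbance profile from band heights
#'
#' The relative absorbance of a band is its corrected height times 100
#' divided by the sum of all compared band heights; the profile therefore
#' sums to 100 and is invariant to global intensity scaling. When the 1037
#' and 1384 cm-1 bands are both present their rA ratio (a C/N-linked
#' stability indicator) is attached.
#'
#' @param heights Named numeric vector of corrected band heights; names are
#'   band positions in cm-1.
#' @return List with `ra` (named rA vector, %) and `ratio_1037_1384`
#'   (`NA` when either band is absent).
#' @export
relative_absorbance <- function(heights) {
  stopifnot(is.numeric(heights), length(heights) >= 2,
            !is.null(names(heights)))
  if (any(heights < 0)) stop("relative_absorbance: negative height")
  s <- sum(heights)
  if (s <= 0) stop("relative_absorbance: all band heights are zero")
  ra <- 100 * heights / s
  ratio <- if (all(c("1037", "1384") %in% names(ra)))
    unname(ra["1037"] / ra["1384"]) else NA_real_
  list(ra = ra, ratio_1037_1384 = ratio)
}

#' Relative absorbance profile of an FT-IR spectrum
#'
#' Measures the corrected height of every band in `bands` with
#' [band_height()] and normalises them with [relative_absorbance()].
#' Unresolvable bands are collected and reported in a single error.
#'
#' @param spec A `compost_spectrum` with a wavenumber axis.
#' @param bands Either a numeric vector of nominal positions (cm-1;
#'   anchors default to nominal +/- 30) or a band table like
#'   [ftir_band_table()] with per-band anchors.
#' @param ... Passed to [band_height()] (e.g. `snap_to_valley`).
#' @return As [relative_absorbance()], plus `heights`.
#' @export
ftir_profile <- function(spec, bands = ftir_band_table(), ...) {
  if (is.numeric(bands))
    bands <- tibble::tibble(nominal = bands, search_halfwidth = 10,
                            anchor_low = bands - 30, anchor_high = bands + 30)
  res <- lapply(seq_len(nrow(bands)), function(i) tryCatch(
    band_height(spec, bands$nominal[i],
                search_halfwidth = bands$search_halfwidth[i],
                anchors = c(bands$anchor_low[i], bands$anchor_high[i]), ...),
    error = function(e) e))
  bad <- vapply(res, inherits, TRUE, "error")
  if (any(bad))
    stop("ftir_profile: unresolvable bands: ",
         paste0(bands$nominal[bad], " cm-1 (",
                vapply(res[bad], conditionMessage, ""),
                ")", collapse = "; "))
  heights <- stats::setNames(unlist(res), bands$nominal)
  out <- relative_absorbance(heights)
  out$heights <- heights
  out
}
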
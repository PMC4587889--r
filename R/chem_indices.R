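#' Humification ratio (HR)
#'
#' The humification ratio expresses the alkali-extractable organic carbon as
#' a percentage of total organic carbon: HR = 100 * Cext / CT. Rising values
#' traditionally indicate progressive humification, although co-extraction of
#' non-humified compounds (e.g. polyphenols in winery wastes) can mask the
#' trend.
#'
#' @param cext Extractable organic carbon, % dry matter.
#' @param ct Total organic carbon, % dry matter; must be positive.
#' @return HR in percent.
#' @examples
#' humification_ratio(6.52, 50.19)
#' @export
humification_ratio <- function(cext, ct) {
  check_fraction_of_total(cext, ct, "cext")
  100 * cext / ct
}

#' Humification index (HI)
#'
#' HI = 100 * Cha / CT: the humic acid-like carbon fraction of total organic
#' carbon, in percent.
#'
#' @param cha Humic acid-like carbon, % dry matter.
#' @param ct Total organic carbon, % dry matter; must be positive.
#' @return HI in percent.
#' @export
humification_index <- function(cha, ct) {
  check_fraction_of_total(cha, ct, "cha")
  100 * cha / ct
}

#' Percentage of humic acids (Pha)
#'
#' Pha = 100 * Cha / Cext: the share of the extractable carbon that
#' precipitates as humic acid-like carbon at acid pH.
#'
#' @param cha Humic acid-like carbon, % dry matter.
#' @param cext Extractable organic carbon, % dry matter; must be positive.
#' @return Pha in percent.
#' @export
percentage_humic_acids <- function(cha, cext) {
  check_fraction_of_total(cha, cext, "cha", total_name = "cext")
  100 * cha / cext
}

#' Polymerisation rate (Cha/Cfa)
#'
#' Ratio of humic acid-like to fulvic acid-like carbon. Values above 1 point
#' to a humic-dominated extractable fraction.
#'
#' @param cha Humic acid-like carbon, % dry matter (>= 0).
#' @param cfa Fulvic acid-like carbon, % dry matter; must be positive.
#' @return Dimensionless ratio.
#' @export
polymerisation_rate <- function(cha, cfa) {
  stopifnot(is.numeric(cha), is.numeric(cfa))
  if (any(cfa <= 0)) stop("polymerisation_rate: cfa must be positive")
  if (any(cha < 0)) stop("polymerisation_rate: cha must be non-negative")
  cha / cfa
}

#' Organic-matter loss from the ash balance
#'
#' Given initial (`x1`) and final (`x2`) ash contents (% dry matter), the
#' fraction of organic matter mineralised is
#' OM loss (%) = 100 - 100 * (x1 * (100 - x2)) / (x2 * (100 - x1)).
#' Ash is conserved during composting, so ash enrichment (x2 > x1) measures
#' OM disappearance. A negative result (x2 < x1) signals a mass-balance
#' anomaly and is returned with a warning rather than an error: early-phase
#' field data can be noisy.
#'
#' @param x1 Initial ash content, % dry matter, in (0, 100).
#' @param x2 Final ash content, % dry matter, in (0, 100).
#' @return OM loss in percent (0 when x1 == x2).
#' @examples
#' om_loss(20, 40) # 62.5
#' @export
om_loss <- function(x1, x2) {
  stopifnot(is.numeric(x1), is.numeric(x2))
  if (any(x1 <= 0 | x1 >= 100)) stop("om_loss: x1 must lie in (0, 100)")
  if (any(x2 <= 0 | x2 >= 100)) stop("om_loss: x2 must lie in (0, 100)")
  loss <- 100 - 100 * (x1 * (100 - x2)) / (x2 * (100 - x1))
  if (any(loss < 0)) {
    warning("om_loss: negative OM loss (final ash below initial); ",
            "mass-balance anomaly")
  }
  loss
}

#' Elemental ratio (e.g. TOC/TN, WSC/TN)
#'
#' @param numerator,denominator Percent dry-matter measurements; the
#'   denominator must be positive.
#' @return Dimensionless ratio.
#' @export
elemental_ratio <- function(numerator, denominator) {
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(denominator <= 0)) stop("elemental_ratio: denominator must be positive")
  numerator / denominator
}

#' Percent decrease relative to an initial value
#'
#' @param initial Initial value; must be positive.
#' @param final Final value.
#' @return 100 * (initial - final) / initial (unrounded).
#' @export
percent_decrease <- function(initial, final) {
  stopifnot(is.numeric(initial), is.numeric(final))
  if (any(initial <= 0)) stop("percent_decrease: initial must be positive")
  100 * (initial - final) / initial
}

#' Maturity/phytotoxicity flags for a compost sample
#'
#' Applies the conventional end-product thresholds: TOC/TN below 20,
#' water-soluble carbon at or below 1.7 % (the WSC bound is inclusive), and
#' germination index above 50 % (absence of phytotoxicity). A flag whose
#' input is missing is `NA` ("undetermined"), never silently `FALSE`.
#'
#' @param toc_tn TOC/TN ratio, or `NA`.
#' @param wsc Water-soluble carbon, % dry matter, or `NA`.
#' @param gi Germination index, %, or `NA`.
#' @param thresholds Named list with elements `toc_tn` (default 20),
#'   `wsc` (default 1.7) and `gi` (default 50).
#' @return Named logical vector `c(tocn_mature, wsc_mature, gi_nonphytotoxic)`
#'   with `NA` for undetermined flags.
#' @export
maturity_flags <- function(toc_tn = NA_real_, wsc = NA_real_, gi = NA_real_,
                           thresholds = list(toc_tn = 20, wsc = 1.7, gi = 50)) {
  flag <- function(x, test) if (is.na(x)) NA else test(x)
  c(tocn_mature = flag(toc_tn, function(x) x < thresholds$toc_tn),
    wsc_mature = flag(wsc, function(x) x <= thresholds$wsc),
    gi_nonphytotoxic = flag(gi, function(x) x > thresholds$gi))
}

#' Assemble a humic fraction set
#'
#' When `cext` is not measured it is defined as `cfa + cha` (the two acid
#' fractions exhaust the extract). When supplied, it is checked for
#' consistency with `cfa + cha` to `tolerance`.
#'
#' @param cfa,cha Fulvic and humic acid-like carbon, % dry matter.
#' @param cext Optional extractable organic carbon, % dry matter.
#' @param tolerance Absolute tolerance for `|cext - (cfa + cha)|`.
#' @return List with elements `cext`, `cfa`, `cha`.
#' @export
humic_fractions <- function(cfa, cha, cext = NULL, tolerance = 0.05) {
  stopifnot(cfa >= 0, cha >= 0)
  if (is.null(cext)) {
    cext <- cfa + cha
  } else {
    if (cext < cha || cext < cfa)
      stop("humic_fractions: cext must be >= each acid fraction")
    if (abs(cext - (cfa + cha)) > tolerance)
      stop("humic_fractions: cext inconsistent with cfa + cha beyond tolerance")
  }
  list(cext = cext, cfa = cfa, cha = cha)
}

#' Derived chemical indices for a table of compost samples
#'
#' Computes per-row humification and maturity quantities from a sample table
#' with columns `pile_id`, `phase`, `day`, and any of `toc`, `tn`, `wsc`,
#' `cfa`, `cha`, `cext`, `gi`. `cext` defaults to `cfa + cha` where absent.
#' HR and HI additionally require `toc` (total organic carbon as `ct`).
#'
#' @param samples Data frame of compost samples, one row per sample.
#' @return A tibble with the input identifiers plus `toc_tn`, `wsc_tn`,
#'   `cext`, `hr`, `hi`, `pha`, `cha_cfa` and the three maturity flags
#'   (computed where inputs allow, `NA` otherwise).
#' @export
chem_index_table <- function(samples) {
  stopifnot(is.data.frame(samples))
  need <- c("pile_id", "phase", "day")
  if (!all(need %in% names(samples)))
    stop("chem_index_table: samples must have columns ",
         paste(need, collapse = ", "))
  col <- function(nm) if (nm %in% names(samples)) samples[[nm]] else
    rep(NA_real_, nrow(samples))
  toc <- col("toc"); tn <- col("tn"); wsc <- col("wsc")
  cfa <- col("cfa"); cha <- col("cha"); gi <- col("gi")
  cext <- col("cext")
  cext <- ifelse(is.na(cext), cfa + cha, cext)
  safe <- function(f, a, b) ifelse(is.na(a) | is.na(b), NA_real_,
                                   mapply(function(x, y) f(x, y), a, b))
  toc_tn <- safe(elemental_ratio, toc, tn)
  out <- tibble::tibble(
    pile_id = samples$pile_id, phase = samples$phase, day = samples$day,
    toc_tn = toc_tn,
    wsc = wsc,
    wsc_tn = safe(elemental_ratio, wsc, tn),
    cfa = cfa, cha = cha, cext = cext,
    hr = safe(humification_ratio, cext, toc),
    hi = safe(humification_index, cha, toc),
    pha = safe(percentage_humic_acids, cha, cext),
    cha_cfa = safe(polymerisation_rate, cha, cfa))
  flags <- t(mapply(function(r, w, g) maturity_flags(r, w, g),
                    toc_tn, wsc, gi))
  out$tocn_mature <- flags[, "tocn_mature"]
  out$wsc_mature <- flags[, "wsc_mature"]
  out$gi_nonphytotoxic <- flags[, "gi_nonphytotoxic"]
  out
}

#' Read a compost sample table from delimited text
#'
#' One row per sample; column names match the field names used by
#' [chem_index_table()]. The delimiter is sniffed from the header line
#' (comma or tab).
#'
#' @param path Path to a CSV or TSV file.
#' @return A tibble.
#' @export
read_compost_samples <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                      stringsAsFactors = FALSE))
}

# shared precondition: 0 <= part <= total, total > 0
check_fraction_of_total <- function(part, total, part_name,
                                    total_name = "ct") {
  stopifnot(is.numeric(part), is.numeric(total))
  if (any(total <= 0))
    stop("domain error: ", total_name, " must be positive")
  if (any(part < 0))
    stop("domain error: ", part_name, " must be non-negative")
  if (any(part > total))
    stop("domain error: ", part_name, " exceeds ", total_name)
  invisible(TRUE)
}
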
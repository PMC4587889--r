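#' Spectrum constructor
#'
#' A one-dimensional spectroscopic trace: abscissa (wavenumber in cm-1 for
#' FT-IR or chemical shift in ppm for NMR) and ordinate intensity. The axis
#' may be supplied ascending or descending and is normalised internally to
#' descending, the plotting convention of both techniques.
#'
#' @param axis Abscissa values, strictly monotone.
#' @param intensity Ordinate values, same length.
#' @param kind `"wavenumber_cm-1"` or `"chemical_shift_ppm"`.
#' @param label Optional sample label.
#' @return An object of class `compost_spectrum`.
#' @export
spectrum <- function(axis, intensity,
                     kind = c("wavenumber_cm-1", "chemical_shift_ppm"),
                     label = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(axis) == length(intensity))
  d <- diff(axis)
  if (any(d == 0) || !(all(d > 0) || all(d < 0)))
    stop("spectrum: axis must be strictly monotone")
  if (all(d > 0)) {  # normalise to descending
    axis <- rev(axis); intensity <- rev(intensity)
  }
  structure(list(axis = axis, intensity = intensity, kind = kind,
                 label = label),
            class = "compost_spectrum")
}

#' @export
print.compost_spectrum <- function(x, ...) {
  cat("<compost_spectrum>", x$kind,
      sprintf("[%g .. %g], %d points", x$axis[1], x$axis[length(x$axis)],
              length(x$axis)),
      if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  invisible(x)
}

#' Read a spectrum from JCAMP-DX or two-column delimited text
#'
#' JCAMP-DX files (detected by a leading `##TITLE=` record) are parsed in
#' their AFFN forms: `##XYDATA=(X++(Y..Y))` with XFACTOR/YFACTOR scaling,
#' and `##XYPOINTS=`/`##PEAK TABLE=` (XY..XY) pairs. Compressed ordinate
#' forms (SQZ/DIF/DUP/PAC ASCII squeezing) are rejected with a clear
#' message. Anything else is treated as two-column delimited text
#' (whitespace, comma or tab separated; `#` comments ignored).
#'
#' @param path Input file.
#' @param kind Axis kind; defaults to `"wavenumber_cm-1"` unless the JCAMP
#'   `##XUNITS=` record says otherwise.
#' @param label Optional sample label (JCAMP `##TITLE=` wins if present).
#' @return A `compost_spectrum`.
#' @export
read_spectrum <- function(path, kind = NULL, label = NULL) {
  lines <- readLines(path, warn = FALSE)
  first <- if (length(lines)) trimws(lines[1]) else ""
  if (grepl("^##TITLE=", first, ignore.case = TRUE)) {
    return(read_jcamp(lines, kind = kind, label = label))
  }
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,\t ]+")
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad))
    stop("read_spectrum: line ", bad[1], " is not two-column data")
  x <- as.numeric(vapply(parts, `[`, "", 1))
  y <- as.numeric(vapply(parts, `[`, "", 2))
  if (anyNA(x) || anyNA(y))
    stop("read_spectrum: non-numeric value at line ",
         which(is.na(x) | is.na(y))[1])
  if (is.null(kind)) kind <- "wavenumber_cm-1"
  spectrum(x, y, kind = kind, label = label)
}

read_jcamp <- function(lines, kind = NULL, label = NULL) {
  get_field <- function(name) {
    hit <- grep(paste0("^##", name, "="), lines, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1]))
  }
  title <- get_field("TITLE")
  if (!is.null(title) && is.null(label)) label <- title
  xunits <- get_field("XUNITS")
  if (is.null(kind)) {
    kind <- if (!is.null(xunits) && grepl("ppm", xunits, ignore.case = TRUE))
      "chemical_shift_ppm" else "wavenumber_cm-1"
  }
  xfac <- as.numeric(get_field("XFACTOR") %||% "1")
  yfac <- as.numeric(get_field("YFACTOR") %||% "1")
  start_xy <- grep("^##(XYPOINTS|PEAK TABLE)=", lines, ignore.case = TRUE)
  start_xyd <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  end_rec <- function(from) {
    nxt <- grep("^##", lines)
    nxt <- nxt[nxt > from]
    if (length(nxt)) nxt[1] - 1 else length(lines)
  }
  if (length(start_xyd)) {
    body <- lines[(start_xyd[1] + 1):end_rec(start_xyd[1])]
    if (any(grepl("[A-DF-Za-df-z%@?]", body)))
      stop("read_spectrum: compressed JCAMP ordinate forms (SQZ/DIF/DUP) ",
           "are not supported; export the file in AFFN (X++(Y..Y)) form")
    xs <- list(); ys <- list()
    for (ln in body) {
      vals <- as.numeric(strsplit(trimws(ln), "[ \t,;]+")[[1]])
      if (anyNA(vals) || length(vals) < 2)
        stop("read_spectrum: malformed JCAMP data line: ", ln)
      nv <- length(vals) - 1
      x0 <- vals[1] * xfac
      xs[[length(xs) + 1]] <- x0  # per-line start; step filled in below
      ys[[length(ys) + 1]] <- vals[-1] * yfac
    }
    ny <- vapply(ys, length, 1L)
    x0s <- unlist(xs)
    # reconstruct X per line from consecutive line starts (uniform step)
    lastx <- as.numeric(get_field("LASTX") %||% NA)
    step <- if (length(x0s) > 1) (x0s[2] - x0s[1]) / ny[1] else
      (lastx - x0s[1]) / max(ny[1] - 1, 1)
    x <- unlist(mapply(function(x0, n) x0 + step * (seq_len(n) - 1),
                       x0s, ny, SIMPLIFY = FALSE))
    return(spectrum(x, unlist(ys), kind = kind, label = label))
  }
  if (length(start_xy)) {
    body <- lines[(start_xy[1] + 1):end_rec(start_xy[1])]
    pairs <- unlist(strsplit(trimws(body), ";"))
    pairs <- pairs[nzchar(trimws(pairs))]
    mat <- t(vapply(strsplit(trimws(pairs), "[, \t]+"),
                    function(p) as.numeric(p[1:2]), numeric(2)))
    if (anyNA(mat)) stop("read_spectrum: malformed JCAMP XY pair")
    return(spectrum(mat[, 1] * xfac, mat[, 2] * yfac, kind = kind,
                    label = label))
  }
  stop("read_spectrum: JCAMP file has no XYDATA/XYPOINTS/PEAK TABLE record")
}

#' Write a spectrum as a JCAMP-DX (XYPOINTS, AFFN) file
#'
#' @param spec A `compost_spectrum`.
#' @param path Output path.
#' @param title `##TITLE=` record content.
#' @return `path`, invisibly.
#' @export
write_jcamp <- function(spec, path, title = spec$label %||% "spectrum") {
  xunits <- if (spec$kind == "wavenumber_cm-1") "1/CM" else "PPM"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=SPECTRUM",
    paste0("##XUNITS=", xunits),
    "##YUNITS=ABSORBANCE",
    "##XFACTOR=1", "##YFACTOR=1",
    paste0("##FIRSTX=", format(spec$axis[1], digits = 15)),
    paste0("##LASTX=", format(spec$axis[length(spec$axis)], digits = 15)),
    paste0("##NPOINTS=", length(spec$axis)),
    "##XYPOINTS=(XY..XY)"), con)
  writeLines(paste(format(spec$axis, digits = 15, trim = TRUE),
                   format(spec$intensity, digits = 15, trim = TRUE),
                   sep = ", "), con)
  writeLines("##END=", con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# linear interpolation of intensity at arbitrary abscissa positions
spectrum_at <- function(spec, x) {
  stats::approx(spec$axis, spec$intensity, xout = x, rule = 1)$y
}
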
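#' Run the consolidated composting analysis pipeline
#'
#' Orchestrates per-pile, per-phase analysis across all techniques from a
#' single YAML configuration and writes a consolidated report: one CSV per
#' technique table-analogue (chemical indices; thermal R1/R2 indices;
#' FT-IR relative-absorbance profiles; NMR region percentages), one JSON
#' bundle and a plain-text run log. Stages whose inputs are absent from
#' the config are skipped and logged; a failing stage is recorded and does
#' not abort the run unless `strict = TRUE`.
#'
#' Config sections (all optional, at least one required):
#' \describe{
#'   \item{chemical}{`file`: sample table CSV (see
#'     [read_compost_samples()]).}
#'   \item{kinetics}{`file`: OM-loss CSV (`day`, `om_loss_pct`).}
#'   \item{temperature}{`file`: temperature CSV; optional `delta`,
#'     `persistence`, `clip_negative`.}
#'   \item{tg}{`runs`: list of `{label, file}`; optional `p1`, `p2`
#'     two-element region bounds (degC).}
#'   \item{ftir}{`runs`: list of `{label, file}`; optional `bands`.}
#'   \item{nmr}{`runs`: list of `{label, file}`; optional `baseline_offset`.}
#' }
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param out_dir Output directory (created if needed).
#' @param strict Abort (error) if any stage fails?
#' @return Invisibly, a list with `report` (nested results), `errors`
#'   (named character vector of stage failures) and `files` (paths
#'   written).
#' @export
run_pipeline <- function(config, out_dir, strict = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("run_pipeline: config file not found")
    cfg_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  } else cfg_hash <- NA_character_
  if (!is.list(config) || length(config) == 0)
    stop("run_pipeline: empty or unreadable config")
  known <- c("chemical", "kinetics", "temperature", "tg", "ftir", "nmr")
  if (!any(known %in% names(config)))
    stop("run_pipeline: config has none of the known sections (",
         paste(known, collapse = ", "), ")")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- c(paste0("compostom ", as.character(utils::packageVersion("compostom"))),
           paste0("config_md5 ", cfg_hash))
  report <- list()
  errors <- character()
  files <- character()
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[name]] <<- conditionMessage(res)
      log <<- c(log, paste0("stage ", name, " FAILED: ",
                            conditionMessage(res)))
    } else {
      report[[name]] <<- res
      log <<- c(log, paste0("stage ", name, " ok"))
    }
  }

  if (!is.null(config$chemical)) stage("chemical", function() {
    samples <- read_compost_samples(config$chemical$file)
    tab <- chem_index_table(samples)
    p <- file.path(out_dir, "chem_indices.csv")
    utils::write.csv(round_df(tab), p, row.names = FALSE)
    files <<- c(files, p)
    tab
  })

  if (!is.null(config$kinetics)) stage("kinetics", function() {
    s <- read_om_loss_series(config$kinetics$file)
    fit <- fit_first_order(s$times, s$losses)
    sm <- fit_summary(fit)
    out <- c(fit[c("a_max", "k_rate", "a_se", "k_se",
                   "residual_mean_square", "f_value", "see", "r_squared",
                   "n_obs")],
             list(p_value = sm$p_value))
    p <- file.path(out_dir, "kinetics.json")
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA)
    files <<- c(files, p)
    out
  })

  if (!is.null(config$temperature)) stage("temperature", function() {
    tc <- config$temperature
    series <- daily_means(read_temperature_series(tc$file))
    end_day <- detect_bio_oxidative_end(series,
                                        delta = tc$delta %||% 2,
                                        persistence = tc$persistence %||% 7)
    clip <- isTRUE(tc$clip_negative)
    exi <- exothermic_index(series, end_day, clip_negative = clip)
    out <- list(end_day = end_day, exi_cumulated_c = exi,
                clip_negative = clip, n_days = nrow(series))
    p <- file.path(out_dir, "temperature.json")
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA)
    files <<- c(files, p)
    out
  })

  if (!is.null(config$tg)) stage("tg", function() {
    p1 <- as.numeric(config$tg$p1 %||% c(250, 400))
    p2 <- as.numeric(config$tg$p2 %||% c(400, 580))
    rows <- lapply(config$tg$runs, function(run) {
      gram <- read_thermogram(run$file)
      ti <- thermal_indices(gram, p1, p2)
      tibble::tibble(label = run$label,
                     p1_mass_loss = ti$p1_mass_loss,
                     p2_mass_loss = ti$p2_mass_loss, r1 = ti$r1,
                     p1_area = ti$p1_area, p2_area = ti$p2_area,
                     r2 = ti$r2)
    })
    tab <- do.call(rbind, rows)
    attr(tab, "regions") <- list(p1 = p1, p2 = p2)
    p <- file.path(out_dir, "thermal_indices.csv")
    utils::write.csv(round_df(tab), p, row.names = FALSE)
    files <<- c(files, p)
    tab
  })

  if (!is.null(config$ftir)) stage("ftir", function() {
    bands <- if (is.null(config$ftir$bands)) ftir_band_table() else
      as.numeric(config$ftir$bands)
    rows <- lapply(config$ftir$runs, function(run) {
      spec <- read_spectrum(run$file, kind = "wavenumber_cm-1")
      prof <- ftir_profile(spec, bands)
      row <- tibble::as_tibble(as.list(stats::setNames(
        prof$ra, paste0("ra_", names(prof$ra)))))
      cbind(tibble::tibble(label = run$label), row,
            tibble::tibble(ratio_1037_1384 = prof$ratio_1037_1384))
    })
    tab <- do.call(rbind, rows)
    p <- file.path(out_dir, "ftir_profiles.csv")
    utils::write.csv(round_df(tab), p, row.names = FALSE)
    files <<- c(files, p)
    tab
  })

  if (!is.null(config$nmr)) stage("nmr", function() {
    offset <- config$nmr$baseline_offset %||% "none"
    rows <- lapply(config$nmr$runs, function(run) {
      spec <- read_spectrum(run$file, kind = "chemical_shift_ppm")
      ints <- integrate_regions(spec, baseline_offset = offset)
      row <- tibble::as_tibble(as.list(ints$relative))
      cbind(tibble::tibble(label = run$label), row,
            tibble::tibble(alkyl_oalkyl = alkyl_oalkyl_ratio(ints)))
    })
    tab <- do.call(rbind, rows)
    p <- file.path(out_dir, "nmr_regions.csv")
    utils::write.csv(round_df(tab), p, row.names = FALSE)
    files <<- c(files, p)
    tab
  })

  if (length(report) == 0 && length(errors) > 0 || strict && length(errors))
    stop("run_pipeline: ", if (length(report) == 0) "all stages failed: "
         else "stage failures under strict mode: ",
         paste(names(errors), collapse = ", "))

  bundle <- file.path(out_dir, "report.json")
  jsonlite::write_json(lapply(report, unclass_deep), bundle,
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(log, file.path(out_dir, "run_log.txt"))
  files <- c(files, bundle, file.path(out_dir, "run_log.txt"))
  invisible(list(report = report, errors = errors, files = files))
}

# round ratios to 2 d.p. and percentages to 1 d.p. at serialisation only
round_df <- function(df, ratio_digits = 2, pct_digits = 2) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) round(x, pct_digits))
  df
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, unclass_deep))
  x
}
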
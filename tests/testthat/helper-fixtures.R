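# Shared fixture builders (everything generated in code; no stored data).

# heights proportional to a published rA row, as generator input
ftir_row_heights <- function(pile, phase) {
  tab <- winery_compost_ftir()
  row <- tab[tab$pile_id == pile & tab$phase == phase, ]
  stats::setNames(as.numeric(row[paste0("ra_", default_ftir_bands())]) / 100,
                  default_ftir_bands())
}

# NMR region targets from a published spectral-distribution row,
# renormalised to sum exactly to 100 (printed rows sum to 100 +/- 0.1)
nmr_row_targets <- function(pile, phase) {
  tab <- winery_compost_nmr()
  row <- tab[tab$pile_id == pile & tab$phase == phase, ]
  lbl <- default_nmr_regions()$label
  t <- stats::setNames(as.numeric(row[lbl]), lbl)
  100 * t / sum(t)
}

# End-to-end pipeline fixture: writes a full synthetic pile-B scenario
# into `dir` and returns the YAML config path.
make_pipeline_inputs <- function(dir, seed = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chem <- winery_compost_chemical()
  samples <- data.frame(pile_id = chem$pile_id, phase = chem$phase,
                        day = chem$day, toc = chem$toc_tn * 2.5, tn = 2.5,
                        wsc = chem$wsc, cfa = chem$cfa, cha = chem$cha)
  utils::write.csv(samples, file.path(dir, "samples.csv"), row.names = FALSE)
  sc <- pile_scenario("B")
  g <- make_om_loss_series(sc, noise_sd = 1, seed = seed)
  utils::write.csv(data.frame(day = g$times, om_loss_pct = g$losses),
                   file.path(dir, "omloss.csv"), row.names = FALSE)
  tm <- make_temperature_series(sc, noise_sd = 0.3, seed = seed)
  utils::write.csv(data.frame(day = tm$series$time,
                              pile_temp_c = tm$series$pile_temp,
                              ambient_temp_c = tm$series$ambient_temp),
                   file.path(dir, "temps.csv"), row.names = FALSE)
  for (ph in c("initial", "maturity")) {
    mk <- make_pile_thermogram(sc, ph, noise_sd = 0.02, seed = seed)
    utils::write.csv(data.frame(temperature_c = mk$gram$temperature,
                                mass_pct = mk$gram$mass,
                                heat_flow = mk$gram$heat_flow),
                     file.path(dir, paste0("tg_", ph, ".csv")),
                     row.names = FALSE)
  }
  ft <- make_ftir_spectrum(ftir_row_heights("B", "initial"),
                           noise_sd = 1e-4, seed = seed)
  write_jcamp(ft$spec, file.path(dir, "ftir.jdx"))
  nm <- make_nmr_spectrum(nmr_row_targets("B", "initial"),
                          noise_sd = 0.002, seed = seed)
  utils::write.table(data.frame(g = nm$spec$axis, i = nm$spec$intensity),
                     file.path(dir, "nmr.txt"), row.names = FALSE,
                     col.names = FALSE)
  cfg <- list(
    chemical = list(file = file.path(dir, "samples.csv")),
    kinetics = list(file = file.path(dir, "omloss.csv")),
    temperature = list(file = file.path(dir, "temps.csv")),
    tg = list(runs = list(
      list(label = "B_initial", file = file.path(dir, "tg_initial.csv")),
      list(label = "B_maturity", file = file.path(dir, "tg_maturity.csv")))),
    ftir = list(runs = list(
      list(label = "B_initial", file = file.path(dir, "ftir.jdx")))),
    nmr = list(runs = list(
      list(label = "B_initial", file = file.path(dir, "nmr.txt")))))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
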
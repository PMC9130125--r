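#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic fossil forests and paleosol profile that
# stand in for the raw measurements, and write them in interchange formats.
suppressPackageStartupMessages(library(paleodendro))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
dir.create("results", showWarnings = FALSE)

# "Late Permian stand": six short-lived trees whose start years span 42 yr.
stand <- forest_config(
  n_trees = 6L, years = 25L, radii_per_tree = 2L,
  offsets = c(0L, 3L, 7L, 10L, 14L, 17L),
  signal_gain = 0.5, climate_noise_sd = 1.0, noise_sd = 0.25, ar1_phi = 0.4,
  marker_years = data.frame(year = seq(5, 40, by = 7),
                            multiplier = rep(c(0.45, 1.7), length.out = 6)),
  seed = seed)
forest <- simulate_forest(stand)
write_rwl(forest$series, "results/stand_series.rwl")
write_series_csv(forest$series, "results/stand_series.csv")
write.csv(forest$true_climate, "results/stand_true_climate.csv",
          row.names = FALSE)
message(sprintf("stand: %d series over a true span of %d yr -> results/stand_series.{rwl,csv}",
                length(forest$series), forest$true_span))

# "Long chronology" with a skewed 30-yr oscillation adversely coupled to
# growth -- the input for the wavelet and growth-response stages.
long_cfg <- forest_config(
  n_trees = 6L, years = 238L, radii_per_tree = 2L,
  climate_signal = list(list(period = 30, amplitude = 1.0, phase = 0),
                        list(period = 15, amplitude = 0.5, phase = 0)),
  climate_noise_sd = 0.3, ar1_phi = 0.3, noise_sd = 0.25,
  signal_gain = -0.8, seed = seed)
long <- simulate_forest(long_cfg)
write_series_csv(long$series, "results/long_series.csv")
message(sprintf("long chronology forest: %d series x %d yr -> results/long_series.csv",
                length(long$series), long$true_span))

# Weathered paleosol profile (five B horizons over parent material).
prof <- simulate_paleosol(seed = seed)
write_paleosol_csv(prof, "results/paleosol_profile.csv")
message("paleosol profile -> results/paleosol_profile.csv")
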
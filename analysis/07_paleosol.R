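#!/usr/bin/env Rscript
# Stage 7 -- paleosol proxy chain: molar conversion, CIA with authigenic-K
# correction, CIA-K, paleo-precipitation, land surface temperature, Eppt/ET
# and the humidity-province classification, with the >5% CIA-K QC gate.
suppressPackageStartupMessages(library(paleodendro))

prof <- read_paleosol_csv("results/paleosol_profile.csv")
qc <- profile_qc(prof)
message(sprintf("QC: CIA-K contrast between B horizons and parent = %.1f%% (%s)",
                qc$ciak_contrast_percent,
                if (qc$passes) "> 5%: pedogenesis preserved"
                else "<= 5%: proxies not applicable"))

est <- paleosol_climate(prof)
write.csv(est, "results/paleosol_estimates.csv", row.names = FALSE)
jsonlite::write_json(qc, "results/paleosol_qc.json", auto_unbox = TRUE,
                     digits = NA)

b <- est[-prof$parent_index, ]
message(sprintf("B horizons: CIA-K %.1f..%.1f, MAP %.0f..%.0f mm/yr, LST %.1f..%.1f degC",
                min(b$cia_k), max(b$cia_k), min(b$map_mm_yr), max(b$map_mm_yr),
                min(b$lst_celsius), max(b$lst_celsius)))
message(sprintf("humidity provinces: %s",
                paste(unique(est$humidity_province), collapse = ", ")))
message("-> results/paleosol_estimates.csv, results/paleosol_qc.json")
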
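#!/usr/bin/env Rscript
# Stage 6 -- hit confirmation by 1:1 binding-model fits.
#
# Simulates the confirmation assays for three fictitious hits with known
# parameters and fits each: SPR steady state, SPR kinetics, DSF melt and
# FP displacement, plus the cross-target selectivity matrix as
# normalized percent binding. Everything here is synthetic: the point is
# parameter recovery and the report format, not any real compound.

library(delscreen)

dir_ <- file.path("results", "binding")
dir.create(dir_, recursive = TRUE, showWarnings = FALSE)
report <- list()

# SPR steady state: 8-point 3-fold titration from 90 uM, 2% noise
ts <- simulate_assay("spr_steady", list(KD = 18e-6, Rmax = 50),
                     list(top = 90e-6, dilution = 3, n_points = 8),
                     cv = 0.02, seed = 61)
f_ss <- fit_steady_state(ts)
message(sprintf("steady state: KD = %.3g M (true 1.8e-05), Rmax = %.3g RU",
                f_ss$parameters[["KD"]], f_ss$parameters[["Rmax"]]))
report$spr_steady <- as.list(f_ss$parameters)

# SPR kinetics: four concentrations, association 300 s / dissociation 300 s
sg <- simulate_assay("spr_kinetic", list(ka = 1e5, kd = 1e-2, Rmax = 80),
                     list(time = seq(0, 600, by = 2),
                          concentrations = c(2e-6, 6e-6, 18e-6, 54e-6),
                          t_assoc = 300), cv = 0.02, seed = 62)
f_kin <- fit_kinetic_1to1(sg)
message(sprintf("kinetics: ka = %.3g 1/(M s), kd = %.3g 1/s, KD = %.3g M",
                f_kin$parameters[["ka"]], f_kin$parameters[["kd"]],
                f_kin$parameters[["KD"]]))
report$spr_kinetic <- as.list(f_kin$parameters)

# DSF: ligand-induced stabilization, 1 degree C sampling, 1% noise
d0 <- simulate_assay("dsf", list(Tm = 52, slope = 2, Fmin = 100, Fmax = 1000),
                     list(temperatures = seq(25, 85)), cv = 0.01, seed = 63)
d1 <- simulate_assay("dsf", list(Tm = 55.5, slope = 2, Fmin = 100, Fmax = 1000),
                     list(temperatures = seq(25, 85)), cv = 0.01, seed = 64)
tm0 <- fit_boltzmann_tm(d0$temperature, d0$fluorescence)$parameters[["Tm"]]
tm1 <- fit_boltzmann_tm(d1$temperature, d1$fluorescence)$parameters[["Tm"]]
message(sprintf("DSF: apo Tm = %.2f C, +compound Tm = %.2f C (delta %.2f C)",
                tm0, tm1, tm1 - tm0))
report$dsf <- list(tm_apo = tm0, tm_holo = tm1, delta_tm = tm1 - tm0)

# FP displacement: 12-point 3-fold titration
fp <- simulate_assay("fp", list(Kdisp = 36e-6, hill = 1, top = 200,
                                bottom = 60),
                     list(concentrations = 2e-4 / 3^(11:0)), cv = 0.02,
                     seed = 65)
f_fp <- fit_fp_displacement(fp)
message(sprintf("FP displacement: Kdisp = %.3g M (true 3.6e-05)",
                f_fp$parameters[["Kdisp"]]))
report$fp <- as.list(f_fp$parameters)

# selectivity: three hits x four proteins at a fixed 50 uM dose,
# triplicate responses scaled against the theoretical Rmax
proteins <- c("T1", "T2", "T3", "T4")
hits <- c("hitA", "hitB", "hitC")
rmax <- expand.grid(compound = hits, protein = proteins,
                    stringsAsFactors = FALSE)
rmax$rmax_theoretical <- theoretical_rmax(5000, 400, 45000)
on_target <- data.frame(compound = hits, protein = proteins[1:3])
sim_panel <- do.call(rbind, lapply(seq_len(nrow(rmax)), function(r) {
  frac <- if (any(on_target$compound == rmax$compound[r] &
                  on_target$protein == rmax$protein[r])) 0.85 else 0.05
  delscreen:::with_seed(70 + r, data.frame(
    compound = rmax$compound[r], protein = rmax$protein[r], replicate = 1:3,
    response = rmax$rmax_theoretical[r] * frac * (1 + stats::rnorm(3, 0, 0.05))))
}))
sel <- selectivity_matrix(sim_panel, rmax)
print(round(sel, 1))
report$selectivity_percent <- as.data.frame(round(sel, 1))

jsonlite::write_json(report, file.path(dir_, "fit_report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote ", file.path(dir_, "fit_report.json"))
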
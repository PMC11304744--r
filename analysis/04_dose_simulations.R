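#!/usr/bin/env Rscript
# Step 4: Monte Carlo dosing simulations and weight-band optimization.
#
# Simulates steady-state exposures for the doses used in the study
# (20 mg/kg/day TB-only capped at 300 mg; 2.5 and 5 mg/kg/day with
# LPV/r) over a virtual population of 500 children per kg between 6
# and 45 kg, compares the per-kg medians with adult reference
# exposures, and derives harmonized weight-band doses targeting the
# 4,500 ug.h/L median AUC floor under the 900 ug/L peak constraint.

library(rifabutinpk)

seed <- 20240904
pop <- make_virtual_population(n_per_kg = 500, weight_range = c(6, 45),
                               seed = seed)
cat("virtual population:", nrow(pop), "children, 6-45 kg\n")

scen <- simulate_study_scenarios(pop, seed = seed + 1)
perkg <- do.call(rbind, lapply(names(scen), function(nm)
  cbind(scenario = nm, scen[[nm]]$per_kg)))
write.csv(perkg, "results/study_dose_exposures.csv", row.names = FALSE)

r <- scen$tb20$per_kg
i <- r$kg_bin >= 10 & r$kg_bin < 15
cat(sprintf("TB-only 20 mg/kg, 10-15 kg: rifabutin median AUC exceeds the adult
  upper reference (5,640 ug.h/L) by up to %.0f%%; des-rifabutin (700) by %.0f%%\n",
  100 * max(r$auc_parent_med[i] / 5640 - 1),
  100 * max(r$auc_metabolite_med[i] / 700 - 1)))
cat(sprintf("largest per-kg median rifabutin Cmax across scenarios: %.0f ug/L (< 900)\n",
  max(sapply(scen, function(s) max(s$per_kg$cmax_parent_med)))))

opt_tb <- optimize_band_doses(pop, context = "tb", seed = seed + 5)
opt_lp <- optimize_band_doses(pop, context = "lpvr", seed = seed + 6)
bands <- data.frame(band = paste0(">=", opt_tb$lo, " to <", opt_tb$hi),
                    dose_tb = opt_tb$dose, dose_lpvr = opt_lp$dose)
cat("\noptimized harmonized weight-band doses (mg):\n")
print(bands, row.names = FALSE)
write.csv(cbind(bands,
                auc_tb = round(opt_tb$auc_parent), auc_lpvr = round(opt_lp$auc_parent),
                cmax_tb = round(opt_tb$cmax_parent), cmax_lpvr = round(opt_lp$cmax_parent)),
          "results/optimized_bands.csv", row.names = FALSE)

ev <- evaluate_rule(simulate_exposures(pop, dose_rule_bands(
  data.frame(lo = opt_lp$lo, hi = opt_lp$hi, dose = opt_lp$dose), lpvr = 1),
  seed = seed + 7), context = "lpvr")
cat("\nband verdicts under the optimized LPV/r doses:\n")
print(ev[, c("group", "auc_median", "cmax_median", "auc_in_window", "cmax_ok",
             "floor_ok", "pass")], row.names = FALSE, digits = 4)
write.csv(ev, "results/band_evaluation.csv", row.names = FALSE)
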
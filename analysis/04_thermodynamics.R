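#!/usr/bin/env Rscript
# Step 4: dissolution thermodynamics. Ideal solubility and activity
# coefficients from the fusion properties; apparent enthalpy, Gibbs
# energy and entropy of dissolution per solvent and per mixture
# composition at the mean harmonic temperature; enthalpy-entropy
# compensation across the mixture.

suppressPackageStartupMessages(library(soluterm))

pure <- read_solubility_csv("results/data/pure_solvents.csv")
mixture <- read_solubility_csv("results/data/twm_mixture.csv")
fusion <- drug_fusion_properties()
thm <- harmonic_mean_temperature(sort(unique(pure$temperature)))

cat(sprintf("fusion: Tfus = %.2f K, dHfus = %.0f J/mol, dCp = %.2f J/mol/K\n",
            fusion$Tfus, fusion$dHfus, fusion$dCp))
cat(sprintf("mean harmonic temperature of the 5-point grid: %.2f K\n", thm))

gamma_tab <- data.frame(
  solvent_id = pure$solvent_id, T_K = pure$temperature,
  x_exp = pure$x,
  x_ideal = ideal_solubility(fusion, pure$temperature))
gamma_tab$gamma <- activity_coefficient(gamma_tab$x_ideal, gamma_tab$x_exp)
write.csv(gamma_tab, "results/activity_coefficients.csv", row.names = FALSE)

thermo_one <- function(d, label, value) {
  th <- vanthoff_thermo(d[, c("temperature", "x")], thm = thm)
  out <- data.frame(value, dH_J_mol = th$dH, dG_J_mol = th$dG,
                    dS_J_molK = th$dS, Thm_K = th$thm)
  names(out)[1] <- label
  out
}
th_pure <- do.call(rbind, lapply(split(pure, pure$solvent_id), function(d)
  thermo_one(d, "solvent_id", d$solvent_id[1])))
th_mix <- do.call(rbind, lapply(split(mixture, mixture$w2), function(d)
  thermo_one(d, "w2", d$w2[1])))
write.csv(th_pure, "results/thermo_pure.csv", row.names = FALSE)
write.csv(th_mix, "results/thermo_mixture.csv", row.names = FALSE)

comp <- compensation_analysis(th_mix$dH_J_mol, th_mix$dG_J_mol)
jsonlite::write_json(list(slope = comp$slope,
                          intercept_J_mol = comp$intercept,
                          n = nrow(th_mix)),
                     "results/compensation.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

gam298 <- gamma_tab[gamma_tab$T_K == min(gamma_tab$T_K), ]
cat(sprintf("activity coefficients at 298.15 K: min %.2f (%s), max %.0f (%s)\n",
            min(gam298$gamma), gam298$solvent_id[which.min(gam298$gamma)],
            max(gam298$gamma), gam298$solvent_id[which.max(gam298$gamma)]))
cat(sprintf("dissolution is endothermic everywhere (all dH > 0: %s)\n",
            all(c(th_pure$dH_J_mol, th_mix$dH_J_mol) > 0)))
cat(sprintf("enthalpy-entropy compensation slope across the mixture: %.3f (positive: %s)\n",
            comp$slope, comp$slope > 0))
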
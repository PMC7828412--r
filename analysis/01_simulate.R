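#!/usr/bin/env Rscript
# Step 1: build the study datasets.
#
# No laboratory measurements ship with this repository, so the datasets
# are simulated from the published model parameters: one 5-point
# temperature series (298.15-318.15 K) per pure solvent from the van't
# Hoff parameters, and an 11 x 5 (composition x temperature) grid for
# the Transcutol HP-water mixture from the Jouyban-Acree van't Hoff
# parameters. Triplicate measurements with 3% multiplicative log-normal
# noise are averaged per point, mimicking the static-equilibrium
# protocol.

suppressPackageStartupMessages(library(soluterm))

seed <- 20260924L
noise_cv <- 0.03
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

ref <- pure_solvent_params()
pure <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
  s <- generate_temperature_series("vanthoff",
                                   list(a = ref$a[i], b = ref$b[i]),
                                   noise_cv = noise_cv, seed = seed + i)
  data.frame(solvent_id = ref$solvent_id[i], T_K = s$temperature,
             w2 = 0, x_exp = s$x)
}))
write.csv(pure, "results/data/pure_solvents.csv", row.names = FALSE)

grid <- generate_mixture_grid(javh_reference_params(), noise_cv = noise_cv,
                              seed = seed + 1000L)
mixture <- data.frame(solvent_id = "twm", T_K = grid$temperature,
                      w2 = grid$w2, x_exp = grid$x)
write.csv(mixture, "results/data/twm_mixture.csv", row.names = FALSE)

cat(sprintf("simulated %d pure-solvent points (%d solvents) and %d mixture points\n",
            nrow(pure), nrow(ref), nrow(mixture)))
cat(sprintf("solubility spans %.1e (water, 298 K) to %.1e (THP-rich, 318 K)\n",
            min(pure$x_exp), max(mixture$x_exp)))
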
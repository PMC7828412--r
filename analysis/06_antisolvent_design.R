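#!/usr/bin/env Rscript
# Step 6: anti-solvent precipitation design. Refits the Jouyban-Acree
# van't Hoff surface to the mixture data and selects the composition for
# liquid anti-solvent precipitation: the solvent share is capped at 0.2
# (solvent-to-anti-solvent ratio rule) and the feasible composition with
# the lowest predicted solubility maximizes supersaturation.

suppressPackageStartupMessages(library(soluterm))

mixture <- read_solubility_csv("results/data/twm_mixture.csv")
javh <- fit_javh(mixture[, c("w2", "temperature", "x")])

sel <- select_antisolvent_composition(javh, temperature = 298.15,
                                      max_solvent_fraction = 0.2)
jsonlite::write_json(
  list(w2 = sel$w2, x_pred = sel$x_pred, temperature_K = 298.15,
       max_solvent_fraction = 0.2),
  "results/antisolvent_design.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat(sprintf("selected Transcutol HP fraction w2 = %.1f at 298.15 K\n", sel$w2))
cat(sprintf("predicted mole-fraction solubility there: %.3e\n", sel$x_pred))
cat("low solubility at the injection composition maximizes supersaturation,\n")
cat("favoring nucleation over growth and hence small particles\n")
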
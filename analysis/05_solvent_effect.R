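#!/usr/bin/env Rscript
# Step 5: solvent-effect (KAT-LSER) study. Regresses ln solubility at
# 298.15 K on the Kamlet-Taft solvatochromic descriptors plus the
# Hildebrand cohesive-energy term, over the ten solvents with bundled
# descriptors (Transcutol HP lacks reliable published descriptors and is
# excluded, as is the near-degenerate water-free mixture data).

suppressPackageStartupMessages(library(soluterm))

pure <- read_solubility_csv("results/data/pure_solvents.csv")
at298 <- pure[pure$temperature == 298.15, ]

desc <- solvent_descriptors()
at298 <- at298[match(desc$solvent_id, at298$solvent_id), ]
stopifnot(!anyNA(at298$x))

X <- kat_design_matrix(desc, vs = 26.5, temperature = 298.15)
fit <- fit_katlser(log(at298$x), X)

jsonlite::write_json(
  list(coefficients = as.list(fit$coefficients),
       std_errors = as.list(fit$std_errors),
       r2 = fit$r2, F = fit$F, rss = fit$rss,
       contributions_percent = as.list(fit$contributions), n = fit$n),
  "results/katlser_fit.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("KAT-LSER over %d solvents: R2 = %.3f, RSS = %.3f\n",
            fit$n, fit$r2, fit$rss))
cat("coefficients (c0..c4):", signif(fit$coefficients, 4), "\n")
cat("term contributions (%):\n")
print(round(fit$contributions, 2))
cat(if (fit$coefficients[["alpha"]] < 0)
      "negative alpha coefficient: hydrogen-bond-donating solvents dissolve the drug worse\n"
    else
      "alpha coefficient is positive for this draw\n")
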
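#!/usr/bin/env Rscript
# Step 2: correlate the pure-solvent temperature series with the three
# single-solvent models (modified Apelblat, van't Hoff, lambda-h) and
# rank them by absolute mean relative deviation.

suppressPackageStartupMessages(library(soluterm))

pure <- read_solubility_csv("results/data/pure_solvents.csv")
Tm <- drug_fusion_properties()$Tfus

rows <- do.call(rbind, lapply(split(pure, pure$solvent_id), function(d) {
  series <- d[, c("temperature", "x")]
  fits <- list(apelblat = fit_apelblat(series),
               vanthoff = fit_vanthoff(series),
               bkm = fit_bkm(series, Tm = Tm))
  do.call(rbind, lapply(names(fits), function(m) {
    f <- fits[[m]]
    data.frame(solvent_id = d$solvent_id[1], model = m,
               params = paste(signif(unlist(f$params), 8), collapse = ";"),
               mrd_abs_percent = f$quality$mrd_abs_percent,
               rmsd = f$quality$rmsd, n = f$quality$n_points)
  }))
}))
dir.create("results", showWarnings = FALSE)
write.csv(rows, "results/pure_solvent_fits.csv", row.names = FALSE)

by_model <- tapply(rows$mrd_abs_percent, rows$model, mean)
cat("mean |MRD| per model across solvents (%):\n")
print(round(by_model, 3))
cat("lowest-solubility solvent at 298.15 K:",
    pure$solvent_id[which.min(pure$x[pure$temperature == 298.15])], "\n")
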
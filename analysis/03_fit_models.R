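#!/usr/bin/env Rscript
# Fit the isotropy null and the four anisotropy error models to each
# body-orientation condition (upright; backward-pitch coded earth- and
# body-centered) and compare them by AICc. Writes one comparison table per
# condition under results/.

library(pathaniso)

tab <- read_trials("results/cleaned.csv")
conditions <- list(list(orientation = "upright", frame = "earth"),
                   list(orientation = "pitch30", frame = "earth"),
                   list(orientation = "pitch30", frame = "body"))

for (cond in conditions) {
  key <- paste(cond$orientation, cond$frame, sep = "_")
  fits <- lapply(model_variants(), function(v)
    fit_anisotropy(tab, v, orientation = cond$orientation,
                   frame = cond$frame))
  cmp <- compare_models(fits)
  utils::write.csv(cmp, sprintf("results/comparison_%s.csv", key),
                   row.names = FALSE)
  cat(sprintf("\n== %s ==\n", key))
  print(cmp, digits = 4)
  best <- fits[[match(cmp$variant[1], vapply(fits, `[[`, "", "variant"))]]
  cat("Best model estimates:\n")
  print(best$fixed_estimates)
}
cat("\nWrote results/comparison_<condition>.csv tables.\n")
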
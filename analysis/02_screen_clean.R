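#!/usr/bin/env Rscript
# Exclusion rules: drop participants whose reproduced distances do not
# correlate with the target distances (duration-strategy responders), then
# drop trials whose absolute error deviates more than 2 SD from the
# participant's overall mean. Writes the cleaned table and an exclusion
# report under results/.

library(pathaniso)
library(jsonlite)

tab <- read_trials("results/cohort.csv")
scr <- screen_participants(tab)
cln <- remove_outlier_trials(scr$kept)
write_trials(cln$trials, "results/cleaned.csv")
write_json(list(excluded_participants = scr$excluded,
                removed_trial_fraction = cln$removed_fraction),
           "results/exclusions.json", auto_unbox = TRUE, digits = NA,
           dataframe = "rows")

cat(sprintf("Excluded %d of %d participants:\n", nrow(scr$excluded),
            length(unique(tab$participant_id))))
print(scr$excluded)
cat(sprintf("Removed %d outlier trials (%.1f%% of the retained data).\n",
            cln$n_removed, 100 * cln$removed_fraction))
cat("Wrote results/cleaned.csv and results/exclusions.json.\n")
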
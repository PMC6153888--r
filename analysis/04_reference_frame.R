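#!/usr/bin/env Rscript
# Body- versus earth-centered anisotropy: correlate the upright
# per-direction error pattern with the backward-pitch pattern coded in
# each frame. A higher body-frame correlation indicates the anisotropy
# rotates with the trunk.

library(pathaniso)
library(jsonlite)

tab <- read_trials("results/cleaned.csv")
fr <- compare_frames(tab)
write_json(list(earth = unclass(fr$earth), body = unclass(fr$body)),
           "results/frames.json", auto_unbox = TRUE, digits = NA)

print(fr$body)
print(fr$earth)
cat(sprintf("Body-frame coding %s the earth-frame coding (r %.3f vs %.3f).\n",
            if (fr$body$r > fr$earth$r) "beats" else "does not beat",
            fr$body$r, fr$earth$r))
cat("Wrote results/frames.json.\n")
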
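#!/usr/bin/env Rscript
# Builds the motif model from the called top windows and renders the
# sequence logo (stack heights = per-column information content in bits,
# dashed line = cut site between columns 5 and 6).
# Run analysis/02_call_cleavage_sites.R first.

library(cleavemap)

report <- jsonlite::read_json("results/report.json", simplifyVector = TRUE)
windows <- report$top$window

model <- build_motif(windows, cut_offset = report$params$flank)
print(model)
render_logo(model, "results/logo.png")
render_logo(model, "results/logo.svg")
cat("Logo written to results/logo.png and results/logo.svg\n")
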
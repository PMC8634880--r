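#!/usr/bin/env Rscript
# Simulates the cleavage library: eight substrate RNAs (533, 1033 x5, 1533,
# 2033 nt) with planted strong/weak recognition-motif variants and decoys,
# digested at the default enzyme model (UACAAA efficiency 0.9, background
# break rate 1e-4, 5000 molecules, 150-nt 5'-anchored reads).
# Writes FASTA + coverage TSV + ground-truth manifest to results/fixtures/.

library(cleavemap)

panel <- make_fixture_panel(seed = 1L, out_dir = "results/fixtures")

cat("Simulated", length(panel$substrates), "substrates:\n")
for (id in names(panel$substrates)) {
  planted <- panel$manifest$substrates[[id]]$planted
  cat(sprintf("  %-7s %5d nt, %d planted site(s): %s\n", id,
              nchar(panel$substrates[[id]]), nrow(planted),
              paste(sprintf("%s@%d", planted$variant, planted$position),
                    collapse = ", ")))
}
cat("Coverage range per substrate:\n")
for (id in names(panel$tracks)) {
  cat(sprintf("  %-7s min %d, median %g, max %d\n", id,
              min(panel$tracks[[id]]), stats::median(panel$tracks[[id]]),
              max(panel$tracks[[id]])))
}
cat("Fixtures written to results/fixtures/\n")
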
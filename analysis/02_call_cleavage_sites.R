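#!/usr/bin/env Rscript
# Calls cleavage sites from the simulated library: pseudocount, RCI,
# per-substrate median filter, RCI >= 3 threshold, 11-nt windows, pooled
# top-10 ranking. Writes the JSON report, a BED6 track of the top sites and
# a TSV site table under results/.
# Run analysis/01_simulate_library.R first.

library(cleavemap)

substrates <- read_fasta("results/fixtures/panel.fasta", "RNA")
tracks <- read_coverage("results/fixtures/coverage.tsv")

report <- detect_recognition_sequence(substrates, tracks)
print(report)

write_report(report, "results/report.json")
write_sites_bed(report$top, "results/top_sites.bed")
utils::write.table(report$sites, "results/sites.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("\nTop-ranked windows (step-up base at window position 6):\n")
print(report$top[, c("rank", "substrate_id", "position", "rci", "window")],
      row.names = FALSE)
cat("\nConsensus:", report$consensus, " cut:", report$cut_annotation, "\n")
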
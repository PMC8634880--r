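#!/usr/bin/env Rscript
# Counts coding sequences containing the recognition motif on the mRNA
# (sense) strand. By default scans the bundled synthetic CDS fixture; pass a
# path to scan a real CDS FASTA (e.g. a genome's "CDS from genomic" file).
# Usage: Rscript analysis/04_scan_cds.R [cds.fasta] [motif]

library(cleavemap)

args <- commandArgs(trailingOnly = TRUE)
cds_path <- if (length(args) >= 1) args[[1]] else
  system.file("extdata", "synthetic_cds.fasta", package = "cleavemap")
motif <- if (length(args) >= 2) args[[2]] else "UACAAA"

cds <- read_fasta(cds_path, "DNA")
res <- scan_cds(cds, motif)
print(res)
scan_report(res, "results/cds_scan.tsv")
cat("Report written to results/cds_scan.tsv\n")
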
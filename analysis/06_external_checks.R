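#!/usr/bin/env Rscript
# OPTIONAL, REQUIRES NETWORK ACCESS. Accession-backed worked examples:
#  (a) fetch the MazF-Da (WP_012302900.1) and MazE-Da (WP_012302901.1)
#      reference proteins and report their lengths (118 and 96 aa);
#  (b) fetch the current NCBI CDS annotation of the Ca. Desulforudis
#      audaxviator genome (NC_010424) and count CDSs containing UACAAA on
#      the sense strand. The count depends on the annotation release, so it
#      is reported together with today's date rather than asserted.

library(cleavemap)

dir.create("results", showWarnings = FALSE)

prot_fa <- file.path("results", "mazEF_Da_proteins.fasta")
fetch_ncbi_proteins(c("WP_012302900.1", "WP_012302901.1"), prot_fa)
prots <- read_fasta(prot_fa, "protein")
cat("Fetched proteins:\n")
for (id in names(prots)) {
  cat(sprintf("  %s: %d aa\n", id, nchar(prots[[id]])))
}
cat("Expected: MazF-Da (WP_012302900.1) 118 aa, MazE-Da (WP_012302901.1) 96 aa\n\n")

cds_fa <- file.path("results", "NC_010424_cds.fasta")
fetch_genome_cds("NC_010424", cds_fa)
cds <- read_fasta(cds_fa, "DNA")
res <- scan_cds(cds, "UACAAA")
cat(sprintf("NC_010424 annotation fetched %s: %d of %d CDSs contain UACAAA\n",
            format(Sys.Date()), res$n_cds_with_hit, res$n_cds_total))
scan_report(res, "results/NC_010424_scan.tsv")
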
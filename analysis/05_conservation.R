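#!/usr/bin/env Rscript
# Conservation displays for the enzyme proteins: column marks on the
# bundled synthetic MazF-like MSA ('*' = 100% identity, '.' = 80% within
# one similarity group), the conserved-site table against the first row,
# and a pairwise global alignment of two (degapped) rows with percent
# identity/similarity.

library(cleavemap)

msa <- read_fasta(system.file("extdata", "synthetic_mazf_msa.fasta",
                              package = "cleavemap"), "protein")
ann <- annotate_msa(msa)
print(ann)

sites <- conserved_site_report(ann)
utils::write.table(sites, "results/conserved_sites.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Fully conserved reference positions:",
    paste(sites$reference_position[sites$mark == "*"], collapse = ", "),
    "\n\n")

al <- global_align(gsub("-", "", msa[[1]]), gsub("-", "", msa[[3]]))
print(al)
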
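# Builds the synthetic text fixtures shipped under inst/extdata/.
# Both files are fully synthetic stand-ins (no database sequences):
#  - synthetic_cds.fasta: 30 random coding-sequence-like DNA records, some
#    of which contain the TACAAA (UACAAA) motif by chance of construction.
#  - synthetic_mazf_msa.fasta: a 9-row MazF-like aligned protein fixture
#    with fully conserved columns planted at reference positions 6, 15, 18,
#    20, 25, 26, 36 and 85 (G, P, G, E, R, P, N, R), mimicking the kind of
#    conservation pattern seen across MazF homologs, plus a gap block.
# Run from the repository root: Rscript data-raw/make_fixtures.R

set.seed(20211111)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

## ---- synthetic CDS panel ----------------------------------------------
n_cds <- 30L
lens <- sample(seq(300L, 1200L, by = 3L), n_cds, replace = TRUE)
cds <- vapply(seq_len(n_cds), function(i) {
  body <- paste(sample(c("A", "C", "G", "T"), lens[i] - 6L, replace = TRUE,
                       prob = c(0.28, 0.22, 0.22, 0.28)), collapse = "")
  paste0("ATG", body, "TAA")
}, character(1))
# plant the motif into a known subset so the fixture always has signal
for (i in c(2L, 7L, 11L, 19L, 23L, 30L)) {
  at <- sample(10:(nchar(cds[i]) - 10L), 1L)
  substr(cds[i], at, at + 5L) <- "TACAAA"
}
names(cds) <- sprintf("syncds_%03d", seq_len(n_cds))
lines <- character(0)
for (i in seq_along(cds)) {
  lines <- c(lines, paste0(">", names(cds)[i], " synthetic CDS fixture"),
             gsub("(.{60})", "\\1\n", cds[[i]], perl = TRUE))
}
writeLines(sub("\n$", "", lines), "inst/extdata/synthetic_cds.fasta")

## ---- synthetic MazF-like MSA ------------------------------------------
aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
ref_len <- 118L
ref <- sample(aa, ref_len, replace = TRUE)
conserved <- c(`6` = "G", `15` = "P", `18` = "G", `20` = "E",
               `25` = "R", `26` = "P", `36` = "N", `85` = "R")
ref[as.integer(names(conserved))] <- conserved
ids <- c("MazF_synthetic_Da", paste0("MazF_synthetic_", LETTERS[1:8]))
rows <- list(paste(ref, collapse = ""))
for (k in 2:9) {
  row <- ref
  mutate <- setdiff(seq_len(ref_len), as.integer(names(conserved)))
  flip <- sample(mutate, round(0.35 * length(mutate)))
  row[flip] <- sample(aa, length(flip), replace = TRUE)
  rows[[k]] <- paste(row, collapse = "")
}
# gap block: rows 3-9 carry a 6-column insert that the reference row (and
# row 2) lack, so reference numbering stays 1..118 and some conserved-ish
# columns are reference-gapped
insert_at <- 60L
with_ins <- function(s, gap) {
  paste0(substr(s, 1, insert_at),
         if (gap) "------" else paste(sample(aa, 6L, TRUE), collapse = ""),
         substr(s, insert_at + 1L, nchar(s)))
}
msa <- vapply(seq_along(rows), function(k) with_ins(rows[[k]], k <= 2L),
              character(1))
names(msa) <- ids
lines <- character(0)
for (i in seq_along(msa)) {
  lines <- c(lines, paste0(">", names(msa)[i], " synthetic aligned fixture"),
             msa[[i]])
}
writeLines(lines, "inst/extdata/synthetic_mazf_msa.fasta")

cat("wrote", length(cds), "CDS records and a", length(msa), "x",
    nchar(msa[[1]]), "MSA\n")
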
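# Optional NCBI helpers. These require network access and are used only by
# analysis/06_external_checks.R for the accession-backed worked examples;
# nothing in the core pipeline or the test suite depends on them.

.EUTILS <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"

#' Fetch protein sequences from NCBI (requires network)
#'
#' Downloads protein records by accession via NCBI E-utilities and writes
#' them to a FASTA file. Intended for the worked examples that check the
#' MazF-Da (WP_012302900.1, 118 aa) and MazE-Da (WP_012302901.1, 96 aa)
#' reference proteins.
#'
#' @param accessions Character vector of protein accessions.
#' @param dest Output FASTA path.
#' @return Invisibly, `dest`.
#' @export
fetch_ncbi_proteins <- function(accessions, dest) {
  url <- sprintf("%s?db=protein&id=%s&rettype=fasta&retmode=text",
                 .EUTILS, paste(accessions, collapse = ","))
  status <- utils::download.file(url, dest, quiet = TRUE)
  if (status != 0 || !file.size(dest)) {
    stop("NCBI fetch failed (network unavailable?)")
  }
  invisible(dest)
}

#' Fetch the annotated CDS set of a genome from NCBI (requires network)
#'
#' Downloads the "CDS from genomic" nucleotide FASTA for a genome accession
#' (e.g. NC_010424 for *Ca.* Desulforudis audaxviator). Note that the CDS
#' count obtained from a current annotation can differ from counts computed
#' on earlier annotation releases.
#'
#' @param accession Genome accession.
#' @param dest Output FASTA path.
#' @return Invisibly, `dest`.
#' @export
fetch_genome_cds <- function(accession, dest) {
  url <- sprintf("%s?db=nuccore&id=%s&rettype=fasta_cds_na&retmode=text",
                 .EUTILS, accession)
  status <- utils::download.file(url, dest, quiet = TRUE)
  if (status != 0 || !file.size(dest)) {
    stop("NCBI fetch failed (network unavailable?)")
  }
  invisible(dest)
}
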
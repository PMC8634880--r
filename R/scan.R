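#' Scan coding sequences for a (degenerate) recognition motif
#'
#' Counts occurrences of an IUPAC motif on the sense (mRNA) strand of each
#' coding sequence. MazF-family enzymes act on single-stranded mRNA, so only
#' the sense strand is biologically exposed; antisense scanning is available
#' behind `both_strands` but off by default. Overlapping occurrences are
#' counted at every start, matching is case-insensitive, and T/U are
#' equivalent. By default an `N` in a CDS matches nothing (conservative);
#' set `n_matches_any = TRUE` to let subject ambiguity codes match.
#'
#' @param cds Named character vector of DNA or RNA sequences (e.g. from
#'   [read_fasta()]), or a `DNAStringSet`.
#' @param motif Motif string over IUPAC RNA/DNA codes (e.g. `"UACAAA"`,
#'   `"UACAAR"`). May be longer than a CDS (0 hits).
#' @param both_strands Also scan the reverse complement (default FALSE).
#' @param n_matches_any Treat ambiguity codes in the CDS as wildcards
#'   (default FALSE).
#' @return An object of class `scan_result`: list with `motif`, `per_cds`
#'   (data frame: `cds_id`, `n_hits`, `hit_positions` comma-joined 1-based
#'   sense-strand starts, plus `n_hits_antisense` when `both_strands`),
#'   `n_cds_with_hit`, `n_cds_total`.
#' @examples
#' scan_cds(c(c1 = "ATACAAAT", c2 = "GGGGGG", c3 = "TACAAATACAAA"), "UACAAA")
#' @export
scan_cds <- function(cds, motif, both_strands = FALSE,
                     n_matches_any = FALSE) {
  if (inherits(cds, "DNAStringSet")) {
    cds <- setNames(as.character(cds),
                    vapply(strsplit(names(cds), "[ \t]+"), `[[`,
                           character(1), 1L))
  }
  stopifnot(is.character(cds), !is.null(names(cds)))
  if (length(cds) == 0L) stop("empty CDS set")
  motif_in <- motif
  motif <- toupper(chartr("Uu", "Tt", motif))
  if (grepl("[^ACGTRYSWKMBDHVN]", motif)) {
    stop("motif contains non-IUPAC characters: ", motif_in)
  }
  seqs <- toupper(chartr("Uu", "Tt", cds))
  set <- Biostrings::DNAStringSet(seqs)
  fixed <- if (n_matches_any) FALSE else "subject"
  hits <- Biostrings::vmatchPattern(motif, set, fixed = fixed)
  starts <- BiocGenerics::start(hits)
  n_hits <- lengths(starts)
  per_cds <- data.frame(
    cds_id = names(cds),
    n_hits = as.integer(n_hits),
    hit_positions = vapply(starts, function(s)
      paste(sort(s), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  if (both_strands) {
    rc <- Biostrings::reverseComplement(set)
    anti <- Biostrings::vmatchPattern(motif, rc, fixed = fixed)
    per_cds$n_hits_antisense <- lengths(BiocGenerics::start(anti))
    per_cds$n_hits <- per_cds$n_hits + per_cds$n_hits_antisense
  }
  structure(list(
    motif = motif_in,
    per_cds = per_cds,
    n_cds_with_hit = sum(per_cds$n_hits >= 1L),
    n_cds_total = length(cds)
  ), class = "scan_result")
}

#' Write a motif-scan report as TSV
#'
#' One row per CDS with at least one hit (`cds_id`, `n_hits`, comma-joined
#' 1-based hit positions), followed by a summary footer row whose
#' `hit_positions` field reads `"<CDSs with hit>/<CDSs total>"`.
#'
#' @param result A `scan_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
scan_report <- function(result, path) {
  stopifnot(inherits(result, "scan_result"))
  if (any(grepl("\t", result$per_cds$cds_id, fixed = TRUE))) {
    stop("CDS id contains a tab character; refusing to write ambiguous TSV")
  }
  rows <- result$per_cds[result$per_cds$n_hits >= 1L,
                         c("cds_id", "n_hits", "hit_positions"), drop = FALSE]
  footer <- data.frame(
    cds_id = "TOTAL",
    n_hits = result$n_cds_with_hit,
    hit_positions = sprintf("%d/%d", result$n_cds_with_hit,
                            result$n_cds_total)
  )
  utils::write.table(rbind(rows, footer), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Motif scan:", x$motif, "\n")
  cat("  CDSs with >= 1 hit:", x$n_cds_with_hit, "of", x$n_cds_total, "\n")
  cat("  total hits:", sum(x$per_cds$n_hits), "\n")
  invisible(x)
}
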
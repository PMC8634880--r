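# Conventional "strong" residue similarity groups (Clustal-style). Each
# residue additionally forms its own singleton group, so a column that is
# mostly one residue counts as conserved-similar even when that residue is
# not in any multi-residue group.
.STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK",
                    "MILV", "MILF", "HY", "FYW")

#' Annotate column conservation of a protein multiple alignment
#'
#' Marks each MSA column with `*` when all rows carry the same residue and
#' none is a gap, with `.` when at least `threshold` of the rows fall into a
#' single similarity group (gaps never count toward a group), and with a
#' space otherwise. Similarity groups are the conventional strong groups
#' plus a singleton group per residue.
#'
#' @param msa Named character vector of equal-length aligned sequences
#'   (gaps as `-` or `.`), or an `AAStringSet` of aligned sequences.
#' @param similarity_groups Character vector of residue groups (default
#'   the strong groups).
#' @param threshold Fraction of rows required for a `.` mark (default 0.8).
#' @return An object of class `msa_conservation`: list with `msa`, `marks`
#'   (string over `*`, `.`, space of MSA width), `conserved_sites` (data
#'   frame: `column`, `reference_residue`, `reference_position`, `mark`,
#'   for `*`/`.` columns mapped to the first row, skipping columns gapped
#'   in it), and `threshold`.
#' @export
annotate_msa <- function(msa, similarity_groups = .STRONG_GROUPS,
                         threshold = 0.8) {
  if (inherits(msa, "XStringSet")) {
    msa <- setNames(as.character(msa), names(msa))
  }
  stopifnot(is.character(msa), length(msa) >= 2L, !is.null(names(msa)))
  msa <- toupper(chartr(".", "-", msa))
  W <- unique(nchar(msa))
  if (length(W) != 1L) stop("ragged MSA: aligned sequences differ in length")
  nr <- length(msa)
  rows <- do.call(rbind, strsplit(msa, ""))
  # multi-residue groups plus one singleton group per residue letter
  groups <- unique(c(similarity_groups, LETTERS))
  marks <- vapply(seq_len(W), function(j) {
    col <- rows[, j]
    if (all(col != "-") && length(unique(col)) == 1L) return("*")
    best <- 0
    for (g in groups) {
      members <- strsplit(g, "")[[1]]
      frac <- sum(col %in% members) / nr
      if (frac > best) best <- frac
    }
    if (best >= threshold) "." else " "
  }, character(1))
  ref <- rows[1L, ]
  ref_pos <- cumsum(ref != "-")
  keep <- marks %in% c("*", ".") & ref != "-"
  conserved_sites <- data.frame(
    column = which(keep),
    reference_residue = ref[keep],
    reference_position = ref_pos[keep],
    mark = marks[keep],
    stringsAsFactors = FALSE
  )
  structure(list(msa = msa, marks = paste(marks, collapse = ""),
                 conserved_sites = conserved_sites, threshold = threshold),
            class = "msa_conservation")
}

#' Tabulate conserved sites against a reference sequence
#'
#' Maps the `*` and `.` columns of an annotated MSA to positions of a chosen
#' reference row (default the first), skipping columns where the reference
#' is gapped. The resulting table (position, residue, mark) is the input
#' for selecting mutagenesis candidates among highly conserved residues.
#'
#' @param conservation An `msa_conservation` from [annotate_msa()].
#' @param reference_id Row name to use as reference; default first row.
#' @return Data frame with columns `reference_position`, `residue`, `mark`.
#' @export
conserved_site_report <- function(conservation, reference_id = NULL) {
  stopifnot(inherits(conservation, "msa_conservation"))
  msa <- conservation$msa
  if (is.null(reference_id)) reference_id <- names(msa)[1L]
  if (!reference_id %in% names(msa)) {
    stop("unknown reference id: ", reference_id)
  }
  ref <- strsplit(msa[[reference_id]], "")[[1]]
  marks <- strsplit(conservation$marks, "")[[1]]
  ref_pos <- cumsum(ref != "-")
  keep <- marks %in% c("*", ".") & ref != "-"
  data.frame(
    reference_position = ref_pos[keep],
    residue = ref[keep],
    mark = marks[keep],
    stringsAsFactors = FALSE
  )
}

#' @export
print.msa_conservation <- function(x, ...) {
  width <- 60L
  W <- nchar(x$marks)
  nm <- formatC(names(x$msa), width = max(nchar(names(x$msa))))
  for (i in seq(1L, W, by = width)) {
    j <- min(i + width - 1L, W)
    for (k in seq_along(x$msa)) {
      cat(nm[k], substr(x$msa[[k]], i, j), "\n")
    }
    cat(formatC("", width = max(nchar(names(x$msa)))),
        substr(x$marks, i, j), "\n\n")
  }
  cat(nrow(x$conserved_sites), "conserved column(s) at threshold",
      x$threshold, "\n")
  invisible(x)
}
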
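#' Read sequences from a FASTA file
#'
#' Reads a multi-record FASTA file and normalises the records to the
#' requested alphabet: residues are uppercased, and T/U are interconverted so
#' that RNA records contain U and DNA records contain T. Record ids are the
#' first whitespace-delimited token of each header and must be unique within
#' the file.
#'
#' @param path Path to a FASTA file.
#' @param alphabet One of `"RNA"`, `"DNA"`, `"protein"`. Controls both
#'   validation and T/U normalisation. `N` (nucleotide) and `X` (protein) are
#'   accepted on read but flagged with a warning.
#' @return A named character vector of residue strings (names are record
#'   ids) with attribute `alphabet`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "tacaaa"), tf)
#' read_fasta(tf, "RNA")   # "UACAAA"
#' @export
read_fasta <- function(path, alphabet = c("RNA", "DNA", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  res <- toupper(as.character(set))
  res <- switch(alphabet,
    RNA = chartr("T", "U", res),
    DNA = chartr("U", "T", res),
    protein = res
  )
  allowed <- switch(alphabet,
    RNA = "ACGUN",
    DNA = "ACGTN",
    protein = "ACDEFGHIKLMNPQRSTVWYXBZ*.-"   # gaps allowed: aligned FASTA
  )
  bad <- grepl(sprintf("[^%s]", allowed), res)
  if (any(bad)) {
    .fasta_char_error(path, ids[bad][1L], allowed, alphabet)
  }
  flagged <- if (alphabet == "protein") grepl("X", res, fixed = TRUE)
             else grepl("N", res, fixed = TRUE)
  if (any(flagged)) {
    warning("ambiguous residues (", if (alphabet == "protein") "X" else "N",
            ") in record(s): ", paste(ids[flagged], collapse = ", "))
  }
  if (any(nchar(res) == 0L)) {
    stop("empty sequence for record(s): ",
         paste(ids[nchar(res) == 0L], collapse = ", "))
  }
  names(res) <- ids
  attr(res, "alphabet") <- alphabet
  res
}

# Locate the first offending line to report a parse error with a line number.
.fasta_char_error <- function(path, id, allowed, alphabet) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, ">")
  probe <- toupper(lines)
  probe <- switch(alphabet,
    RNA = chartr("T", "U", probe),
    DNA = chartr("U", "T", probe),
    protein = probe
  )
  hit <- which(body & grepl(sprintf("[^[:space:]%s]", allowed), probe))
  line_no <- if (length(hit)) hit[1L] else NA_integer_
  stop(sprintf(
    "illegal %s character in record '%s' (line %s of %s)",
    alphabet, id, line_no, path), call. = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @param width Line width for wrapping (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read per-position coverage tracks
#'
#' The native dialect is a TSV with columns `substrate_id`, `position`
#' (1-based), `coverage`; a header line is detected automatically. Positions
#' absent from the file get coverage 0 (dense tracks). A 0-based half-open
#' bedGraph dialect is accepted behind `format = "bedgraph"`.
#'
#' @param path Input path.
#' @param format `"tsv"` (native) or `"bedgraph"`.
#' @param lengths Optional named integer vector giving the full length of
#'   each substrate; defaults to the maximum position seen per substrate.
#' @return A named list of non-negative integer vectors, one per substrate,
#'   where element `i` is the coverage of 1-based position `i`.
#' @export
read_coverage <- function(path, format = c("tsv", "bedgraph"), lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("coverage file not found: ", path)
  if (format == "tsv") .read_coverage_tsv(path, lengths)
  else .read_coverage_bedgraph(path, lengths)
}

.read_coverage_tsv <- function(path, lengths) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty coverage file: ", path)
  f1 <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_header <- length(f1) >= 3L &&
    (is.na(suppressWarnings(as.numeric(f1[2]))) ||
     is.na(suppressWarnings(as.numeric(f1[3]))))
  df <- utils::read.delim(path, header = has_header,
                          colClasses = c("character", "numeric", "numeric"))
  names(df) <- c("substrate_id", "position", "coverage")
  if (any(df$position != as.integer(df$position)) ||
      any(df$coverage != as.integer(df$coverage))) {
    stop("non-integer position or coverage in ", path)
  }
  if (any(df$position <= 0)) stop("position <= 0 in ", path, " (TSV is 1-based)")
  if (any(df$coverage < 0)) stop("negative coverage in ", path)
  if (anyDuplicated(df[c("substrate_id", "position")])) {
    stop("duplicate (substrate_id, position) rows in ", path)
  }
  .densify(df, lengths)
}

.read_coverage_bedgraph <- function(path, lengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(
    substrate_id = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),   # already 1-based closed after import
    end = BiocGenerics::end(gr),
    coverage = gr$score,
    stringsAsFactors = FALSE
  )
  if (any(df$coverage != as.integer(df$coverage)) || any(df$coverage < 0)) {
    stop("non-integer or negative coverage in ", path)
  }
  # overlap check per substrate
  for (id in unique(df$substrate_id)) {
    d <- df[df$substrate_id == id, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])) {
      stop("overlapping bedGraph intervals for substrate ", id)
    }
  }
  long <- data.frame(
    substrate_id = rep(df$substrate_id, df$end - df$start + 1L),
    position = unlist(Map(seq.int, df$start, df$end), use.names = FALSE),
    coverage = rep(df$coverage, df$end - df$start + 1L),
    stringsAsFactors = FALSE
  )
  .densify(long, lengths)
}

.densify <- function(df, lengths) {
  ids <- unique(df$substrate_id)
  out <- lapply(ids, function(id) {
    d <- df[df$substrate_id == id, , drop = FALSE]
    L <- if (!is.null(lengths) && id %in% names(lengths)) {
      as.integer(lengths[[id]])
    } else {
      max(d$position)
    }
    if (any(d$position > L)) {
      stop("position beyond declared length ", L, " for substrate ", id)
    }
    v <- integer(L)
    v[d$position] <- as.integer(d$coverage)
    v
  })
  names(out) <- ids
  out
}

#' Write coverage tracks as TSV
#'
#' Writes the dense track (every position, including zeros) in the native
#' three-column dialect understood by [read_coverage()].
#'
#' @param tracks Named list of integer vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coverage <- function(tracks, path) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  df <- data.frame(
    substrate_id = rep(names(tracks), lengths(tracks)),
    position = unlist(lapply(tracks, seq_along), use.names = FALSE),
    coverage = unlist(tracks, use.names = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called cleavage sites as BED6
#'
#' A site called at 1-based position n becomes `chromStart = n - 1`,
#' `chromEnd = n` (0-based half-open). The BED score is
#' `min(1000, round(RCI * 100))`; strand is `"+"` (the substrates are
#' single-stranded RNAs).
#'
#' @param sites Data frame with columns `substrate_id`, `position`, `rci`
#'   (as returned by [call_sites()] or [top_k_sites()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sites_bed <- function(sites, path) {
  if (nrow(sites) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  stopifnot(all(c("substrate_id", "position", "rci") %in% names(sites)))
  bed <- data.frame(
    chrom = sites$substrate_id,
    start = sites$position - 1L,
    end = sites$position,
    name = paste0("site_", seq_len(nrow(sites))),
    score = pmin(1000, round(sites$rci * 100)),
    strand = "+"
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
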
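#' Replace zero coverage with a pseudocount of 1
#'
#' The RCI ratio cov(n)/cov(n-1) must be defined at every position, so each
#' position with zero coverage is set to 1. This is zero-replacement, not
#' add-one: positive values are unchanged, and the operation is idempotent.
#'
#' @param track Non-negative integer coverage vector.
#' @return Integer vector with all values >= 1.
#' @examples
#' apply_pseudocount(c(0L, 5L, 0L))  # 1 5 1
#' @export
apply_pseudocount <- function(track) {
  stopifnot(is.numeric(track), all(track >= 0))
  track <- as.integer(track)
  track[track == 0L] <- 1L
  track
}

#' Compute the relative coverage increase (RCI) at every position
#'
#' RCI at position n (n >= 2) is the coverage of the nth position divided by
#' the coverage of the (n-1)th position, computed on a pseudocounted track.
#' A coverage step-up marks the 5' end of a cleavage-generated fragment.
#'
#' @param track Pseudocounted coverage vector (all values >= 1; apply
#'   [apply_pseudocount()] first).
#' @param substrate_id Substrate identifier carried into the records.
#' @return Data frame with columns `substrate_id`, `position` (2..L),
#'   `cov_n`, `cov_nm1`, `rci`, in position order.
#' @export
compute_rci <- function(track, substrate_id = "substrate") {
  stopifnot(is.numeric(track), length(track) >= 2)
  if (any(track < 1)) {
    stop("track contains zero coverage; apply_pseudocount() first")
  }
  n <- 2:length(track)
  data.frame(
    substrate_id = substrate_id,
    position = n,
    cov_n = as.integer(track[n]),
    cov_nm1 = as.integer(track[n - 1L]),
    rci = track[n] / track[n - 1L]
  )
}

#' Exclude positions below the per-substrate median coverage
#'
#' Keeps a record only if its coverage cov_n is greater than or equal to the
#' median of the substrate's (pseudocounted) coverage distribution, taken
#' over all L positions. The boundary is inclusive; for even L the median is
#' the mean of the two central order statistics.
#'
#' @param records RCI records from [compute_rci()].
#' @param track The same substrate's pseudocounted coverage vector.
#' @return The surviving subset of `records`.
#' @export
filter_by_median <- function(records, track) {
  stopifnot(is.data.frame(records))
  if (any(track < 1)) {
    stop("track contains zero coverage; apply_pseudocount() first")
  }
  if (nrow(records)) {
    if (max(records$position) > length(track) ||
        !all(records$cov_n == track[records$position])) {
      stop("records do not match the supplied track ",
           "(substrate mismatch or track not pseudocounted)")
    }
  }
  med <- stats::median(track)
  records[records$cov_n >= med, , drop = FALSE]
}

#' Call cleavage sites and attach their sequence windows
#'
#' Keeps median-filtered records whose RCI meets the threshold, then
#' attaches the window of `flank` bases on each side of the step-up base
#' (an 11-mer at the default flank of 5, with the step-up base at window
#' index 6). Sites whose full window does not fit inside the substrate are
#' dropped with a message; windows are not padded, so all returned windows
#' have equal width.
#'
#' @param records Median-filtered RCI records.
#' @param substrate_seq The substrate's RNA sequence (string).
#' @param rci_threshold Minimum RCI, inclusive (default 3.0).
#' @param flank Bases on each side of the step-up base (default 5).
#' @return Data frame of called sites with an added `window` column.
#' @export
call_sites <- function(records, substrate_seq, rci_threshold = 3.0,
                       flank = 5L) {
  stopifnot(is.data.frame(records), is.character(substrate_seq),
            length(substrate_seq) == 1L)
  L <- nchar(substrate_seq)
  keep <- records[records$rci >= rci_threshold, , drop = FALSE]
  fits <- keep$position - flank >= 1L & keep$position + flank <= L
  if (any(!fits)) {
    message(sum(!fits), " site(s) dropped: window would extend past the ",
            "substrate ends (positions ",
            paste(keep$position[!fits], collapse = ", "), ")")
  }
  keep <- keep[fits, , drop = FALSE]
  keep$window <- if (nrow(keep)) {
    substring(substrate_seq, keep$position - flank, keep$position + flank)
  } else {
    character(0)
  }
  keep
}

#' Rank pooled sites and keep the top k
#'
#' Sites from all substrates are pooled and sorted by RCI, descending; ties
#' are broken by substrate id then position (both ascending). The first `k`
#' are returned with ranks 1..k; if fewer than `k` sites exist, all are
#' returned with a warning.
#'
#' @param sites Data frame of called sites (pooled across substrates).
#' @param k Number of sites to keep (default 10).
#' @return The ranked subset with an added `rank` column.
#' @export
top_k_sites <- function(sites, k = 10L) {
  stopifnot(is.data.frame(sites))
  if (nrow(sites) == 0L) {
    sites$rank <- integer(0)
    return(sites)
  }
  o <- order(-sites$rci, sites$substrate_id, sites$position)
  out <- utils::head(sites[o, , drop = FALSE], k)
  if (nrow(out) < k) {
    warning("only ", nrow(out), " site(s) available for top-", k, " ranking")
  }
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Detect the recognition sequence end-to-end
#'
#' Runs the full procedure on matched substrate sequences and coverage
#' tracks: pseudocount, RCI, per-substrate median filter, threshold site
#' calling with window extraction, pooled top-k ranking, and the motif model
#' (PWM, per-column information content, IUPAC consensus) of the top
#' windows. The cut site is annotated between window columns `flank` and
#' `flank + 1` (U^ACAAA-style).
#'
#' @param substrates Named character vector of RNA sequences (e.g. from
#'   [read_fasta()] or [make_fixture_panel()]).
#' @param tracks Named list of coverage vectors; every name must also name a
#'   substrate, otherwise the call is fatal and the missing ids are listed.
#' @param rci_threshold Minimum RCI, inclusive (default 3.0).
#' @param flank Window flank (default 5).
#' @param top_k Number of top sites aligned into the motif (default 10).
#' @param min_fraction Consensus frequency threshold (see
#'   [iupac_consensus()]).
#' @param correction Apply the small-sample information-content correction
#'   (default off; see [build_motif()]).
#' @return An object of class `cleavage_report`: a list with the resolved
#'   `params`, per-substrate site tables (`site_tables`), pooled called
#'   sites (`sites`), the ranked `top` table, `motif` (a `motif_model` or
#'   NULL), `consensus` and `cut_annotation` (NULL when no site passes both
#'   filters).
#' @export
detect_recognition_sequence <- function(substrates, tracks,
                                        rci_threshold = 3.0, flank = 5L,
                                        top_k = 10L, min_fraction = 0.5,
                                        correction = FALSE) {
  stopifnot(is.character(substrates), !is.null(names(substrates)),
            is.list(tracks), !is.null(names(tracks)))
  missing_ids <- setdiff(names(tracks), names(substrates))
  if (length(missing_ids)) {
    stop("substrate(s) named in coverage but absent from FASTA: ",
         paste(missing_ids, collapse = ", "))
  }
  site_tables <- list()
  for (id in names(tracks)) {
    tr <- apply_pseudocount(tracks[[id]])
    if (length(tr) != nchar(substrates[[id]])) {
      stop("coverage track length ", length(tr), " does not match substrate ",
           id, " length ", nchar(substrates[[id]]))
    }
    rec <- compute_rci(tr, substrate_id = id)
    rec <- filter_by_median(rec, tr)
    site_tables[[id]] <- call_sites(rec, substrates[[id]],
                                    rci_threshold = rci_threshold,
                                    flank = flank)
  }
  sites <- do.call(rbind, c(site_tables, list(make.row.names = FALSE)))
  if (is.null(sites)) {
    sites <- data.frame(substrate_id = character(), position = integer(),
                        cov_n = integer(), cov_nm1 = integer(),
                        rci = numeric(), window = character())
  }
  top <- suppressWarnings(top_k_sites(sites, k = top_k))
  motif <- NULL
  consensus <- NULL
  cut_annotation <- NULL
  if (nrow(top) > 0L) {
    motif <- build_motif(top$window, cut_offset = flank,
                         correction = correction,
                         min_fraction = min_fraction)
    consensus <- motif$consensus
    cut_annotation <- paste0(substring(consensus, 1L, flank), "^",
                             substring(consensus, flank + 1L))
  }
  structure(list(
    version = "1.0",
    params = list(rci_threshold = rci_threshold, flank = flank,
                  top_k = top_k, min_fraction = min_fraction,
                  correction = correction),
    site_tables = site_tables,
    sites = sites,
    top = top,
    motif = motif,
    consensus = consensus,
    cut_annotation = cut_annotation
  ), class = "cleavage_report")
}

#' Write a cleavage report as JSON
#'
#' The report is serialised with a schema version and the full resolved
#' parameter set; identical inputs and parameters give byte-identical files
#' (no timestamps).
#'
#' @param report A `cleavage_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cleavage_report"))
  ser <- list(
    schema_version = report$version,
    params = report$params,
    n_sites = nrow(report$sites),
    sites = report$sites,
    top = report$top,
    consensus = report$consensus,
    cut_annotation = report$cut_annotation
  )
  if (!is.null(report$motif)) {
    m <- report$motif
    ser$motif <- list(
      counts = as.data.frame(m$counts),
      probs = as.data.frame(m$probs),
      info = m$info,
      consensus = m$consensus,
      cut_offset = m$cut_offset,
      n_windows = m$n_windows
    )
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' @export
print.cleavage_report <- function(x, ...) {
  cat("Cleavage-site report (schema", x$version, ")\n")
  cat("  substrates analysed:", length(x$site_tables), "\n")
  cat("  sites called:", nrow(x$sites), "\n")
  if (!is.null(x$consensus)) {
    cat("  top-", x$params$top_k, " consensus: ", x$consensus,
        "  cut: ", x$cut_annotation, "\n", sep = "")
  } else {
    cat("  no sites passed both filters; consensus: NULL\n")
  }
  invisible(x)
}
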
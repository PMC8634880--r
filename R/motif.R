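# IUPAC nucleotide codes keyed by their sorted base set (RNA form)
.IUPAC_FROM_SET <- c(
  A = "A", C = "C", G = "G", U = "U",
  AC = "M", AG = "R", AU = "W", CG = "S", CU = "Y", GU = "K",
  ACG = "V", ACU = "H", AGU = "D", CGU = "B", ACGU = "N"
)

#' Build a position weight matrix from aligned windows
#'
#' Tallies per-column base counts over equal-width RNA windows, converts to
#' column-stochastic probabilities, and computes per-column information
#' content in bits: `info[j] = 2 + sum_b p[b,j] * log2(p[b,j])` with
#' `0 * log(0) = 0`. No small-sample correction is applied by default (the
#' optional correction subtracts `e_n = 3 / (2 * ln(2) * N)` per column,
#' clamped at 0).
#'
#' @param windows Character vector of equal-width windows over ACGU (T is
#'   normalised to U).
#' @param cut_offset The cut lies between window columns `cut_offset` and
#'   `cut_offset + 1` (default 5, matching an 11-nt window whose step-up
#'   base sits at column 6).
#' @param correction Apply the small-sample correction (default FALSE).
#' @param min_fraction Consensus threshold passed to [iupac_consensus()].
#' @return An object of class `motif_model`: list with `counts` (4 x W
#'   integer matrix, rows A, C, G, U), `probs`, `info`, `consensus`,
#'   `cut_offset`, `n_windows`.
#' @examples
#' m <- build_motif(rep("GUACAAAGCAU", 10))
#' m$info          # all exactly 2 bits
#' m$consensus     # "GUACAAAGCAU"
#' @export
build_motif <- function(windows, cut_offset = 5L, correction = FALSE,
                        min_fraction = 0.5) {
  stopifnot(is.character(windows), length(windows) >= 1L)
  windows <- toupper(chartr("T", "U", windows))
  W <- unique(nchar(windows))
  if (length(W) != 1L) stop("windows have unequal widths")
  if (any(grepl("[^ACGU]", windows))) {
    stop("illegal character in windows (RNA alphabet ACGU required)")
  }
  N <- length(windows)
  mat <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
                nrow = N, byrow = TRUE)
  bases <- c("A", "C", "G", "U")
  counts <- vapply(seq_len(W), function(j) {
    tabulate(factor(mat[, j], levels = bases), nbins = 4L)
  }, integer(4))
  dimnames(counts) <- list(bases, seq_len(W))
  probs <- counts / N
  plogp <- ifelse(probs > 0, probs * log2(probs), 0)
  info <- 2 + colSums(plogp)
  if (correction) {
    info <- pmax(0, info - 3 / (2 * log(2) * N))
  }
  model <- structure(list(counts = counts, probs = probs, info = info,
                          consensus = NULL, cut_offset = as.integer(cut_offset),
                          n_windows = N),
                     class = "motif_model")
  model$consensus <- iupac_consensus(model, min_fraction = min_fraction)
  model
}

#' IUPAC consensus of a motif model
#'
#' Per column, the smallest IUPAC code covering all bases with frequency at
#' or above `min_fraction`. If no base reaches `min_fraction`, bases are
#' added in descending frequency (ties broken alphabetically) until their
#' cumulative frequency reaches 0.75, and the smallest code covering that
#' set is used.
#'
#' @param model A `motif_model`, or a 4 x W column-stochastic matrix with
#'   rows A, C, G, U.
#' @param min_fraction Frequency threshold (default 0.5).
#' @return IUPAC string of length W.
#' @export
iupac_consensus <- function(model, min_fraction = 0.5) {
  probs <- if (inherits(model, "motif_model")) model$probs else model
  stopifnot(is.matrix(probs), nrow(probs) == 4L)
  bases <- c("A", "C", "G", "U")
  code_for <- function(set) {
    .IUPAC_FROM_SET[[paste(sort(set), collapse = "")]]
  }
  out <- vapply(seq_len(ncol(probs)), function(j) {
    p <- probs[, j]
    names(p) <- bases
    hi <- bases[p >= min_fraction]
    if (length(hi)) return(code_for(hi))
    o <- order(-p, bases)
    cum <- cumsum(p[o])
    take <- seq_len(which(cum >= 0.75)[1L])
    code_for(bases[o][take])
  }, character(1))
  paste(out, collapse = "")
}

#' Render a sequence logo of a motif model
#'
#' Draws a stacked-letter logo: each column's total stack height is its
#' information content in bits (max 2 for RNA), letters are stacked in
#' increasing frequency order with heights proportional to their
#' frequencies, and a dashed vertical line marks the cut site between
#' columns `cut_offset` and `cut_offset + 1`.
#'
#' @param model A `motif_model`.
#' @param path Optional output file; the device is chosen from the
#'   extension (`.png`, `.svg`, `.pdf`). With `path = NULL`, draws on the
#'   current device.
#' @param width,height Device size in inches.
#' @return Invisibly, `path` (or NULL).
#' @export
render_logo <- function(model, path = NULL, width = 7, height = 3) {
  stopifnot(inherits(model, "motif_model"))
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    switch(ext,
      png = grDevices::png(path, width = width, height = height,
                           units = "in", res = 150),
      svg = grDevices::svg(path, width = width, height = height),
      pdf = grDevices::pdf(path, width = width, height = height),
      stop("unsupported logo format: .", ext, " (use png, svg or pdf)")
    )
    on.exit(grDevices::dev.off())
  }
  W <- ncol(model$probs)
  cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", U = "#D62839")
  op <- graphics::par(mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0.5, W + 0.5), ylim = c(0, 2))
  graphics::axis(1, at = seq_len(W))
  graphics::axis(2, at = 0:2, las = 1)
  graphics::title(xlab = "position in window", ylab = "bits")
  one_h <- graphics::strheight("A", cex = 1)
  for (j in seq_len(W)) {
    p <- model$probs[, j]
    o <- order(p)                       # draw small letters first (bottom)
    y0 <- 0
    for (b in rownames(model$probs)[o]) {
      h <- model$probs[b, j] * model$info[j]
      if (h <= 0) next
      graphics::text(j, y0 + h / 2, b, col = cols[[b]],
                     cex = max(h / one_h, 0.01), font = 2)
      y0 <- y0 + h
    }
  }
  graphics::abline(v = model$cut_offset + 0.5, lty = 2, col = "grey30")
  invisible(path)
}

#' @export
print.motif_model <- function(x, ...) {
  cat("Motif model over", x$n_windows, "window(s), width",
      ncol(x$probs), "\n")
  cat("  consensus:", x$consensus, "\n")
  cat("  cut between columns", x$cut_offset, "and", x$cut_offset + 1L, "\n")
  cat("  information (bits):",
      paste(formatC(x$info, digits = 2, format = "f"), collapse = " "), "\n")
  invisible(x)
}
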
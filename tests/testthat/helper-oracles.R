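# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package: plain loops and
# enumeration only.

# Pseudocount -> RCI -> median filter -> threshold, with direct loops.
# Returns per-position (n >= 2) rci values and the kept/dropped decision.
oracle_rci_pipeline <- function(track, rci_threshold = 3.0) {
  L <- length(track)
  pc <- numeric(L)
  for (i in 1:L) pc[i] <- if (track[i] == 0) 1 else track[i]
  s <- sort(pc)
  med <- if (L %% 2 == 1) s[(L + 1) / 2] else (s[L / 2] + s[L / 2 + 1]) / 2
  pos <- integer(0); rci <- numeric(0); kept <- logical(0)
  for (n in 2:L) {
    r <- pc[n] / pc[n - 1]
    pos <- c(pos, n)
    rci <- c(rci, r)
    kept <- c(kept, pc[n] >= med && r >= rci_threshold)
  }
  list(position = pos, rci = rci, kept = kept, median = med)
}

# IUPAC base sets (DNA form) for the brute-force scanner
.oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Position-by-position overlapping motif matcher (sense strand, N in the
# subject matches nothing). Returns 1-based start positions.
oracle_scan <- function(seq, motif) {
  seq <- toupper(chartr("Uu", "Tt", seq))
  motif <- toupper(chartr("Uu", "Tt", motif))
  sc <- strsplit(seq, "")[[1]]
  mc <- strsplit(motif, "")[[1]]
  L <- length(sc); m <- length(mc)
  hits <- integer(0)
  if (m > L) return(hits)
  for (s in 1:(L - m + 1)) {
    ok <- TRUE
    for (k in 1:m) {
      if (!(sc[s + k - 1] %in% .oracle_iupac[[mc[k]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# Exhaustive enumeration of all global alignments with affine gaps
# (gap of length L costs gap_open + L * gap_extend); returns the optimal
# score. Feasible for sequences of length <= ~7.
oracle_align_score <- function(a, b, mat, gap_open = 10, gap_extend = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  ai <- match(A, rownames(mat)); bi <- match(B, colnames(mat))
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i > na && j > nb) {
      if (sc > best) best <<- sc
      return(NULL)
    }
    if (i <= na && j <= nb) rec(i + 1L, j + 1L, sc + mat[ai[i], bi[j]], 0L)
    if (i <= na) rec(i + 1L, j,
                     sc - if (last == 1L) gap_extend else gap_open + gap_extend,
                     1L)
    if (j <= nb) rec(i, j + 1L,
                     sc - if (last == 2L) gap_extend else gap_open + gap_extend,
                     2L)
    NULL
  }
  rec(1L, 1L, 0, 0L)
  best
}

# Random RNA string helper
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

# A tiny two-substrate input for end-to-end tests: one clean planted site
# per substrate, deep deterministic-ish coverage.
tiny_panel <- function(seed = 42L, efficiency = 1.0) {
  enz <- enzyme_model(efficiency = c(UACAAA = efficiency),
                      background_break_rate = 0)
  subs <- list(
    s1 = generate_substrate(200L, planted = data.frame(position = 60L,
                                                       variant = "UACAAA"),
                            seed = seed, avoid = "UACAAA", id = "s1"),
    s2 = generate_substrate(250L, planted = data.frame(position = 120L,
                                                       variant = "UACAAA"),
                            seed = seed + 1L, avoid = "UACAAA", id = "s2")
  )
  tracks <- lapply(subs, function(s)
    digest_and_sequence(s, enz, n_molecules = 500L, read_length = 40L,
                        seed = seed + 7L)$coverage)
  substrates <- vapply(subs, `[[`, character(1), "residues")
  list(substrates = substrates, tracks = tracks, panel = subs)
}
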
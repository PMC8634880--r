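#' Default enzyme model for the simulator
#'
#' Per-molecule cleavage probabilities for the recognition-motif variants of
#' a MazF-like six-base cutter, plus a small per-position background breakage
#' rate. The numeric values are simulator defaults chosen to respect the
#' enzyme's qualitative preference ordering (UACAAA strongest; UACUAA weaker;
#' UACGAA and UACCAA weaker still; sixth-base variants barely cut); they are
#' configuration, not measured constants, and every simulator entry point
#' takes the model as an argument.
#'
#' @param efficiency Named numeric vector mapping 6-mer RNA variants to
#'   per-molecule cleavage probabilities in \[0, 1\].
#' @param background_break_rate Per-position, per-molecule probability of a
#'   nonspecific break, in \[0, 1).
#' @return An object of class `enzyme_model`.
#' @export
enzyme_model <- function(efficiency = c(
                           UACAAA = 0.9, UACUAA = 0.4, UACGAA = 0.3,
                           UACCAA = 0.1, UACAAC = 0.02, UACAAG = 0.02,
                           UACAAU = 0.02),
                         background_break_rate = 1e-4) {
  stopifnot(is.numeric(efficiency), !is.null(names(efficiency)),
            all(efficiency >= 0 & efficiency <= 1),
            all(nchar(names(efficiency)) == 6L),
            all(grepl("^[ACGU]+$", names(efficiency))),
            is.numeric(background_break_rate),
            background_break_rate >= 0, background_break_rate < 1)
  structure(list(efficiency = efficiency,
                 background_break_rate = background_break_rate),
            class = "enzyme_model")
}

#' Generate a substrate RNA with planted motif variants
#'
#' Background residues are drawn i.i.d. at the requested GC fraction; the
#' planted 6-mer variants are then written over the background. A planted
#' site is specified by the 1-based position `n` of its step-up base (the
#' base whose coverage increases when the site is cut): the variant occupies
#' positions `n-1 ... n+4`, i.e. cleavage falls between the first and second
#' variant base (U^ACAAA for the canonical motif). Accidental occurrences of
#' any motif in `avoid` outside the planted windows are removed by
#' resampling the offending background positions, so planted sites are the
#' only true motif instances.
#'
#' @param length Substrate length in nt (>= 50).
#' @param gc_fraction Background GC fraction in (0, 1).
#' @param planted Data frame with columns `position` (step-up base, 1-based)
#'   and `variant` (6-mer over ACGU), or an empty data frame / NULL.
#' @param seed Integer RNG seed; the result is deterministic given the seed.
#' @param avoid Character vector of 6-mers that must not occur outside
#'   planted windows (typically `names(enzyme$efficiency)`). Defaults to the
#'   planted variants.
#' @param id Record id for the substrate.
#' @return An object of class `substrate_rna`: a list with elements `id`,
#'   `residues` (RNA string) and `planted` (the input data frame).
#' @export
generate_substrate <- function(length, gc_fraction = 0.5, planted = NULL,
                               seed = 1L, avoid = NULL, id = "substrate") {
  stopifnot(length >= 50, gc_fraction > 0, gc_fraction < 1)
  planted <- .normalize_planted(planted)
  if (nrow(planted)) {
    if (any(planted$position < 7L) || any(planted$position > length - 6L)) {
      stop("planted site position out of bounds: sites must lie at least 7 ",
           "bases from the 5' end and 6 from the 3' end")
    }
    win_start <- planted$position - 1L
    win_end <- planted$position + 4L
    o <- order(win_start)
    if (nrow(planted) > 1L &&
        any(win_start[o][-1L] <= win_end[o][-nrow(planted)])) {
      stop("overlapping planted windows")
    }
  }
  avoid <- unique(c(avoid, planted$variant))
  base_p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
              G = gc_fraction / 2, U = (1 - gc_fraction) / 2)
  res <- with_seed(seed, {
    chars <- sample(names(base_p), length, replace = TRUE, prob = base_p)
    for (i in seq_len(nrow(planted))) {
      chars[(planted$position[i] - 1L):(planted$position[i] + 4L)] <-
        strsplit(planted$variant[i], "")[[1]]
    }
    protected <- logical(length)
    for (i in seq_len(nrow(planted))) {
      protected[(planted$position[i] - 1L):(planted$position[i] + 4L)] <- TRUE
    }
    for (iter in seq_len(200L)) {
      seqstr <- paste(chars, collapse = "")
      extra <- .accidental_hits(seqstr, avoid, planted)
      if (length(extra) == 0L) break
      for (s in extra) {
        idx <- s:(s + 5L)
        idx <- idx[!protected[idx]]
        chars[idx] <- sample(names(base_p), length(idx),
                             replace = TRUE, prob = base_p)
      }
    }
    seqstr <- paste(chars, collapse = "")
    if (length(.accidental_hits(seqstr, avoid, planted)) > 0L) {
      stop("could not remove accidental motif occurrences; ",
           "sequence too constrained")
    }
    seqstr
  })
  structure(list(id = id, residues = res, planted = planted),
            class = "substrate_rna")
}

.normalize_planted <- function(planted) {
  if (is.null(planted) || (is.data.frame(planted) && nrow(planted) == 0L)) {
    return(data.frame(position = integer(), variant = character()))
  }
  stopifnot(is.data.frame(planted),
            all(c("position", "variant") %in% names(planted)))
  planted$position <- as.integer(planted$position)
  planted$variant <- toupper(chartr("T", "U", planted$variant))
  stopifnot(all(nchar(planted$variant) == 6L),
            all(grepl("^[ACGU]+$", planted$variant)))
  planted[order(planted$position), c("position", "variant"), drop = FALSE]
}

# 1-based start positions of avoid-motif occurrences that are not planted
.accidental_hits <- function(seqstr, avoid, planted) {
  planted_starts <- planted$position - 1L
  subj <- Biostrings::BStringSet(seqstr)[[1]]
  out <- integer()
  for (m in avoid) {
    hits <- BiocGenerics::start(Biostrings::matchPattern(m, subj))
    keep <- !(hits %in% planted_starts[planted$variant == m])
    out <- c(out, hits[keep])
  }
  sort(unique(out))
}

#' Simulate digestion and 5'-anchored sequencing of one substrate
#'
#' For each molecule, every planted site is cleaved independently with the
#' model probability of its variant (the cut falls immediately before the
#' step-up base), and every other position breaks with the background rate.
#' Each resulting fragment is sequenced exactly once as a single-end,
#' 5'-anchored read covering its first `min(read_length, fragment_length)`
#' positions. Coverage is the per-position count of covering reads.
#'
#' @param substrate A `substrate_rna` object from [generate_substrate()].
#' @param enzyme An `enzyme_model`. Variants absent from the efficiency map
#'   (e.g. planted decoys) are never specifically cleaved.
#' @param n_molecules Number of substrate molecules digested.
#' @param read_length Read length in nt.
#' @param seed Integer RNG seed; deterministic given the seed.
#' @return A list with elements `coverage` (integer vector, 1-based),
#'   `reads` (data frame: `molecule`, `start`, `length`, `fragment_length`,
#'   one row per fragment/read) and the echoed parameters.
#' @export
digest_and_sequence <- function(substrate, enzyme, n_molecules = 5000L,
                                read_length = 150L, seed = 1L) {
  stopifnot(inherits(substrate, "substrate_rna"),
            inherits(enzyme, "enzyme_model"),
            n_molecules >= 1, read_length >= 1)
  L <- nchar(substrate$residues)
  planted <- substrate$planted
  eff <- enzyme$efficiency[planted$variant]
  eff[is.na(eff)] <- 0
  rate <- enzyme$background_break_rate

  sim <- with_seed(seed, {
    cut_mol <- integer(0)
    cut_pos <- integer(0)
    # specific cleavage at planted sites
    for (i in seq_len(nrow(planted))) {
      hit <- which(rbinom(n_molecules, 1L, eff[i]) == 1L)
      cut_mol <- c(cut_mol, hit)
      cut_pos <- c(cut_pos, rep.int(planted$position[i], length(hit)))
    }
    # background breaks: exact i.i.d. Bernoulli over (molecule, position)
    # cells via a binomial total plus a uniform subset of distinct cells
    elig <- setdiff(2:L, planted$position)
    if (rate > 0 && length(elig) > 0L) {
      ncell <- as.numeric(n_molecules) * length(elig)
      k <- rbinom(1L, ncell, rate)
      if (k > 0L) {
        cell <- sample(ncell, k)
        cut_mol <- c(cut_mol, as.integer((cell - 1) %/% length(elig)) + 1L)
        cut_pos <- c(cut_pos, elig[as.integer((cell - 1) %% length(elig)) + 1L])
      }
    }
    list(mol = cut_mol, pos = cut_pos)
  })

  # fragment bookkeeping: every molecule starts a fragment at position 1
  mol <- c(seq_len(n_molecules), sim$mol)
  pos <- c(rep.int(1L, n_molecules), sim$pos)
  o <- order(mol, pos)
  mol <- mol[o]; pos <- pos[o]
  n <- length(mol)
  last_in_mol <- c(mol[-1L] != mol[-n], TRUE)
  frag_end <- ifelse(last_in_mol, L, c(pos[-1L], 0L) - 1L)
  frag_len <- frag_end - pos + 1L
  rlen <- pmin(read_length, frag_len)

  adds <- tabulate(pos, nbins = L)
  subs <- tabulate(pos + rlen, nbins = L + 1L)
  coverage <- as.integer(cumsum(adds - subs[seq_len(L)]))

  list(coverage = coverage,
       reads = data.frame(molecule = mol, start = pos, length = rlen,
                          fragment_length = frag_len),
       n_molecules = n_molecules, read_length = read_length, seed = seed)
}

# Planted-site roster for the eight-substrate panel. Step-up positions are
# placed > read_length from the 5' end and from each other so each site's
# upstream coverage is background-dominated.
.panel_roster <- function() {
  list(
    "500-2"  = list(length = 533L,  sites = data.frame(
      position = c(200L, 400L), variant = c("UACAAA", "UACUAA"))),
    "1000-1" = list(length = 1033L, sites = data.frame(
      position = c(200L, 500L, 800L),
      variant = c("UACAAA", "UACAAA", "UACGAA"))),
    "1000-2" = list(length = 1033L, sites = data.frame(
      position = c(300L, 700L, 950L),
      variant = c("UACAAA", "UACCAA", "GGCGCC"))),
    "1000-3" = list(length = 1033L, sites = data.frame(
      position = c(250L, 600L, 900L),
      variant = c("UACAAA", "UACAAA", "UACUAA"))),
    "1000-4" = list(length = 1033L, sites = data.frame(
      position = c(350L, 750L, 550L),
      variant = c("UACAAA", "UACGAA", "GGCGCC"))),
    "1000-5" = list(length = 1033L, sites = data.frame(
      position = c(400L, 800L), variant = c("UACAAA", "UACAAA"))),
    "1500-1" = list(length = 1533L, sites = data.frame(
      position = c(300L, 700L, 1100L, 1400L),
      variant = c("UACAAA", "UACAAA", "UACAAA", "UACCAA"))),
    "2000-1" = list(length = 2033L, sites = data.frame(
      position = c(400L, 900L, 1400L, 1800L),
      variant = c("UACAAA", "UACAAA", "UACAAA", "UACUAA")))
  )
}

#' Generate the eight-substrate fixture panel
#'
#' Builds eight substrate RNAs of lengths 533, 1033 (x5), 1533 and 2033 nt
#' with a planted-site roster containing strong (UACAAA) and weak (UACUAA,
#' UACGAA, UACCAA) motif instances plus motif-free decoy 6-mers (GGCGCC,
#' absent from the enzyme's efficiency map), digests each substrate, and
#' returns matched coverage tracks together with a ground-truth manifest.
#'
#' @param enzyme An `enzyme_model` (defaults to [enzyme_model()]).
#' @param n_molecules Molecules digested per substrate.
#' @param read_length Read length in nt.
#' @param gc_fraction Background GC fraction.
#' @param seed Master integer seed; per-substrate generation and digestion
#'   seeds are derived from it, and the panel is byte-reproducible given it.
#' @param out_dir Optional directory: if given, writes `panel.fasta`,
#'   `coverage.tsv` and `manifest.json` there.
#' @return A list with `substrates` (named character vector of RNA
#'   sequences), `tracks` (named list of integer coverage vectors),
#'   `panel` (list of `substrate_rna` objects) and `manifest`.
#' @export
make_fixture_panel <- function(enzyme = enzyme_model(), n_molecules = 5000L,
                               read_length = 150L, gc_fraction = 0.5,
                               seed = 1L, out_dir = NULL) {
  roster <- .panel_roster()
  avoid <- names(enzyme$efficiency)
  panel <- vector("list", length(roster))
  tracks <- vector("list", length(roster))
  names(panel) <- names(tracks) <- names(roster)
  for (i in seq_along(roster)) {
    id <- names(roster)[i]
    gen_seed <- (seed %% 1000000L) + i * 1000000L
    dig_seed <- (seed %% 1000000L) + i * 1000000L + 500000L
    panel[[i]] <- generate_substrate(
      length = roster[[i]]$length, gc_fraction = gc_fraction,
      planted = roster[[i]]$sites, seed = gen_seed, avoid = avoid, id = id)
    tracks[[i]] <- digest_and_sequence(
      panel[[i]], enzyme, n_molecules = n_molecules,
      read_length = read_length, seed = dig_seed)$coverage
  }
  substrates <- vapply(panel, `[[`, character(1), "residues")
  attr(substrates, "alphabet") <- "RNA"
  manifest <- list(
    substrates = lapply(panel, function(s)
      list(id = s$id, length = nchar(s$residues),
           planted = s$planted)),
    enzyme = list(efficiency = as.list(enzyme$efficiency),
                  background_break_rate = enzyme$background_break_rate),
    n_molecules = n_molecules, read_length = read_length, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(substrates, file.path(out_dir, "panel.fasta"))
    write_coverage(tracks, file.path(out_dir, "coverage.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(substrates = substrates, tracks = tracks, panel = panel,
       manifest = manifest)
}
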
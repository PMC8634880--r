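---
title: "Mapping endoribonuclease cleavage sites from positional coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping endoribonuclease cleavage sites from positional coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavemap)
```

## The problem

MazF-family toxins are ribosome-independent, sequence-specific
single-stranded RNA endoribonucleases. Determining the recognition motif of
such an enzyme is a small but delicate sequence-analysis problem: digest a
set of substrate RNAs of known sequence, convert the cleavage products to a
sequencing library in which every cleavage event deposits a read 5' end at
the first base of the downstream fragment, and look for positions where
read coverage *steps up*. The motif is then read off the sequence context
of the strongest step-ups. `cleavemap` implements this workflow for the
thermophilic six-base cutter MazF-Da of *Candidatus* Desulforudis
audaxviator, whose recognition sequence is UACAAA cleaved as U^ACAAA, but
everything is parameterised and applies to any enzyme with this library
chemistry.

## The statistic

Let $c_n$ be the read coverage of the $n$th substrate position (1-based).
The **relative coverage increase** at $n \ge 2$ is

$$\mathrm{RCI}(n) = \frac{c_n}{c_{n-1}},$$

computed after a **pseudocount** step that replaces every zero coverage
value with 1 (zero-*replacement*, not add-one, so positive values are
untouched and the operation is idempotent). A position is called a cleavage
site when two criteria hold:

1. $c_n$ is at or above the **median** of the substrate's own coverage
   distribution (taken over all $L$ positions of the pseudocounted track;
   for even $L$, the mean of the two central order statistics); this
   removes low-coverage regions where ratios are unstable;
2. $\mathrm{RCI}(n) \ge 3$.

For each called site the **11-nt window** $n-5 \dots n+5$ is extracted, so
the step-up base sits at window position 6 and the scissile bond falls
between window columns 5 and 6. Sites from all substrates are pooled,
ranked by RCI, and the **top 10** windows are summarised as a position
weight matrix with per-column information content

$$I_j = 2 + \sum_b p_{bj}\,\log_2 p_{bj} \quad \text{bits},$$

and an IUPAC consensus. With clean signal the consensus core at columns
5–10 reads `UACAAA` and is annotated `U^ACAAA`.

### Decisions the statistic's description leaves open

Several details are underdetermined by the verbal description of the
procedure; the package fixes them as follows and exposes each as a
parameter:

* **Threshold inclusivity.** The criterion is stated both as "RCI > 3" and
  as "RCI greater than or equal to 3" in different places of the
  protocol's lineage. The package uses **$\ge 3.0$** (the formal criterion
  form) and exposes `rci_threshold`.
* **Median before or after pseudocounting.** The median is computed on the
  **pseudocounted** track, because pseudocounting precedes the exclusion
  step in the procedure's stated order. On deeply covered tracks the two
  choices rarely differ.
* **Which coverage the median test applies to.** Only $c_n$ (the step-up
  base) is tested, not $c_{n-1}$: the filter excludes *positions*, and the
  position of interest is $n$.
* **Pooling.** Top-k selection is across all substrates jointly — the ten
  aligned windows form one logo, not one per substrate.
* **Ties at the top-k boundary** are broken deterministically by substrate
  id, then position (both ascending).
* **Edge windows** (closer than `flank` to a substrate end) are dropped
  with a message, never padded: logo input must be equal-width.
* **Consensus rule.** A logo is read by eye; a reproducible pipeline needs
  a rule. Per column the smallest IUPAC code covering all bases at
  frequency $\ge$ `min_fraction` (default 0.5) is used; if no base
  reaches it, bases are accumulated in descending frequency (alphabetical
  tie-break) until 0.75 cumulative frequency.
* **Information content** uses no small-sample correction by default
  (10 windows; the logo is interpreted qualitatively). The $e_n = 3/(2 N
  \ln 2)$ correction is available behind `correction = TRUE`.

## The simulator

The deposited raw sequencing data behind this kind of experiment are not
reproducible at desk scale, so the package ships a generative model of the
whole digestion–sequencing process and tests the pipeline by **parameter
recovery** on synthetic truth.

`generate_substrate()` draws an i.i.d. background at a given GC fraction
and writes planted motif variants over it; accidental occurrences of any
motif in the enzyme's efficiency table are resampled away, so the planted
sites are the only true instances. `digest_and_sequence()` then, per
molecule:

* cleaves each planted site independently with the per-variant efficiency
  (the cut falls immediately before the step-up base);
* breaks every other position with a small i.i.d. background rate (this is
  what the median filter and the RCI denominator have to reject);
* sequences **every fragment exactly once** as a single-end, 5'-anchored
  read of `min(read_length, fragment_length)` nt.

Sequencing depth is controlled by `n_molecules` alone — there is no second
sampling layer. This is deliberately the *simplest* model that produces
the characteristic coverage step at a cut site; it does not emulate
end-repair/ligation biases, RT dropout, PCR duplicates, paired ends, or
sequencing error. Passing the recovery tests therefore shows that the
statistic correctly inverts this idealised generative process, not that it
is robust to every artefact of real libraries.

`make_fixture_panel()` builds the standard eight-substrate panel (533,
1033 ×5, 1533 and 2033 nt — the lengths of the artificial RNA mixture used
in this assay family) with a planted roster of 15 strong (UACAAA) sites,
7 weak-variant sites (UACUAA, UACGAA, UACCAA) and motif-free decoy 6-mers
(GGCGCC, absent from the efficiency map). Sites are placed more than one
read length from the 5' end and from each other, so each site's upstream
position is covered only by background fragments.

### Default conditions

The default study conditions are: UACAAA efficiency 0.9, UACUAA 0.4,
UACGAA 0.3, UACCAA 0.1, sixth-base variants 0.02 (a qualitative ordering —
strongest motif first, fourth-base variants weaker, sixth-base variants
nearly uncut — encoded as simulator configuration, not measured
constants); background break rate $10^{-4}$ per position per molecule;
5000 molecules; 150-nt reads. Sequencing depth and mapped read length of
the original experiments are not published, so these are the package's own
realistic choices: 150 nt is a standard short-read length, and 5000
molecules gives site coverages in the thousands against a background of
$\approx 150 \times 5000 \times 10^{-4} = 75$, similar in contrast to the
published coverage plots. All randomness flows from one master seed
through derived per-substrate generation and digestion seeds, so fixtures
are byte-reproducible.

Under these conditions the expected behaviour, verified by the test suite,
is:

* the consensus core equals the planted `UACAAA` (U at window column 5,
  ACAAA at 6–10) in at least 95 of 100 master seeds;
* with nothing planted, fewer than one site per substrate is called on
  average (in practice essentially zero: a false call needs a three-fold
  coverage jump against a background of ~75, which the Poisson-scale
  fluctuations cannot produce).

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere internally; 0-based
  half-open appears only at the BED boundary (`write_sites_bed()`), and
  bedGraph input is converted on read.
* `compute_rci()` refuses tracks containing zeros rather than silently
  pseudocounting: the pseudocount is an explicit, separate step.
* An input with no site passing both filters yields a valid report with an
  empty site table and `NULL` consensus, not an error.
* Coverage TSV is the native track dialect (auditable by eye); bedGraph is
  accepted behind a flag. Duplicate (substrate, position) rows and
  overlapping bedGraph intervals are errors, not silently summed.
* Motif columns with $0 \cdot \log 0$ terms use the convention that the
  term is 0, so a deterministic column is exactly 2 bits and a uniform
  column exactly 0.

## Motif scanning of coding sequences

`scan_cds()` counts coding sequences containing at least one occurrence of
an IUPAC motif. Scanning is **sense-strand only** by default: the enzyme
cleaves single-stranded mRNA, so only the coding strand is biologically
exposed (antisense scanning sits behind `both_strands`). Overlapping
occurrences are counted at every start; `N` in a CDS matches nothing
unless `n_matches_any = TRUE` (conservative default: an ambiguous base is
not evidence of a motif). The matcher is Biostrings'
`vmatchPattern`; the test suite cross-checks it against an independent
position-by-position matcher.

## Conservation displays

`global_align()` wraps Needleman–Wunsch global alignment with affine gaps
(gap of length $L$ costs `gap_open` $+ L \cdot$ `gap_extend`;
EMBOSS-needle-style defaults BLOSUM62/10/0.5). Percent identity is
identical columns over alignment length; percent similarity additionally
counts residue pairs with positive substitution score. Because the tool
and parameters behind published identity/similarity percentages are
usually unstated, such numbers should be treated as approximately
checkable only; the alignment *scores* are exact and are verified against
exhaustive enumeration of all alignments for short peptides. The traceback
(which of several co-optimal alignments is reported) is delegated to the
alignment engine and is deterministic, but the choice among co-optimal
paths does not affect the score and can affect identity percentages only
among equally scoring alignments.

`annotate_msa()` consumes an existing protein MSA (it does not build one:
progressive alignment is out of scope) and marks columns with `*` where
all rows agree without gaps, and `.` where at least 80% of rows fall into
one similarity group. Groups are the conventional strong groups (STA,
NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW) **plus a singleton group per
residue**, so a column that is mostly one residue is conserved-similar
even when the residue belongs to no multi-residue group. Gaps never count
toward a group, and the denominator is the full row count — a heavily
gapped column cannot be called conserved. `conserved_site_report()` maps
marked columns to reference-row positions, skipping columns where the
reference is gapped; this is the table from which mutagenesis candidates
(conserved glycines, prolines, catalytic residues, …) are picked.

The shipped MSA (`inst/extdata/synthetic_mazf_msa.fasta`) is a fully
**synthetic** MazF-like fixture: nine rows with complete conservation
planted at reference positions 6, 15, 18, 20, 25, 26, 36 and 85 (G, P, G,
E, R, P, N, R — the residue classes that are conserved across real MazF
homologs), a gap block, and 35% random divergence elsewhere. Likewise
`synthetic_cds.fasta` is a random 30-record CDS-like set with the motif
planted in a known subset. Neither file contains database sequences;
accession-backed checks against real RefSeq records live in
`analysis/06_external_checks.R` and require network access.

## Problem sizes

The test suite runs the full panel at the default depth (5000 molecules,
eight substrates) over 100 master seeds for recovery and 100 for
specificity, 1000 random tracks against the brute-force RCI oracle, 1000
random sequences against the brute-force scanner, and 1000 random peptide
pairs (length ≤ 7, where exhaustive alignment enumeration is feasible)
against the alignment engine. The analysis scripts use a single master
seed; `scripts/acceptance.R` measures recovery over 20 seeds and
specificity over 10.

## Known limitations

* The simulator's idealisations listed above; in particular, real
  libraries show 3'-end coverage decay and position-dependent ligation
  efficiency that the flat background model does not produce.
* The RCI caller has no significance model — thresholds are fixed, as in
  the protocol it reproduces; no FDR is attached to a called site.
* Differential analysis between enzymes (wild type vs point mutants) is a
  visual comparison of logos, not a formal test.
* The consensus rule is a reasonable reduction of "read the logo by eye"
  but any such rule is a convention; the PWM and information content are
  the primary outputs.

## A worked run

```{r demo, eval = FALSE}
panel <- make_fixture_panel(seed = 1)
report <- detect_recognition_sequence(panel$substrates, panel$tracks)
report
#> Cleavage-site report (schema 1.0 )
#>   substrates analysed: 8
#>   sites called: 19
#>   top-10 consensus: UBSVUACAAAD  cut: UBSVU^ACAAAD
substring(report$consensus, 5, 10)   # "UACAAA"
```

The flank columns (1–4 and 11) are low-information (codes like B, S, V, D
at information near 0 bits), the core columns 5–10 are at 2 bits each, and
the cut annotation places the scissile bond after the U — the planted
truth, recovered.
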
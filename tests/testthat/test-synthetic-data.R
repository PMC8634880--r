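# Exact expected per-position coverage for one substrate with at most one
# planted site, zero background: enumerate the cut / no-cut outcomes.
oracle_expected_cov <- function(L, site_n, eff, read_length) {
  p_cover <- numeric(L)
  cover_from_reads <- function(starts, ends) {
    v <- numeric(L)
    for (k in seq_along(starts)) v[starts[k]:ends[k]] <- 1
    v
  }
  # outcome 1: not cut (prob 1 - eff): single fragment 1..L
  p_cover <- p_cover + (1 - eff) *
    cover_from_reads(1, min(read_length, L))
  # outcome 2: cut (prob eff): fragments 1..site_n-1 and site_n..L
  p_cover <- p_cover + eff *
    cover_from_reads(c(1, site_n),
                     c(min(read_length, site_n - 1),
                       min(site_n + read_length - 1, L)))
  p_cover
}

test_that("substrate generation plants variants at the stated window", {
  s <- generate_substrate(533L, planted = data.frame(position = 100L,
                                                     variant = "UACAAA"),
                          seed = 3L)
  expect_identical(nchar(s$residues), 533L)
  # variant occupies positions n-1 .. n+4
  expect_identical(substr(s$residues, 99L, 104L), "UACAAA")

  s2 <- generate_substrate(533L, planted = data.frame(position = 100L,
                                                      variant = "UACAAA"),
                           seed = 3L)
  expect_identical(s2$residues, s$residues)

  expect_error(generate_substrate(533L,
                                  planted = data.frame(position = 3L,
                                                       variant = "UACAAA"),
                                  seed = 1L),
               "out of bounds")
  expect_error(generate_substrate(533L,
                                  planted = data.frame(position = c(100L, 103L),
                                                       variant = "UACAAA"),
                                  seed = 1L),
               "overlapping")
})

test_that("no accidental occurrences of avoided motifs survive generation", {
  avoid <- c("UACAAA", "UACUAA", "UACGAA", "UACCAA")
  for (seed in 1:10) {
    s <- generate_substrate(1033L, gc_fraction = 0.5,
                            planted = data.frame(position = c(200L, 600L),
                                                 variant = c("UACAAA",
                                                             "UACUAA")),
                            seed = seed, avoid = avoid)
    for (m in avoid) {
      hits <- oracle_scan(s$residues, m)
      planted_starts <- s$planted$position[s$planted$variant == m] - 1L
      expect_identical(hits, planted_starts)
    }
  }
})

test_that("digestion bookkeeping is exact in the degenerate regimes", {
  s <- generate_substrate(120L, planted = data.frame(position = 60L,
                                                     variant = "UACAAA"),
                          seed = 5L, avoid = "UACAAA")
  # no cleavage at all, full-length reads: flat coverage at n_molecules
  enz0 <- enzyme_model(efficiency = c(UACAAA = 0), background_break_rate = 0)
  d0 <- digest_and_sequence(s, enz0, n_molecules = 100L, read_length = 200L,
                            seed = 1L)
  expect_identical(d0$coverage, rep(100L, 120L))

  # complete cleavage at one site: every molecule cut once
  enz1 <- enzyme_model(efficiency = c(UACAAA = 1), background_break_rate = 0)
  d1 <- digest_and_sequence(s, enz1, n_molecules = 100L, read_length = 200L,
                            seed = 1L)
  expect_identical(d1$coverage, rep(100L, 120L))
  expect_identical(nrow(d1$reads), 200L)
  expect_identical(sum(d1$reads$start == 1L), 100L)
  expect_identical(sum(d1$reads$start == 60L), 100L)
})

test_that("observed coverage matches the enumerated expectation at a
           half-efficiency site", {
  s <- generate_substrate(533L, planted = data.frame(position = 300L,
                                                     variant = "UACAAA"),
                          seed = 8L, avoid = "UACAAA")
  enz <- enzyme_model(efficiency = c(UACAAA = 0.5), background_break_rate = 0)
  n <- 10000L
  d <- digest_and_sequence(s, enz, n_molecules = n, read_length = 150L,
                           seed = 21L)
  p <- oracle_expected_cov(533L, 300L, 0.5, 150L)
  se <- sqrt(n * p * (1 - p))
  expect_true(all(abs(d$coverage - n * p) <= 3 * se + 1e-9))
  # in particular the step at the site is binomially sized
  expect_identical(d$coverage[299], 0L)
  expect_lt(abs(d$coverage[300] - n / 2), 3 * sqrt(n * 0.25))
})

test_that("fragment and coverage conservation hold with background breaks", {
  s <- generate_substrate(400L, planted = data.frame(position = 150L,
                                                     variant = "UACAAA"),
                          seed = 2L, avoid = "UACAAA")
  enz <- enzyme_model(efficiency = c(UACAAA = 0.7),
                      background_break_rate = 5e-3)
  d <- digest_and_sequence(s, enz, n_molecules = 300L, read_length = 80L,
                           seed = 4L)
  # per molecule, fragment lengths sum to the substrate length
  frag_sum <- tapply(d$reads$fragment_length, d$reads$molecule, sum)
  expect_true(all(frag_sum == 400L))
  # number of fragments = number of cuts + 1
  n_frags <- tapply(d$reads$fragment_length, d$reads$molecule, length)
  n_cuts <- tapply(d$reads$start, d$reads$molecule,
                   function(s) sum(s != 1L))
  expect_true(all(n_frags == n_cuts + 1L))
  # coverage mass equals total sequenced bases
  expect_identical(sum(d$coverage), sum(d$reads$length))
})

test_that("the site step-up grows with cleavage efficiency", {
  s <- generate_substrate(500L, planted = data.frame(position = 250L,
                                                     variant = "UACAAA"),
                          seed = 6L, avoid = "UACAAA")
  mean_rci <- function(eff) {
    enz <- enzyme_model(efficiency = c(UACAAA = eff),
                        background_break_rate = 1e-4)
    r <- vapply(1:10, function(seed) {
      d <- digest_and_sequence(s, enz, n_molecules = 2000L,
                               read_length = 150L, seed = seed)
      tr <- apply_pseudocount(d$coverage)
      tr[250] / tr[249]
    }, numeric(1))
    mean(r)
  }
  expect_gt(mean_rci(0.8), mean_rci(0.3))
})

test_that("without cleavage the coverage is a step function of read length", {
  s <- generate_substrate(300L, seed = 9L)
  enz <- enzyme_model(efficiency = c(UACAAA = 0), background_break_rate = 0)
  d <- digest_and_sequence(s, enz, n_molecules = 50L, read_length = 120L,
                           seed = 1L)
  expect_identical(d$coverage, c(rep(50L, 120L), rep(0L, 180L)))
})

test_that("the fixture panel reproduces the eight substrate lengths and is
           byte-reproducible", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_fixture_panel(n_molecules = 500L, seed = 7L, out_dir = d1)
  p2 <- make_fixture_panel(n_molecules = 500L, seed = 7L, out_dir = d2)
  expect_identical(unname(nchar(p1$substrates)),
                   c(533L, 1033L, 1033L, 1033L, 1033L, 1033L, 1533L, 2033L))
  expect_identical(unname(lengths(p1$tracks)), unname(nchar(p1$substrates)))
  for (f in c("panel.fasta", "coverage.tsv", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # roster carries strong and weak variants plus motif-free decoys
  planted <- do.call(rbind, lapply(p1$panel, `[[`, "planted"))
  expect_true(all(c("UACAAA", "UACUAA", "UACGAA", "UACCAA", "GGCGCC") %in%
                  planted$variant))
})
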
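test_that("pseudocount replaces zeros with 1 and is idempotent", {
  expect_identical(apply_pseudocount(c(0L, 5L, 0L)), c(1L, 5L, 1L))
  expect_identical(apply_pseudocount(c(3L, 4L)), c(3L, 4L))
  x <- c(0L, 2L, 0L, 9L)
  expect_identical(apply_pseudocount(apply_pseudocount(x)),
                   apply_pseudocount(x))
})

test_that("RCI is the ratio of consecutive coverages, one record per n >= 2", {
  r <- compute_rci(c(10, 10, 40, 40), "s")
  expect_identical(r$position, 2:4)
  expect_equal(r$rci, c(1.0, 4.0, 1.0))

  expect_equal(compute_rci(rep(1, 20))$rci, rep(1.0, 19))
  expect_equal(compute_rci(c(100, 1))$rci, 0.01)
  expect_error(compute_rci(c(3, 0, 2)), "pseudocount")
})

test_that("median filter keeps cov_n >= per-substrate median, inclusive", {
  tr <- c(1L, 1L, 1L, 9L, 9L, 9L)      # even L: median 5
  rec <- compute_rci(tr, "s")
  kept <- filter_by_median(rec, tr)
  expect_identical(kept$cov_n, c(9L, 9L, 9L))

  tr2 <- rep(4L, 10L)                  # all equal: everything kept
  expect_identical(nrow(filter_by_median(compute_rci(tr2), tr2)), 9L)

  tr3 <- c(1L, 2L, 100L)               # odd L: median 2, boundary inclusive
  kept3 <- filter_by_median(compute_rci(tr3), tr3)
  expect_true(2L %in% kept3$cov_n)

  expect_error(filter_by_median(compute_rci(tr3), c(5L, 5L, 5L)), "mismatch")
})

test_that("site calling applies the inclusive RCI threshold and drops edge
           windows", {
  seqstr <- random_rna(30)
  rec <- data.frame(substrate_id = "s", position = c(4L, 10L, 15L, 20L),
                    cov_n = 9L, cov_nm1 = 3L,
                    rci = c(5.0, 3.0, 2.99, 4.0))
  expect_message(
    sites <- call_sites(rec, seqstr, rci_threshold = 3.0, flank = 5L),
    "dropped")
  # rci 3.0 kept (inclusive), 2.99 dropped, position 4 dropped (edge)
  expect_identical(sites$position, c(10L, 20L))
  expect_identical(nchar(sites$window), c(11L, 11L))
  # the step-up base sits at window index 6
  expect_identical(substr(sites$window, 6L, 6L),
                   substring(seqstr, sites$position, sites$position))
})

test_that("top-k ranking sorts by RCI with the stated tie-break", {
  sites <- data.frame(
    substrate_id = c("b", "a", "a", "c"),
    position = c(50L, 80L, 20L, 10L),
    cov_n = 9L, cov_nm1 = 1L,
    rci = c(7.0, 7.0, 9.0, 5.0),
    window = "GGGGGUACAAA")
  top <- top_k_sites(sites, k = 3L)
  expect_identical(top$rank, 1:3)
  expect_identical(top$substrate_id, c("a", "a", "b"))  # tie: "a" before "b"
  expect_identical(top$position[2:3], c(80L, 50L))
  expect_warning(top_k_sites(sites, k = 10L), "only 4")
})

test_that("pipeline decisions match the brute-force oracle on random tracks", {
  set.seed(101)
  for (i in 1:200) {
    L <- sample(10:200, 1)
    track <- rpois(L, lambda = sample(c(0.5, 2, 20), 1))
    orc <- oracle_rci_pipeline(track)
    tr <- apply_pseudocount(track)
    rec <- compute_rci(tr, "s")
    expect_identical(rec$position, orc$position)
    expect_equal(rec$rci, orc$rci)
    kept <- filter_by_median(rec, tr)
    kept <- kept[kept$rci >= 3.0, , drop = FALSE]
    expect_identical(kept$position, orc$position[orc$kept])
  }
})

test_that("median filter and RCI threshold commute (both per-record
           predicates)", {
  set.seed(55)
  for (i in 1:20) {
    track <- apply_pseudocount(rpois(60, 3))
    rec <- compute_rci(track, "s")
    a <- filter_by_median(rec, track)
    a <- a[a$rci >= 3, , drop = FALSE]
    b <- rec[rec$rci >= 3, , drop = FALSE]
    b <- filter_by_median(b, track)
    expect_identical(a, b)
  }
})

test_that("end-to-end detection recovers a planted motif and annotates the
           cut", {
  tp <- tiny_panel(seed = 42L)
  rep <- detect_recognition_sequence(tp$substrates, tp$tracks)
  expect_s3_class(rep, "cleavage_report")
  expect_identical(substring(rep$consensus, 5L, 10L), "UACAAA")
  expect_match(rep$cut_annotation, "U\\^ACAAA")
  expect_identical(rep$top$position, c(60L, 120L))
})

test_that("coverage-only input with no passing site yields an empty, valid
           report", {
  substrates <- c(s1 = random_rna(80))
  tracks <- list(s1 = rep(10L, 80L))      # flat: no step-ups anywhere
  rep <- detect_recognition_sequence(substrates, tracks)
  expect_identical(nrow(rep$sites), 0L)
  expect_null(rep$consensus)
  tf <- withr::local_tempfile(fileext = ".json")
  expect_no_error(write_report(rep, tf))
})

test_that("a coverage id missing from the FASTA is fatal and listed", {
  expect_error(
    detect_recognition_sequence(c(s1 = random_rna(50)),
                                list(s2 = rep(1L, 50L))),
    "s2")
})

test_that("identical inputs and parameters give byte-identical reports", {
  tp <- tiny_panel(seed = 9L)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report(detect_recognition_sequence(tp$substrates, tp$tracks), f1)
  write_report(detect_recognition_sequence(tp$substrates, tp$tracks), f2)
  expect_identical(readLines(f1), readLines(f2))
})
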
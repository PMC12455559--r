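# Profile HMM construction, scoring, alignment and tuning.

# hand-built single-match model: emits A with probability 1, no gaps
single_a_hmm <- function() {
  me <- matrix(0, 20, 1, dimnames = list(AA_ALPHABET, NULL))
  me["A", 1] <- 1
  structure(list(L = 1L, match_emissions = me,
                 insert_emissions = setNames(rep(1 / 20, 20), AA_ALPHABET),
                 background = setNames(rep(1 / 20, 20), AA_ALPHABET),
                 mm = c(1, 1), mi = c(0, 0), md = c(0, 0),
                 im = c(0, 1), ii = c(0, 0), dm = c(1, 1), dd = c(0, 0),
                 mode = "global", match_cols = 1L, alignment = NULL),
            class = "profile_hmm")
}

test_that("build_profile: closed-form emissions and column typing", {
  # n identical gap-free rows, Laplace alpha: (n + a) / (n + 20 a)
  aln <- c(x = "A", y = "A", z = "A")
  h <- build_profile(aln, pseudocount = 1)
  expect_equal(unname(h$match_emissions["A", 1]), (3 + 1) / (3 + 20))
  expect_equal(unname(h$match_emissions["C", 1]), 1 / 23)
  expect_equal(sum(h$match_emissions[, 1]), 1, tolerance = 1e-12)

  # column with gap fraction 0.6 at threshold 0.5 -> insert column
  aln2 <- c(a = "MA", b = "M-", c = "M-", d = "MA", e = "M-")
  h2 <- build_profile(aln2, match_gap_threshold = 0.5)
  expect_identical(h2$match_cols, 1L)
  expect_identical(h2$L, 1L)
  expect_error(build_profile(c(a = "-", b = "-")), "match columns")
  expect_error(build_profile(c(a = "M")), "2 alignment rows")
})

test_that("build_profile reproduces hand-tabulated counts on a toy alignment", {
  # rows: MA / M- / -A ; both columns are match columns (gap fraction 1/3)
  aln <- c(r1 = "MA", r2 = "M-", r3 = "-A")
  h <- build_profile(aln, pseudocount = 1)
  expect_identical(h$L, 2L)
  # column 1 counts: M,M ; column 2 counts: A,A
  expect_equal(unname(h$match_emissions["M", 1]), 3 / 22)
  expect_equal(unname(h$match_emissions["A", 2]), 3 / 22)
  # transitions out of Begin: r1,r2 -> M1 (2), r3 -> D1 (1); +1 pseudocount
  expect_equal(h$mm[1], 3 / 6)  # (2+1) / (3+1+1+ ... ) denominators include mi,md
  expect_equal(h$md[1], 2 / 6)
  expect_equal(h$mi[1], 1 / 6)
  # node 1: M1->M2 (r1), M1->D2 (r2), D1->M2 (r3); pseudocounts added
  expect_equal(h$mm[2], 2 / 5)
  expect_equal(h$md[2], 2 / 5)
  expect_equal(h$dm[2], 2 / 3)
  # outgoing transition sets are normalized
  expect_equal(h$mm + h$mi + h$md, rep(1, 3), tolerance = 1e-12)
  expect_equal(h$im + h$ii, rep(1, 3), tolerance = 1e-12)
  expect_equal(h$dm + h$dd, rep(1, 3), tolerance = 1e-12)
})

test_that("forward: closed forms", {
  h <- single_a_hmm()
  expect_equal(forward_bitscore(h, "A", mode = "global"), log2(20))
  # emissions equal to background -> 0 bits in the transition-free limit
  h0 <- single_a_hmm()
  h0$match_emissions[, 1] <- 1 / 20
  expect_equal(forward_bitscore(h0, "W", mode = "global"), 0)
  # X emits at background -> 0 bits even in the enriched model
  expect_equal(forward_bitscore(h, "X", mode = "global"), 0)
  expect_error(forward_bitscore(h, "AZ"), "alphabet")
  expect_error(forward_bitscore(h, ""), "empty")
})

test_that("forward equals exhaustive path enumeration on tiny models", {
  set.seed(21)
  for (r in 1:20) {
    L <- sample(1:3, 1)
    h <- rand_tiny_hmm(L)
    s <- paste(sample(AA_ALPHABET, sample(1:4, 1), TRUE), collapse = "")
    got <- forward_bitscore(h, s, mode = "global") * log(2)
    expect_equal(got, enum_forward_logprob(h, s), tolerance = 1e-9,
                 info = paste("L =", L, "seq =", s))
  }
})

test_that("Viterbi: consensus path, insert behaviour, bound by forward", {
  aln <- c(a = "MKVWA", b = "MKVWA", c = "MKVWA")
  h <- build_profile(aln)
  v <- align_to_profile(h, "MKVWA", mode = "global")
  expect_identical(v$colmap, 1:5)

  # one extra residue relative to the consensus -> exactly one insertion
  v2 <- align_to_profile(h, "MKVQWA", mode = "global")
  expect_identical(sum(v2$colmap == 0), 1L)
  expect_identical(v2$colmap[v2$colmap > 0], 1:5)

  set.seed(31)
  for (r in 1:10) {
    h <- rand_tiny_hmm(sample(1:3, 1))
    s <- paste(sample(AA_ALPHABET, sample(1:4, 1), TRUE), collapse = "")
    expect_lte(align_to_profile(h, s, mode = "global")$bits,
               forward_bitscore(h, s, mode = "global") + 1e-9)
  }
})

test_that("uni-local mode scores flanked domains sensibly", {
  aln <- c(a = "MKVWAHCE", b = "MKVWAHCE", c = "MKVWAHCE")
  h <- build_profile(aln)
  core <- forward_bitscore(h, "MKVWAHCE", mode = "unilocal")
  flanked <- forward_bitscore(h, "GGGGMKVWAHCEGGGG", mode = "unilocal")
  # flanking residues are nearly free; in global mode they are penalized
  expect_gt(flanked, core - 2)
  expect_lt(forward_bitscore(h, "GGGGMKVWAHCEGGGG", mode = "global"), flanked)
  v <- align_to_profile(h, "GGGGMKVWAHCEGGGG", mode = "unilocal")
  expect_identical(unname(v$span), c(5L, 12L))
})

test_that("scores are invariant to training-row order", {
  set.seed(41)
  seqs <- setNames(replicate(5, paste(sample(AA_ALPHABET, 12, TRUE),
                                      collapse = "")), paste0("s", 1:5))
  aln <- progressive_align(seqs)
  h1 <- build_profile(aln)
  h2 <- build_profile(aln[rev(names(aln))])
  probe <- paste(sample(AA_ALPHABET, 12, TRUE), collapse = "")
  expect_equal(forward_bitscore(h1, probe), forward_bitscore(h2, probe),
               tolerance = 1e-9)
})

test_that("background sequences score at or below zero on average (global)", {
  set.seed(51)
  aln <- c(a = "MKVWAHCEDR", b = "MKVWAHCEDR", c = "MKVAAHCEDR")
  h <- build_profile(aln)
  sc <- replicate(200, forward_bitscore(
    h, paste(sample(AA_ALPHABET, 10, TRUE), collapse = ""), mode = "global"))
  expect_lte(mean(sc), 0)
})

test_that("tune_hmm: identity case and pseudocount-weighted augmentation", {
  base <- c(b1 = "MKVWAHCE", b2 = "MKVWAHCE", b3 = "MKVWACCE")
  h0 <- tune_hmm(base)
  h1 <- tune_hmm(base, character(0))
  expect_equal(h0$match_emissions, h1$match_emissions)
  expect_equal(h0$mm, h1$mm)

  # adding exact copies doubles counts: (2c + a) / (2n + 20a)
  copies <- setNames(base, paste0("c", 1:3))
  h2 <- tune_hmm(base, copies)
  c_h <- 2  # column 6 has H in 2 of 3 rows
  expect_equal(unname(h0$match_emissions["H", 6]), (c_h + 1) / (3 + 20))
  expect_equal(unname(h2$match_emissions["H", 6]),
               (2 * c_h + 1) / (6 + 20))

  # mapping mode appends rows on the existing architecture
  h3 <- tune_hmm(base, c(n1 = "MKVWAHCE"), method = "map")
  expect_identical(h3$L, h0$L)
  expect_length(h3$alignment, 4)
})

test_that("normalize_scores and JSON serialization", {
  sc <- c(ref = 100, a = 50, b = 100)
  ns <- normalize_scores(sc, "ref")
  expect_equal(unname(ns$normalized), c(1, 0.5, 1))
  expect_error(normalize_scores(sc, "missing"), "not scored")
  expect_error(normalize_scores(c(ref = 0, a = 1), "ref"), "zero")

  h <- build_profile(c(a = "MKVW", b = "MKVW"))
  f <- withr::local_tempfile(fileext = ".json")
  write_profile_json(h, f)
  h2 <- read_profile_json(f)
  expect_equal(h2$match_emissions, h$match_emissions, tolerance = 1e-12)
  expect_equal(forward_bitscore(h2, "MKVW"), forward_bitscore(h, "MKVW"))
})
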
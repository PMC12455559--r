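# Group comparison: splits, Mann-Whitney, conservation, factors, mapping,
# accessory-domain clustering.

toy_summary <- function() {
  plate <- data.frame(
    enzyme_id = c("a", "a", "b", "b", "c", "d"),
    substrate = "cryPow",
    pH = c(4.5, 7.5, 4.5, 7.5, 7.5, 4.5),
    temperature = 40, replicate = 1,
    A260 = c(0.30, 0.30, 0.05, 0.30, 0.30, 0.05),
    A280 = 0.1, blank_A260 = 0.05)
  summarize_enzymes(plate)
}

test_that("split_groups assigns acid/neutral/excluded correctly", {
  sp <- split_groups(toy_summary())
  expect_identical(sp$acid, "a")        # active at 4.5
  expect_identical(sp$neutral, "b")     # active, tested at 4.5, not active
  expect_identical(sp$excluded, "c")    # active but never tested at 4.5
  # d is inactive everywhere and belongs to no group
  expect_false("d" %in% unlist(sp))
})

test_that("mann_whitney_u: exact enumeration, ties, degenerate cases", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U1, 0)
  expect_equal(mw$p, 2 / 6, tolerance = 1e-12)
  expect_identical(mw$method, "exact")

  expect_equal(mann_whitney_u(c(2, 2, 2), c(2, 2))$p, 1)

  set.seed(101)
  for (r in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:6, n1, TRUE); y <- sample(1:6, n2, TRUE)  # ties frequent
    if (length(unique(c(x, y))) == 1) next
    mw <- mann_whitney_u(x, y)
    expect_equal(mw$U1 + mw$U2, n1 * n2)
    expect_equal(mw$p, mw_exact_oracle(x, y), tolerance = 1e-9,
                 info = paste(paste(x, collapse = ","), "|",
                              paste(y, collapse = ",")))
  }
})

test_that("exact and normal-approximation p agree at moderate n", {
  set.seed(111)
  diffs <- replicate(40, {
    x <- rnorm(6); y <- rnorm(6)
    abs(mann_whitney_u(x, y, exact_max = 12)$p -
          mann_whitney_u(x, y, exact_max = 0)$p)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("position_property_test finds planted shifts with power", {
  split <- structure(list(acid = paste0("A", 1:35),
                          neutral = paste0("N", 1:57),
                          excluded = character(0)), class = "group_split")
  # planted pKa shift of -0.37 (sd 0.2) at one column; power >= 95%
  set.seed(121)
  hits <- replicate(100, {
    tab <- data.frame(
      enzyme_id = c(split$acid, split$neutral), column = 384,
      property = "pKa",
      value = c(rnorm(35, 6.5 - 0.37, 0.2), rnorm(57, 6.5, 0.2)))
    out <- position_property_test(tab, split)
    nrow(out) == 1 && out$mean_diff < 0
  })
  expect_gte(mean(hits), 0.95)

  # identical groups -> nothing significant
  set.seed(122)
  null_tab <- data.frame(enzyme_id = c(split$acid, split$neutral),
                         column = 1, property = "pKa",
                         value = rep(5, 92))
  expect_identical(nrow(position_property_test(null_tab, split)), 0L)
})

test_that("null calibration: ~5% of positions flagged under permuted labels", {
  set.seed(131)
  ids <- c(paste0("A", 1:35), paste0("N", 1:57))
  split <- structure(list(acid = ids[1:35], neutral = ids[36:92],
                          excluded = character(0)), class = "group_split")
  n_cols <- 300
  tab <- data.frame(enzyme_id = rep(ids, n_cols),
                    column = rep(seq_len(n_cols), each = 92),
                    property = "pKa", value = rnorm(92 * n_cols))
  frac <- nrow(position_property_test(tab, split)) / n_cols
  # binomial band around 0.05 for 300 tests
  expect_gt(frac, 0.05 - 3 * sqrt(0.05 * 0.95 / n_cols))
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n_cols))
})

test_that("differential_conservation: extreme case and null", {
  split <- structure(list(acid = paste0("A", 1:6),
                          neutral = paste0("N", 1:6),
                          excluded = character(0)), class = "group_split")
  aln <- setNames(c(rep("HMK", 6), rep("DMK", 6)),
                  c(split$acid, split$neutral))
  out <- differential_conservation(aln, split)
  pos1 <- out[out$column == 1, ]
  expect_true("positive" %in% pos1$class)
  expect_identical(unique(pos1$conserved_in[pos1$class == "positive"]),
                   "acid")
  expect_true("negative" %in% pos1$class)
  # identical distributions -> no flags anywhere
  aln0 <- setNames(rep("HMK", 12), c(split$acid, split$neutral))
  expect_identical(nrow(differential_conservation(aln0, split)), 0L)
})

test_that("kyte_doolittle_profile matches the published scale", {
  expect_equal(kyte_doolittle_profile(strrep("I", 12), 9), rep(4.5, 12))
  expect_equal(kyte_doolittle_profile(strrep("R", 12), 9), rep(-4.5, 12))
  s <- "MKVLA"
  expect_equal(kyte_doolittle_profile(s, 1),
               unname(KYTE_DOOLITTLE[strsplit(s, "")[[1]]]))
  expect_error(kyte_doolittle_profile("MKV", 4), "odd")
})

test_that("factor_profile: counts, tie rule, monotonicity", {
  factors <- data.frame(column = c(10, 20), property = "pKa",
                        mean_acid = c(5, 5), mean_neutral = c(7, 7),
                        mean_diff = -2, p = 0.01)
  props <- data.frame(enzyme_id = rep(c("e1", "e2", "e3"), each = 2),
                      column = rep(c(10, 20), 3), property = "pKa",
                      value = c(5, 5,    # e1 at acid mean -> 2 factors
                                6, 6,    # e2 equidistant -> 0 (strict)
                                5, 7))   # e3 mixed -> 1
  pr <- factor_profile(props, factors)
  counts <- setNames(pr$n_factors, pr$enzyme_id)
  expect_identical(counts, c(e1 = 2L, e2 = 0L, e3 = 1L))
  expect_true(all(pr$n_factors <= nrow(factors)))
  # adding a factor never decreases counts
  more <- rbind(factors, data.frame(column = 10, property = "hydro",
                                    mean_acid = 1, mean_neutral = 0,
                                    mean_diff = 1, p = 0.01))
  props2 <- rbind(props, data.frame(enzyme_id = c("e1", "e2", "e3"),
                                    column = 10, property = "hydro",
                                    value = c(1, 1, 0)))
  pr2 <- factor_profile(props2, more)
  expect_true(all(pr2$n_factors >= pr$n_factors[match(pr2$enzyme_id,
                                                      pr$enzyme_id)]))
})

test_that("map_to_reference inverts through degapping", {
  aln <- c(ref = "A-C", other = "AGC")
  mp <- map_to_reference(aln, "ref")
  expect_identical(mp, c(1L, NA, 2L))
  expect_error(map_to_reference(aln, "nope"), "not in alignment")

  set.seed(141)
  row <- paste(sample(c(AA_ALPHABET, rep("-", 8)), 40, TRUE), collapse = "")
  aln2 <- c(ref = row, pad = strrep("A", 40))
  mp2 <- map_to_reference(aln2, "ref")
  ch <- strsplit(row, "")[[1]]
  expect_identical(sum(!is.na(mp2)), sum(ch != "-"))
  expect_identical(mp2[!is.na(mp2)], seq_len(sum(ch != "-")))
})

test_that("cluster_accessory_domains: trivial and planted cases", {
  core <- strrep("MKVWAHCE", 5)
  aln <- setNames(rep(core, 3), paste0("t", 1:3))
  hmm <- build_profile(aln)
  # no residues beyond the catalytic span -> empty
  out <- cluster_accessory_domains(setNames(rep(core, 2), c("x", "y")), hmm,
                                   min_length = 10)
  expect_identical(nrow(out), 0L)

  seg <- strrep("GGSTNQ", 8)
  seqs <- c(x = paste0(core, seg), y = paste0(core, seg), z = core)
  out2 <- cluster_accessory_domains(seqs, hmm, min_length = 10,
                                    acid_active = c(x = TRUE, y = FALSE,
                                                    z = FALSE))
  expect_identical(nrow(out2), 1L)
  expect_identical(out2$n, 2L)
  expect_equal(out2$acid_hit_rate, 0.5)
})

test_that("planted accessory cluster is enriched for low-pH activity", {
  w <- small_world(seed = 42, n = 80)
  sim <- simulate_assay(w)
  s <- summarize_enzymes(sim$assay, yields = sim$yields)
  cc <- s$conditions
  acid_act <- tapply(cc$active & cc$pH == 4.5, cc$enzyme_id, any)
  base <- head(s$enzymes$enzyme_id[s$enzymes$active], 10)
  hmm <- tune_hmm(w$sequences[base])
  cl <- cluster_accessory_domains(w$sequences, hmm,
                                  acid_active = acid_act)
  expect_gt(nrow(cl), 0)
  big <- cl[which.max(cl$n), ]
  expect_gt(big$acid_hit_rate, mean(acid_act, na.rm = TRUE))
})
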
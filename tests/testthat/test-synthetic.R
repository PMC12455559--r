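# Synthetic world generator: configuration guards, limiting cases,
# determinism, file round-trips, recovery of the planted structure.

test_that("world_config validates its inputs", {
  expect_error(world_config(domain_length = 100), "planted column")
  expect_error(world_config(baseline_class_freq = 1.2), "probabilities")
  expect_error(world_config(condition_grid = list(substrates = character(0),
                                                  temperatures = 40,
                                                  ph = 4.5)), "nonempty")
  expect_s3_class(world_config(n_enzymes = 10), "world_config")

  w <- generate_world(world_config(n_enzymes = 10))
  w$config$assay_noise$sd <- -1
  expect_error(simulate_assay(w), "nonnegative")
})

test_that("zero-mutation limit reproduces the root", {
  cfg <- world_config(n_enzymes = 8, substitution_rate = 0,
                      acid_subfamily_rate = 0, indel_rate = 0,
                      planted_conservation = data.frame(
                        column = integer(0), class = character(0),
                        enrichment = numeric(0)),
                      planted_property_shifts = data.frame(
                        column = 1, property = "pKa", shift = 0, sd = 0.1),
                      seed = 3)
  cfg$accessory$attach_prob <- 0
  w <- generate_world(cfg)
  expect_true(all(w$sequences == w$root))
  expect_false(any(grepl("-", w$alignment)))
})

test_that("enrichment probability 1 forces the class in acid-prone enzymes", {
  cfg <- world_config(n_enzymes = 60, seed = 5)
  cfg$planted_conservation$enrichment <- 1
  w <- generate_world(cfg)
  m <- do.call(rbind, strsplit(unname(w$alignment), ""))
  rownames(m) <- w$ids
  pc <- cfg$planted_conservation
  for (j in seq_len(nrow(pc))) {
    col <- w$root_col_map[pc$column[j]]
    cls <- RESIDUE_CLASSES[[pc$class[j]]]
    expect_true(all(m[w$acid_prone, col] %in% cls), info = paste("col", j))
  }
})

test_that("identical seeds give byte-identical worlds and assays", {
  cfg <- world_config(n_enzymes = 25, seed = 7)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1, w2)
  expect_identical(simulate_assay(w1), simulate_assay(w2))
  expect_identical(emit_property_tables(w1), emit_property_tables(w2))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_world(w1, d1)
  write_world(w2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("noiseless assay reproduces the affine absorbance formula", {
  cfg <- world_config(n_enzymes = 15, seed = 9)
  cfg$assay_noise$sd <- 0
  w <- generate_world(cfg)
  sim <- simulate_assay(w)
  an <- cfg$assay_noise
  coef <- an$epsilon * an$path_length / (an$reaction_volume * an$dilution)
  g <- match(paste(sim$assay$substrate, sim$assay$temperature, sim$assay$pH),
             paste(w$condition_grid$substrate, w$condition_grid$temperature,
                   w$condition_grid$pH))
  lat <- w$latent_activity[cbind(match(sim$assay$enzyme_id, w$ids), g)]
  expect_equal(sim$assay$A260,
               an$blank_a260 + coef * lat * an$enzyme_mg, tolerance = 1e-12)
  # zero latent activity -> A260 equals the blank exactly
  zero <- lat == 0
  expect_true(any(zero))
  expect_equal(sim$assay$A260[zero], rep(an$blank_a260, sum(zero)))
})

test_that("emitted files round-trip through the package readers", {
  w <- generate_world(world_config(n_enzymes = 12, seed = 13))
  d <- withr::local_tempdir()
  paths <- write_world(w, d)
  expect_identical(read_fasta(paths[["sequences"]]), w$sequences)
  expect_identical(read_fasta(paths[["alignment"]]), w$alignment)
  assay <- read.csv(paths[["assay"]])
  sim <- simulate_assay(w)
  expect_equal(assay$A260, sim$assay$A260, tolerance = 1e-9)
  expect_identical(nrow(assay), nrow(sim$assay))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_identical(truth$ids, w$ids)
  expect_equal(truth$true_tm, unname(w$true_tm))
})

test_that("planted-class frequency difference matches the configured
           enrichment over seeds", {
  # one planted column with strong weighting; Monte-Carlo tabulation
  diffs <- sapply(1:50, function(seed) {
    cfg <- world_config(n_enzymes = 200, seed = seed)
    w <- generate_world(cfg)
    pc <- cfg$planted_conservation
    col <- w$root_col_map[pc$column[1]]
    cls <- RESIDUE_CLASSES[[pc$class[1]]]
    m <- substring(unname(w$alignment), col, col)
    mean(m[w$acid_prone] %in% cls) - mean(m[!w$acid_prone] %in% cls)
  })
  target <- 0.95 - 0.30
  expect_equal(mean(diffs), target, tolerance = 0.03)
})

test_that("activity calls recover the acid-tolerant flag (balanced
           accuracy >= 0.9 over 20 seeds)", {
  accs <- sapply(1:20, function(seed) {
    w <- generate_world(world_config(n_enzymes = 120, seed = 1000 + seed))
    sim <- simulate_assay(w)
    s <- summarize_enzymes(sim$assay)
    cc <- s$conditions
    called <- tapply(cc$active & cc$pH == 4.5, cc$enzyme_id, any)
    tested <- tapply(cc$pH == 4.5, cc$enzyme_id, any)
    ids <- names(called)[tested]
    truth <- w$acid_tolerant_flag[ids]
    pred <- called[ids]
    if (!any(truth) || all(truth)) return(NA)
    (mean(pred[truth]) + mean(!pred[!truth])) / 2
  })
  expect_gte(mean(accs, na.rm = TRUE), 0.9)
})

test_that("property tables realize the configured shifts", {
  cfg <- world_config(n_enzymes = 100, seed = 17)
  # sd = 0: group difference is exactly the configured shift
  cfg$planted_property_shifts <- data.frame(
    column = 130, property = "pKa", shift = -0.37, sd = 0)
  w <- generate_world(cfg)
  tab <- emit_property_tables(w)
  planted <- tab[tab$column == w$root_col_map[130], ]
  d <- mean(planted$value[w$acid_prone[planted$enzyme_id]]) -
    mean(planted$value[!w$acid_prone[planted$enzyme_id]])
  expect_equal(d, -0.37, tolerance = 1e-12)
  # shift 0 -> group means equal within sampling error
  cfg$planted_property_shifts$shift <- 0
  cfg$planted_property_shifts$sd <- 0.2
  w0 <- generate_world(cfg)
  tab0 <- emit_property_tables(w0)
  p0 <- tab0[tab0$column == w0$root_col_map[130], ]
  d0 <- mean(p0$value[w0$acid_prone[p0$enzyme_id]]) -
    mean(p0$value[!w0$acid_prone[p0$enzyme_id]])
  expect_lt(abs(d0), 0.15)
})
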
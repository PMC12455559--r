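# Synthetic enzyme world with planted determinants of low-pH activity.
#
# The generator emulates the structure of a high-throughput PET-hydrolase
# screen: ~212 enzymes across three discovery rounds (DP/TEP/ESM id
# prefixes), a condition grid of two substrates x two temperatures x four
# pH levels, duplicate wells for high-yield enzymes, partial condition
# coverage by yield tier (32/8/4 conditions), purification yields, DSF melt
# curves, and per-residue property tables.  Activity is driven by planted
# sequence determinants: class-enriched alignment columns, property (e.g.
# predicted pKa) shifts at specific columns, and an accessory domain whose
# presence boosts acid tolerance.

#' Configuration for the synthetic enzyme world
#'
#' Defaults state the emulated screen: 212 enzymes, 250-residue catalytic
#' domain, nine class-enriched columns (conditional enrichment 0.95 in
#' acid-tolerant enzymes versus 0.30 baseline), pKa shifts of -0.37 at the
#' catalytic-histidine column, +0.26 at the catalytic-aspartate column and
#' +1.5 at the serine-adjacent histidine column, hydrophobicity shifts of
#' +1.0 near the binding site, an accessory domain (attachment probability
#' 0.15, acid log-odds boost 2.5, 60 residues), and plate noise of 0.005
#' absorbance units (typical replicate precision of a UV plate reader).
#'
#' @param n_enzymes number of enzymes
#' @param domain_length catalytic-domain length (residues)
#' @param substitution_rate expected substitutions per site from the root
#' @param acid_subfamily_rate portion of the root-to-leaf divergence shared
#'   by all acid-prone enzymes (their common subfamily branch)
#' @param indel_rate per-site deletion probability and per-sequence
#'   insertion intensity
#' @param planted_conservation data.frame `column`, `class`, `enrichment`
#' @param baseline_class_freq class probability at planted columns for
#'   non-acid enzymes
#' @param planted_property_shifts data.frame `column`, `property`, `shift`,
#'   `sd`
#' @param n_decoy_columns decoy (unshifted) columns per property
#' @param accessory list: `attach_prob`, `acid_logodds`, `length`
#' @param condition_grid list: `substrates`, `temperatures`, `ph`
#' @param activity_model list of latent-activity parameters (logistic
#'   weights on planted features, pH response width, Tm-temperature
#'   penalty, lognormal maximum activity)
#' @param assay_noise list: `blank_a260`, `sd`, plus the quantification
#'   constants `epsilon`, `path_length`, `reaction_volume`, `dilution`,
#'   `enzyme_mg`
#' @param yield_model list: lognormal `meanlog`/`sdlog` (ug), purification
#'   `failure_prob`, tier cutoffs `tier32_min`, `tier8_min`
#' @param round_fractions named fractions of enzymes per round label
#' @param round_ph named list of pH levels tested per round
#' @param seed integer seed; fully determines the world
#' @return list of class `world_config`
#' @export
world_config <- function(
    n_enzymes = 212,
    domain_length = 250,
    substitution_rate = 0.35,
    acid_subfamily_rate = 0.04,
    indel_rate = 0.01,
    planted_conservation = data.frame(
      column = c(30, 55, 62, 90, 130, 160, 177, 208, 224),
      class = c("positive", "negative", "hydrophobic", "polar", "aromatic",
                "positive", "hydrophobic", "hydrophobic", "negative"),
      enrichment = 0.95,
      stringsAsFactors = FALSE),
    baseline_class_freq = 0.30,
    planted_property_shifts = data.frame(
      column = c(130, 100, 160, 62, 177, 208, 45, 70, 115),
      property = c("pKa", "pKa", "pKa", "hydrophobicity", "hydrophobicity",
                   "hydrophobicity", "electrostatics", "electrostatics",
                   "stickiness"),
      shift = c(-0.37, 0.26, 1.5, 1.0, 1.0, 1.0, -0.5, -0.5, 0.4),
      sd = c(0.2, 0.3, 0.5, 0.5, 0.5, 0.5, 0.3, 0.3, 0.3),
      stringsAsFactors = FALSE),
    n_decoy_columns = 8,
    accessory = list(attach_prob = 0.15, acid_logodds = 2.5, length = 60),
    condition_grid = list(substrates = c("aFilm", "cryPow"),
                          temperatures = c(40, 60),
                          ph = c(4.5, 5.5, 6.5, 7.5, 8.5)),
    activity_model = list(active_intercept = 0, conservation_weight = 0,
                          accessory_activity_logodds = 1.5,
                          acid_intercept = -0.6, ph_width = 1.0,
                          ph_cutoff = 2.5,
                          acid_ph_opt = 5.0, neutral_ph_opt = 7.5,
                          ph_opt_sd = 0.15, tm_margin = 5, tm_decay = 5,
                          substrate_factor = c(aFilm = 0.3, cryPow = 1.0),
                          amax_meanlog = log(30), amax_sdlog = 1),
    assay_noise = list(blank_a260 = 0.05, sd = 0.005, epsilon = 17,
                       path_length = 1, reaction_volume = 0.5,
                       dilution = 10, enzyme_mg = 0.005),
    yield_model = list(meanlog = log(150), sdlog = 0.7, failure_prob = 0.04,
                       tier32_min = 200, tier8_min = 100),
    round_fractions = c(DP = 0.30, TEP = 0.35, ESM = 0.35),
    round_ph = list(DP = c(5.5, 6.5, 7.5, 8.5),
                    TEP = c(4.5, 5.5, 6.5, 7.5),
                    ESM = c(4.5, 5.5, 6.5, 7.5)),
    seed = 1) {
  cfg <- as.list(environment())
  probs <- c(cfg$planted_conservation$enrichment, cfg$baseline_class_freq,
             cfg$accessory$attach_prob, cfg$yield_model$failure_prob,
             cfg$round_fractions)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (!length(cfg$condition_grid$substrates) ||
      !length(cfg$condition_grid$temperatures) ||
      !length(cfg$condition_grid$ph)) stop("condition grid must be nonempty")
  if (cfg$domain_length < max(cfg$planted_conservation$column,
                              cfg$planted_property_shifts$column)) {
    stop("domain_length smaller than the largest planted column")
  }
  if (cfg$assay_noise$sd < 0) stop("assay noise sd must be nonnegative")
  if (!all(cfg$planted_conservation$class %in% names(RESIDUE_CLASSES))) {
    stop("unknown residue class in planted_conservation")
  }
  class(cfg) <- "world_config"
  cfg
}

.random_seq <- function(n) paste(sample(AA_ALPHABET, n, TRUE), collapse = "")

#' Generate a synthetic enzyme world with known ground truth
#'
#' Draws a root domain sequence and mutates it along a star phylogeny
#' (per-site substitutions, occasional indels).  An accessory domain is
#' attached to some enzymes; an acid-tolerance propensity is the logistic of
#' the accessory indicator plus standard-normal noise, thresholded at zero.
#' Planted alignment columns are then written with the configured class at
#' the conditional enrichment (acid-prone) or baseline frequency, so that
#' the realized sequences carry recoverable determinants; overall activity
#' is a logistic function of the fraction of planted columns carried.  The
#' acid-tolerant flag is the conjunction of being active and acid-prone.
#'
#' @param config a `world_config`
#' @return list of class `pet_world` with `sequences`, `alignment` (true
#'   MSA), `root_col_map` (root column -> alignment column), per-enzyme
#'   truth vectors, the latent activity matrix over the full condition grid,
#'   and the configuration
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  n <- config$n_enzymes
  L <- config$domain_length

  rounds <- rep(names(config$round_fractions),
                times = round(config$round_fractions * n))
  rounds <- c(rounds, rep("ESM", max(0, n - length(rounds))))[seq_len(n)]
  counters <- c(DP = 0L, TEP = 0L, ESM = 0L)
  ids <- character(n)
  for (i in seq_len(n)) {
    counters[rounds[i]] <- counters[rounds[i]] + 1L
    ids[i] <- sprintf("%s%03d", rounds[i], counters[rounds[i]])
  }

  root <- strsplit(.random_seq(L), "")[[1]]
  acc_root <- .random_seq(config$accessory$length)

  p_sub <- 1 - exp(-config$substitution_rate)
  planted_cols <- config$planted_conservation$column

  # accessory attachment and acid propensity (logistic of planted features
  # plus standard-normal noise, thresholded at 0)
  acc <- runif(n) < config$accessory$attach_prob
  am <- config$activity_model
  u <- am$acid_intercept + config$accessory$acid_logodds * acc + rnorm(n)
  acid_prone <- u > 0

  # two-level star phylogeny: acid-prone enzymes descend from a shared
  # subfamily root (condition-active homologs cluster together on the tree),
  # everything else directly from the family root; total root-to-leaf
  # divergence is the same for both groups
  sub_rate <- min(config$acid_subfamily_rate, config$substitution_rate)
  p_sub_acid <- 1 - exp(-(config$substitution_rate - sub_rate))
  acid_root <- root
  mut <- runif(L) < 1 - exp(-sub_rate)
  acid_root[mut] <- vapply(root[mut], function(r)
    sample(setdiff(AA_ALPHABET, r), 1), character(1))
  dom <- matrix(rep(root, each = n), nrow = n)  # n x L residues
  for (i in seq_len(n)) {
    src <- if (acid_prone[i]) acid_root else root
    pm <- if (acid_prone[i]) p_sub_acid else p_sub
    mut <- runif(L) < pm
    dom[i, ] <- src
    if (any(mut)) {
      dom[i, mut] <- vapply(src[mut], function(r)
        sample(setdiff(AA_ALPHABET, r), 1), character(1))
    }
  }
  # plant class-enriched columns conditioned on acid propensity
  for (j in seq_len(nrow(config$planted_conservation))) {
    col <- config$planted_conservation$column[j]
    cls <- RESIDUE_CLASSES[[config$planted_conservation$class[j]]]
    pr <- ifelse(acid_prone, config$planted_conservation$enrichment[j],
                 config$baseline_class_freq)
    carry <- runif(n) < pr
    dom[carry, col] <- sample(cls, sum(carry), TRUE)
    if (any(!carry)) {
      dom[!carry, col] <- sample(setdiff(AA_ALPHABET, cls), sum(!carry), TRUE)
    }
  }
  carried <- matrix(FALSE, n, length(planted_cols))
  for (j in seq_along(planted_cols)) {
    cls <- RESIDUE_CLASSES[[config$planted_conservation$class[j]]]
    carried[, j] <- dom[, planted_cols[j]] %in% cls
  }

  # indels: per-site deletions (sparing planted columns) and at most one
  # short insertion per enzyme
  del <- matrix(runif(n * L) < config$indel_rate, n, L)
  del[, planted_cols] <- FALSE
  ins_prob <- min(1, 10 * config$indel_rate)  # insertions rarer than deletions
  ins_pos <- ifelse(runif(n) < ins_prob, sample.int(L - 1, n, TRUE), 0L)
  ins_len <- ifelse(ins_pos > 0, 1L + (runif(n) < 0.3), 0L)
  ins_seq <- vapply(ins_len, function(l)
    if (l > 0) .random_seq(l) else "", character(1))

  # true alignment: root columns plus one insertion slot per used position
  ins_after <- sort(unique(ins_pos[ins_pos > 0]))
  slot_len <- vapply(ins_after, function(p) max(ins_len[ins_pos == p]),
                     integer(1))
  n_cols <- L + sum(slot_len)
  root_col_map <- integer(L)
  aln_m <- matrix("-", n, n_cols)
  colptr <- 0L
  for (p in seq_len(L)) {
    colptr <- colptr + 1L
    root_col_map[p] <- colptr
    keep <- !del[, p]
    aln_m[keep, colptr] <- dom[keep, p]
    si <- match(p, ins_after)
    if (!is.na(si)) {
      for (i in which(ins_pos == p)) {
        chs <- strsplit(ins_seq[i], "")[[1]]
        aln_m[i, colptr + seq_along(chs)] <- chs
      }
      colptr <- colptr + slot_len[si]
    }
  }
  alignment <- setNames(apply(aln_m, 1, paste, collapse = ""), ids)
  domain_seqs <- degap(alignment)

  # accessory segments: mutated copies of a common accessory root
  acc_seqs <- character(n)
  for (i in which(acc)) {
    a <- strsplit(acc_root, "")[[1]]
    mut <- runif(length(a)) < 0.2
    a[mut] <- vapply(a[mut], function(r)
      sample(setdiff(AA_ALPHABET, r), 1), character(1))
    acc_seqs[i] <- paste(a, collapse = "")
  }
  sequences <- setNames(paste0(domain_seqs, acc_seqs), ids)

  # overall activity: logistic of the planted-column load, decoupled from
  # acid tolerance by default (conservation_weight = 0), so that generic
  # activity and condition-specific tolerance are separate axes as in a
  # real screen
  frac <- rowMeans(carried)
  p_active <- plogis(am$active_intercept + am$conservation_weight *
                       (2 * frac - 1) +
                       am$accessory_activity_logodds * acc)
  active <- runif(n) < p_active
  acid_flag <- active & acid_prone
  ph_opt <- ifelse(acid_prone, am$acid_ph_opt, am$neutral_ph_opt) +
    rnorm(n, 0, am$ph_opt_sd)
  amax <- rlnorm(n, am$amax_meanlog, am$amax_sdlog)
  true_tm <- pmin(85, pmax(30, rnorm(n, 56, 8)))

  grid <- expand.grid(substrate = config$condition_grid$substrates,
                      temperature = config$condition_grid$temperatures,
                      pH = config$condition_grid$ph,
                      stringsAsFactors = FALSE)
  lat <- matrix(0, n, nrow(grid), dimnames = list(ids, NULL))
  for (g in seq_len(nrow(grid))) {
    # Gaussian response around the optimum; hard zero beyond ph_cutoff units
    # (activity collapses once catalytic protonation states are lost)
    ph_resp <- exp(-(grid$pH[g] - ph_opt)^2 / (2 * am$ph_width^2)) *
      (abs(grid$pH[g] - ph_opt) <= am$ph_cutoff)
    soft_tm <- true_tm - am$tm_margin
    temp_fac <- ifelse(grid$temperature[g] <= soft_tm, 1,
                       exp(-(grid$temperature[g] - soft_tm) / am$tm_decay))
    lat[, g] <- active * amax * ph_resp * temp_fac *
      am$substrate_factor[[grid$substrate[g]]]
  }

  yield_ug <- rlnorm(n, config$yield_model$meanlog, config$yield_model$sdlog)
  purified <- runif(n) >= config$yield_model$failure_prob
  tier <- ifelse(!purified, 0L,
                 ifelse(yield_ug >= config$yield_model$tier32_min, 32L,
                        ifelse(yield_ug >= config$yield_model$tier8_min,
                               8L, 4L)))

  world <- list(ids = ids, round = rounds, sequences = sequences,
                alignment = alignment, root_col_map = root_col_map,
                root = paste(root, collapse = ""),
                accessory_flag = setNames(acc, ids),
                accessory_root = acc_root,
                acid_prone = setNames(acid_prone, ids),
                acid_tolerant_flag = setNames(acid_flag, ids),
                active = setNames(active, ids),
                carried = carried,
                ph_opt = setNames(ph_opt, ids),
                amax = setNames(amax, ids),
                true_tm = setNames(true_tm, ids),
                yield_ug = setNames(yield_ug, ids),
                purified = setNames(purified, ids),
                tier = setNames(tier, ids),
                condition_grid = grid,
                latent_activity = lat,
                config = config)
  class(world) <- "pet_world"
  world
}

#' @export
print.pet_world <- function(x, ...) {
  cat("Synthetic enzyme world:", length(x$ids), "enzymes,",
      sum(x$active), "active,", sum(x$acid_tolerant_flag),
      "acid tolerant; seed", x$config$seed, "\n")
  invisible(x)
}

#' Simulate the plate assay and DSF melt curves for a world
#'
#' Well absorbance is `blank + c * specific_activity * enzyme_mg + noise`
#' with `c = epsilon * path_length / (reaction_volume * dilution)` (the
#' inverse of [quantify_product()]).  High-yield enzymes (tier 32) are
#' tested on both substrates and temperatures in duplicate; tier 8 on
#' crystalline powder at both temperatures; tier 4 on crystalline powder at
#' 40 degC only.  pH coverage follows the enzyme's round.  Melt curves are
#' two-state sigmoids centered at the true Tm (with an occasional lower
#' secondary transition) plus noise.
#'
#' @param world a `pet_world`
#' @param seed RNG seed for assay noise (default: world seed + 1)
#' @return list: `assay` (well-level data.frame), `melt` (melt curves),
#'   `yields` (per-enzyme yields and purification flags)
#' @export
simulate_assay <- function(world, seed = world$config$seed + 1) {
  cfg <- world$config
  an <- cfg$assay_noise
  if (an$sd < 0) stop("assay noise sd must be nonnegative")
  set.seed(seed)
  coef <- an$epsilon * an$path_length / (an$reaction_volume * an$dilution)
  grid <- world$condition_grid
  rows <- lapply(seq_along(world$ids), function(i) {
    tier <- world$tier[[i]]
    if (tier == 0L) return(NULL)
    phs <- intersect(cfg$round_ph[[world$round[i]]], cfg$condition_grid$ph)
    if (!length(phs)) return(NULL)
    wells <- expand.grid(
      replicate = seq_len(if (tier == 32L) 2L else 1L),
      pH = phs,
      temperature = if (tier >= 8L) cfg$condition_grid$temperatures else 40,
      substrate = if (tier == 32L) cfg$condition_grid$substrates else "cryPow",
      stringsAsFactors = FALSE)
    cbind(enzyme_id = world$ids[i], round = world$round[i], wells)
  })
  assay <- do.call(rbind, rows)
  g <- match(paste(assay$substrate, assay$temperature, assay$pH),
             paste(grid$substrate, grid$temperature, grid$pH))
  umol <- world$latent_activity[cbind(match(assay$enzyme_id, world$ids), g)] *
    an$enzyme_mg
  nw <- nrow(assay)
  assay$A260 <- an$blank_a260 + coef * umol + rnorm(nw, 0, an$sd)
  assay$A280 <- an$blank_a260 + 0.6 * coef * umol + rnorm(nw, 0, an$sd)
  assay$A260 <- pmax(0, assay$A260)
  assay$A280 <- pmax(0, assay$A280)
  # matched blanks per (substrate, pH, temperature)
  bl <- unique(assay[c("substrate", "pH", "temperature")])
  bl$blank_A260 <- pmax(0, an$blank_a260 + rnorm(nrow(bl), 0, an$sd))
  assay <- merge(assay, bl, by = c("substrate", "pH", "temperature"),
                 sort = FALSE)
  assay <- assay[order(assay$enzyme_id, assay$substrate, assay$pH,
                       assay$temperature, assay$replicate),
                 c("enzyme_id", "round", "substrate", "pH", "temperature",
                   "replicate", "A260", "A280", "blank_A260")]
  rownames(assay) <- NULL

  temps <- seq(25, 95, by = 0.5)
  melt <- do.call(rbind, lapply(seq_along(world$ids), function(i) {
    id <- world$ids[i]
    tm <- world$true_tm[[id]]
    two <- runif(1) < 0.2
    f <- if (two) {
      tm2 <- tm - runif(1, 12, 20)
      0.05 + 0.45 / (1 + exp(-(temps - tm2) / 2)) +
        0.45 / (1 + exp(-(temps - tm) / 2))
    } else {
      0.05 + 0.9 / (1 + exp(-(temps - tm) / 2))
    }
    data.frame(enzyme_id = id, temperature = temps,
               fluorescence = f + rnorm(length(temps), 0, 0.02),
               stringsAsFactors = FALSE)
  }))
  yields <- data.frame(enzyme_id = world$ids,
                       yield_ug = unname(world$yield_ug),
                       purified = unname(world$purified),
                       tier = unname(world$tier),
                       stringsAsFactors = FALSE)
  list(assay = assay, melt = melt, yields = yields)
}

#' Emit per-residue property tables with planted group shifts
#'
#' For every configured property, values are drawn around a per-column base
#' level; at planted columns, acid-prone enzymes are shifted by the
#' configured mean.  Decoy columns (no shift) are included for every
#' property so that false-positive rates can be measured.  Columns are
#' reported in true-alignment coordinates.
#'
#' @param world a `pet_world`
#' @param seed RNG seed (default: world seed + 2)
#' @return data.frame: `enzyme_id`, `column`, `property`, `value`
#' @export
emit_property_tables <- function(world, seed = world$config$seed + 2) {
  cfg <- world$config
  shifts <- cfg$planted_property_shifts
  if (!nrow(shifts)) return(data.frame(enzyme_id = character(0),
                                       column = integer(0),
                                       property = character(0),
                                       value = numeric(0)))
  set.seed(seed)
  base_level <- c(pKa = 6.5, hydrophobicity = 0, electrostatics = 0,
                  circular_variance = 0.5, stickiness = 0)
  n <- length(world$ids)
  out <- list()
  for (prop in unique(shifts$property)) {
    sh <- shifts[shifts$property == prop, ]
    decoys <- setdiff(sample.int(cfg$domain_length, cfg$n_decoy_columns +
                                   nrow(sh)), sh$column)[seq_len(cfg$n_decoy_columns)]
    cols <- c(sh$column, decoys)
    base <- if (prop %in% names(base_level)) base_level[[prop]] else 0
    col_base <- base + rnorm(length(cols), 0, 0.5)
    for (k in seq_along(cols)) {
      sd_k <- if (k <= nrow(sh)) sh$sd[k] else 0.3
      mu <- rep(col_base[k], n)
      if (k <= nrow(sh)) mu <- mu + sh$shift[k] * world$acid_prone
      out[[length(out) + 1]] <- data.frame(
        enzyme_id = world$ids,
        column = world$root_col_map[cols[k]],
        property = prop,
        value = rnorm(n, mu, sd_k),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write all world artifacts to a directory
#'
#' Emits sequences (FASTA), the true alignment (aligned FASTA), the assay
#' table and melt curves (CSV), property tables (TSV) and the ground truth
#' (JSON).
#'
#' @param world a `pet_world`
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of file paths
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_assay(world)
  props <- emit_property_tables(world)
  paths <- c(
    sequences = file.path(dir, "sequences.fasta"),
    alignment = file.path(dir, "true_alignment.fasta"),
    assay = file.path(dir, "assay.csv"),
    melt = file.path(dir, "melt_curves.csv"),
    properties = file.path(dir, "properties.tsv"),
    truth = file.path(dir, "truth.json"))
  write_fasta(world$sequences, paths[["sequences"]])
  write_fasta(world$alignment, paths[["alignment"]])
  write.csv(sim$assay, paths[["assay"]], row.names = FALSE)
  write.csv(sim$melt, paths[["melt"]], row.names = FALSE)
  write.table(props, paths[["properties"]], sep = "\t", row.names = FALSE,
              quote = FALSE)
  truth <- list(ids = world$ids, round = world$round,
                acid_tolerant_flag = unname(world$acid_tolerant_flag),
                acid_prone = unname(world$acid_prone),
                active = unname(world$active),
                ph_opt = unname(world$ph_opt),
                true_tm = unname(world$true_tm),
                yield_ug = unname(world$yield_ug),
                purified = unname(world$purified),
                tier = unname(world$tier),
                planted_conservation = world$config$planted_conservation,
                planted_property_shifts = world$config$planted_property_shifts,
                root_col_map = world$root_col_map,
                seed = world$config$seed)
  jsonlite::write_json(truth, paths[["truth"]], digits = NA,
                       auto_unbox = TRUE)
  invisible(paths)
}
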
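# Config-driven orchestration: synthetic world -> alignment -> profile HMM
# -> scoring -> assay processing -> supervised training -> selection ->
# group analysis, with structured logging and full determinism under a seed.

#' Default pipeline configuration
#'
#' Returns the default configuration list; any element may be overridden via
#' a YAML file or the `...` arguments of [run_pipeline()].  The synthetic
#' world is kept small by default (60 enzymes) so the end-to-end run stays
#' fast; the world itself defaults to the full screen size when used
#' directly.
#'
#' @param seed master seed
#' @return nested configuration list
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    synthetic = TRUE,
    n_enzymes = 60,
    stages = list(simulate = TRUE, align = TRUE, hmm = TRUE, assay = TRUE,
                  train = TRUE, select = TRUE, analyze = TRUE),
    hmm = list(n_base_actives = 12, match_gap_threshold = 0.5,
               pseudocount = 1, bit_threshold = 100),
    train = list(condition = list(substrate = "cryPow", pH = 4.5,
                                  temperature = 40),
                 folds = 5, model = "ridge", lambda = 1, kmax = 2),
    select = list(percentile = 50, identity_threshold = 0.90,
                  activity_min = 10, tm_min = 55),
    analyze = list(acid_ph = 4.5, alpha = 0.05, hi = 0.9, lo = 0.5,
                   accessory_min_length = 40,
                   accessory_identity = 0.35)
  )
}

.log_stage <- function(con, stage, t0, ...) {
  entry <- c(list(stage = stage,
                  elapsed_s = round(as.numeric(Sys.time()) - t0, 3)),
             list(...))
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE)
  writeLines(as.character(line), con)
  message("[", stage, "] done in ", entry$elapsed_s, "s")
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full screening pipeline
#'
#' Executes simulate -> align -> HMM build/score -> assay processing ->
#' supervised training -> candidate selection -> group analysis, writing all
#' reports, a JSON-lines run log, and the resolved configuration into
#' `out_dir`.  Deterministic under a fixed seed.
#'
#' @param config a configuration list (see [default_pipeline_config()]) or
#'   a path to a YAML file with overrides
#' @param out_dir output directory
#' @return invisibly, a list with the main in-memory results
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("petscreen_run_")) {
  if (is.character(config)) {
    config <- .merge_config(default_pipeline_config(),
                            yaml::read_yaml(config))
  } else {
    config <- .merge_config(default_pipeline_config(), config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
  logcon <- file(file.path(out_dir, "run_log.jsonl"), "w")
  on.exit(close(logcon))
  st <- config$stages
  res <- list(config = config, out_dir = out_dir)
  run_stage <- function(name, enabled, fun) {
    if (!isTRUE(enabled)) return(invisible(NULL))
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    out
  }

  # --- simulate ---
  world <- run_stage("simulate", st$simulate, function() {
    t0 <- as.numeric(Sys.time())
    w <- generate_world(world_config(n_enzymes = config$n_enzymes,
                                     seed = config$seed))
    write_world(w, file.path(out_dir, "world"))
    .log_stage(logcon, "simulate", t0, n_enzymes = length(w$ids))
    w
  })
  if (is.null(world)) stop("pipeline currently requires synthetic mode")
  sim <- simulate_assay(world)
  props <- emit_property_tables(world)

  # --- assay processing (needed by several later stages) ---
  summ <- run_stage("assay", TRUE, function() {
    t0 <- as.numeric(Sys.time())
    s <- summarize_enzymes(sim$assay, melt = sim$melt, yields = sim$yields)
    write.csv(s$enzymes, file.path(out_dir, "enzyme_summary.csv"),
              row.names = FALSE)
    write.csv(s$conditions, file.path(out_dir, "condition_summary.csv"),
              row.names = FALSE)
    rates <- list(
      any_condition = hit_rate(s),
      per_round = lapply(c(DP = "DP", TEP = "TEP", ESM = "ESM"),
                         function(r) hit_rate(s, round = r)),
      cryPow_55_40 = hit_rate(s, condition = list(substrate = "cryPow",
                                                  pH = 5.5,
                                                  temperature = 40)))
    cont <- condition_contingency(s, "substrate", "cryPow", "aFilm")
    jsonlite::write_json(
      list(hit_rates = rates,
           contingency_substrate = as.list(cont),
           n_cotested = attr(cont, "n_cotested")),
      file.path(out_dir, "assay_report.json"), auto_unbox = TRUE, digits = NA)
    .log_stage(logcon, "assay", t0, n_active = sum(s$enzymes$active))
    s
  })

  active_ids <- summ$enzymes$enzyme_id[summ$enzymes$active]

  # --- align active enzymes ---
  aln <- run_stage("align", st$align, function() {
    t0 <- as.numeric(Sys.time())
    a <- progressive_align(world$sequences[active_ids])
    write_fasta(a, file.path(out_dir, "active_alignment.fasta"))
    stripped <- strip_gappy_columns(a, 0.5)
    nwk <- nj_tree(identity_distance(stripped))
    writeLines(nwk, file.path(out_dir, "active_tree.nwk"))
    .log_stage(logcon, "align", t0, n_rows = length(a))
    a
  })

  # --- profile HMM ---
  hmm <- run_stage("hmm", st$hmm, function() {
    t0 <- as.numeric(Sys.time())
    base_ids <- head(active_ids, config$hmm$n_base_actives)
    h <- tune_hmm(world$sequences[base_ids],
                  match_gap_threshold = config$hmm$match_gap_threshold,
                  pseudocount = config$hmm$pseudocount)
    bits <- score_sequences(h, world$sequences)
    tab <- data.frame(enzyme_id = names(bits), bits = unname(bits))
    write.table(tab, file.path(out_dir, "hmm_scores.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write_profile_json(h, file.path(out_dir, "profile_hmm.json"))
    .log_stage(logcon, "hmm", t0, L = h$L)
    list(hmm = h, bits = bits)
  })

  # --- supervised training at the target condition ---
  train <- run_stage("train", st$train, function() {
    t0 <- as.numeric(Sys.time())
    cnd <- config$train$condition
    cc <- summ$conditions
    sel <- cc$substrate == cnd$substrate & cc$pH == cnd$pH &
      cc$temperature == cnd$temperature
    labels <- setNames(as.integer(cc$active[sel]), cc$enzyme_id[sel])
    if (length(unique(labels)) < 2) {
      .log_stage(logcon, "train", t0, skipped = "single-class labels")
      return(NULL)
    }
    X <- build_features(world$sequences[names(labels)],
                        hmms = if (is.null(hmm)) list() else
                          list(base = hmm$hmm),
                        k = seq_len(config$train$kmax))
    folds <- make_folds(names(labels), k = config$train$folds,
                        seed = config$seed)
    model <- if (config$train$model == "ridge")
      model_ridge(config$train$lambda) else model_bagged_trees()
    pred <- pooled_cv_predict(X, labels, folds, model, seed = config$seed)
    act <- setNames(cc$specific_activity[sel], cc$enzyme_id[sel])
    metrics <- list(
      auroc = auroc(pred$score, pred$label),
      precision = score_metrics(pred$score, pred$label)$precision,
      spearman = score_metrics(pred$score, pred$label,
                               act[pred$id])$spearman)
    write.table(pred, file.path(out_dir, "cv_predictions.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    jsonlite::write_json(metrics, file.path(out_dir, "cv_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    .log_stage(logcon, "train", t0, auroc = metrics$auroc)
    list(pred = pred, metrics = metrics)
  })

  # --- candidate selection demo on the scored pool ---
  sel_out <- run_stage("select", st$select, function() {
    t0 <- as.numeric(Sys.time())
    cand <- data.frame(
      id = world$ids,
      activity = summ$enzymes$max_activity[match(world$ids,
                                                 summ$enzymes$enzyme_id)],
      tm = unname(world$true_tm),
      acid_tolerance = if (is.null(train)) unname(world$acid_prone) * 1 else {
        p <- rep(0, length(world$ids))
        p[match(train$pred$id, world$ids)] <- train$pred$score
        p
      },
      sequence = unname(world$sequences),
      stringsAsFactors = FALSE)
    cand$activity[is.na(cand$activity)] <- 0
    picked <- multiobjective_select(cand,
                                    percentile = config$select$percentile,
                                    identity_threshold =
                                      config$select$identity_threshold)
    write.table(picked[c("id", "admitted_by")],
                file.path(out_dir, "selected_candidates.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    .log_stage(logcon, "select", t0, n_selected = nrow(picked))
    picked
  })

  # --- group analysis ---
  analysis <- run_stage("analyze", st$analyze, function() {
    t0 <- as.numeric(Sys.time())
    split <- tryCatch(split_groups(summ, config$analyze$acid_ph),
                      error = function(e) NULL)
    if (is.null(split)) {
      .log_stage(logcon, "analyze", t0, skipped = "empty group")
      return(NULL)
    }
    cons <- differential_conservation(world$alignment, split,
                                      hi = config$analyze$hi,
                                      lo = config$analyze$lo)
    factors <- position_property_test(props, split,
                                      alpha = config$analyze$alpha)
    prof <- factor_profile(props, factors)
    cc <- summ$conditions
    acid_cc <- cc[cc$pH == config$analyze$acid_ph &
                    cc$substrate == "cryPow" & cc$temperature == 40, ]
    act45 <- setNames(acid_cc$specific_activity, acid_cc$enzyme_id)
    rho <- tryCatch(factor_activity_spearman(prof, act45),
                    error = function(e) NA_real_)
    write.table(factors, file.path(out_dir, "significant_factors.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(cons, file.path(out_dir, "differential_conservation.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    acid_flags <- setNames(cc$enzyme_id %in% split$acid, cc$enzyme_id)
    clusters <- if (is.null(hmm)) NULL else
      cluster_accessory_domains(world$sequences, hmm$hmm,
                                identity_threshold =
                                  config$analyze$accessory_identity,
                                min_length =
                                  config$analyze$accessory_min_length,
                                acid_active = acid_flags)
    jsonlite::write_json(
      list(n_acid = length(split$acid), n_neutral = length(split$neutral),
           n_excluded = length(split$excluded),
           factor_spearman = rho,
           accessory_clusters = clusters),
      file.path(out_dir, "group_analysis.json"), auto_unbox = TRUE,
      digits = NA)
    .log_stage(logcon, "analyze", t0, n_factors = nrow(factors))
    list(split = split, conservation = cons, factors = factors,
         profile = prof, spearman = rho, clusters = clusters)
  })

  res$world <- world
  res$summary <- summ
  res$alignment <- aln
  res$hmm <- hmm
  res$train <- train
  res$selected <- sel_out
  res$analysis <- analysis
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands: `run-all` (default), `simulate`.  Typical use:
#' `Rscript -e 'petscreen::petscreen_cli()' run-all --config cfg.yaml --out out/`
#'
#' @param args command-line arguments (default `commandArgs(TRUE)`)
#' @return exit status (0 success, 1 usage error, 2 stage failure)
#' @export
petscreen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: petscreen <run-all|simulate> [--config file.yaml] [--out dir] [--seed n]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[[1]]
  opts <- list(config = NULL, out = "petscreen_out", seed = 1L)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (!key %in% names(opts) || i == length(args)) {
      message(usage); return(invisible(1L))
    }
    opts[[key]] <- args[[i + 1]]
    i <- i + 2
  }
  opts$seed <- as.integer(opts$seed)
  status <- tryCatch({
    if (cmd == "run-all") {
      cfg <- if (is.null(opts$config)) default_pipeline_config(opts$seed)
      else opts$config
      run_pipeline(cfg, opts$out)
      0L
    } else if (cmd == "simulate") {
      w <- generate_world(world_config(seed = opts$seed))
      write_world(w, opts$out)
      0L
    } else {
      message(usage)
      1L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
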
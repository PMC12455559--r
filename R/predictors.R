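# Condition-specific supervised activity prediction: feature construction,
# cross-validation plans, pooled out-of-fold prediction, and evaluation
# metrics (AUROC, precision at 0.5, Spearman).

# run expr with a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' k-mer composition features
#'
#' Explicit k-mer frequency blocks for each k; each block sums to 1 per
#' sequence (sequences shorter than k give an all-zero block).  k-mers
#' containing 'X' are skipped.
#'
#' @param seqs named character vector of ungapped sequences
#' @param k integer vector of k-mer sizes (default `1:2`)
#' @return numeric matrix, rows = sequences, named columns per k-mer
#' @export
kmer_features <- function(seqs, k = 1:2) {
  seqs <- toupper(gsub("-", "", seqs))
  blocks <- lapply(k, function(kk) {
    lev <- apply(expand.grid(rep(list(AA_ALPHABET), kk),
                             stringsAsFactors = FALSE)[rev(seq_len(kk))],
                 1, paste, collapse = "")
    out <- matrix(0, length(seqs), length(lev),
                  dimnames = list(names(seqs), paste0("k", kk, "_", lev)))
    for (i in seq_along(seqs)) {
      n <- nchar(seqs[[i]])
      if (n < kk) next
      km <- substring(seqs[[i]], seq_len(n - kk + 1), seq_len(n - kk + 1) + kk - 1)
      tb <- table(factor(km, levels = lev))
      tot <- sum(tb)
      if (tot > 0) out[i, ] <- as.numeric(tb) / tot
    }
    out
  })
  do.call(cbind, blocks)
}

#' Build the default feature matrix for supervised predictors
#'
#' k-mer composition plus profile-HMM bit scores (raw and
#' reference-normalized when a reference is given), plus an optional
#' externally supplied embedding table.
#'
#' @param seqs named character vector
#' @param hmms named list of `profile_hmm` objects whose scores become
#'   features (may be empty)
#' @param reference optional id used to normalize HMM scores
#' @param embedding optional numeric matrix (rows named by sequence id)
#'   loaded from an external table, substituting for language-model
#'   embeddings
#' @param k k-mer sizes
#' @return numeric feature matrix with one row per sequence
#' @export
build_features <- function(seqs, hmms = list(), reference = NULL,
                           embedding = NULL, k = 1:2) {
  X <- kmer_features(seqs, k = k)
  for (nm in names(hmms)) {
    sc <- score_sequences(hmms[[nm]], seqs)
    X <- cbind(X, setNames(data.frame(sc), paste0("hmm_", nm)))
    if (!is.null(reference) && reference %in% names(seqs)) {
      ns <- normalize_scores(sc, reference)$normalized
      X <- cbind(X, setNames(data.frame(ns), paste0("hmmnorm_", nm)))
    }
  }
  X <- as.matrix(X)
  if (!is.null(embedding)) {
    miss <- setdiff(rownames(X), rownames(embedding))
    if (length(miss)) stop("embedding table missing ids: ",
                           paste(head(miss, 5), collapse = ", "))
    X <- cbind(X, embedding[rownames(X), , drop = FALSE])
  }
  X
}

#' Random k-fold cross-validation plan
#'
#' @param ids example identifiers
#' @param k number of folds (default 5)
#' @param seed RNG seed controlling the partition
#' @return data.frame with columns `id` and `fold`; class `cv_plan`
#' @export
make_folds <- function(ids, k = 5, seed = 1) {
  n <- length(ids)
  if (k > n) stop("k (", k, ") exceeds number of examples (", n, ")")
  fold <- .with_seed(seed, sample(rep_len(seq_len(k), n)))
  out <- data.frame(id = ids, fold = fold, stringsAsFactors = FALSE)
  class(out) <- c("cv_plan", "data.frame")
  out
}

#' Cross-split sequence identity diagnostic
#'
#' For every pair of folds computes the maximum and mean pairwise identity
#' between members, and reports the maximum of the per-pair maxima and the
#' mean of the per-pair means.
#'
#' @param seqs named character vector (ids must cover the plan)
#' @param folds a `cv_plan`
#' @return list with `max_of_max`, `mean_of_means`, and the per-pair table
#' @export
cross_split_identity <- function(seqs, folds) {
  ks <- sort(unique(folds$fold))
  pairs <- combn(ks, 2)
  res <- data.frame(fold1 = pairs[1, ], fold2 = pairs[2, ],
                    max_identity = NA_real_, mean_identity = NA_real_)
  for (r in seq_len(ncol(pairs))) {
    a <- folds$id[folds$fold == pairs[1, r]]
    b <- folds$id[folds$fold == pairs[2, r]]
    idm <- outer(a, b, Vectorize(function(x, y)
      pairwise_identity(seqs[[x]], seqs[[y]])))
    res$max_identity[r] <- max(idm)
    res$mean_identity[r] <- mean(idm)
  }
  list(max_of_max = max(res$max_identity),
       mean_of_means = mean(res$mean_identity),
       pairs = res)
}

#' Bagged decision-tree model specification
#'
#' An ensemble of `ntree` CART trees grown on bootstrap samples with a
#' random feature subset at each node; the predicted probability is the
#' fraction of trees voting "active".
#'
#' @param ntree number of trees (default 100)
#' @param mtry features tried per split (default `sqrt(p)`)
#' @param max_depth,min_node tree growth limits
#' @return a model spec (list with `fit` and `predict`) usable by
#'   [pooled_cv_predict()]
#' @export
model_bagged_trees <- function(ntree = 100, mtry = NULL, max_depth = 6,
                               min_node = 5) {
  list(
    name = "bagged_trees",
    fit = function(X, y) {
      if (length(unique(y)) < 2) return(list(constant = mean(y)))
      m <- if (is.null(mtry)) max(1L, floor(sqrt(ncol(X)))) else mtry
      list(trees = .forest_fit_cpp(X, as.integer(y), ntree, m,
                                   max_depth, min_node))
    },
    predict = function(model, X) {
      if (!is.null(model$constant)) return(rep(model$constant, nrow(X)))
      .forest_predict_cpp(model$trees, X)
    }
  )
}

#' Ridge-regularized linear model specification
#'
#' Logistic ridge for binary labels (glmnet, alpha = 0, fixed lambda).
#'
#' @param lambda L2 penalty (default 1)
#' @return a model spec usable by [pooled_cv_predict()]
#' @export
model_ridge <- function(lambda = 1) {
  list(
    name = "ridge",
    fit = function(X, y) {
      if (length(unique(y)) < 2) return(list(constant = mean(y)))
      # small per-condition datasets routinely trip glmnet's class-size
      # advisory; the constant-model guard above covers the degenerate case
      list(fit = suppressWarnings(
        glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                       lambda = lambda, standardize = TRUE)))
    },
    predict = function(model, X) {
      if (!is.null(model$constant)) return(rep(model$constant, nrow(X)))
      as.numeric(predict(model$fit, X, type = "response"))
    }
  )
}

#' Pooled cross-validated predictions
#'
#' For each fold, trains on the remaining folds and predicts the held-out
#' examples; out-of-fold predictions are concatenated so that downstream
#' metrics are computed once over the whole dataset ("scores over
#' cross-validated predictions"), while no example is ever predicted by a
#' model that saw it in training.
#'
#' @param X feature matrix with rownames = ids
#' @param labels named 0/1 vector (untested examples must already be
#'   excluded)
#' @param folds a `cv_plan` over `names(labels)`
#' @param model a model spec (e.g. [model_bagged_trees()], [model_ridge()])
#' @param seed RNG seed for model fitting
#' @return data.frame: `id`, `fold`, `score`, `label`
#' @export
pooled_cv_predict <- function(X, labels, folds, model = model_bagged_trees(),
                              seed = 1) {
  ids <- folds$id
  if (!all(ids %in% rownames(X))) stop("feature matrix missing ids")
  if (!all(ids %in% names(labels))) stop("labels missing ids")
  out <- vector("list", max(folds$fold))
  for (k in sort(unique(folds$fold))) {
    test_ids <- ids[folds$fold == k]
    train_ids <- ids[folds$fold != k]
    if (!length(test_ids) || !length(train_ids)) {
      stop("fold ", k, " has an empty train or test set")
    }
    fitted <- .with_seed(seed + k,
                         model$fit(X[train_ids, , drop = FALSE],
                                   labels[train_ids]))
    sc <- model$predict(fitted, X[test_ids, , drop = FALSE])
    out[[k]] <- data.frame(id = test_ids, fold = k, score = sc,
                           label = unname(labels[test_ids]),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Compare base HMM, tuned HMM and supervised predictors at one condition
#'
#' Reproduces the model-comparison protocol for a single assay condition:
#' a base profile HMM is built from a held-out set of enzymes (typically
#' the "known" hydrolases, biased away from the target condition); for each
#' cross-validation fold the HMM is re-tuned with the condition-active
#' training enzymes and used to score the held-out fold, normalizing by a
#' reference enzyme so fold scores pool; the supervised model is trained
#' per fold on sequence length plus the base and fold-tuned HMM bit scores
#' (optionally k-mer composition blocks).  All three AUROCs are computed
#' over pooled out-of-fold predictions.
#'
#' @param seqs named character vector covering base and evaluation ids
#' @param labels named 0/1 vector: activity call at the target condition
#'   for the evaluation enzymes (base ids are removed if present)
#' @param base_ids ids of the base-HMM training set (never evaluated)
#' @param k_folds folds (default 5)
#' @param model supervised model spec (default `model_ridge(0.01)`)
#' @param kmer_k k-mer sizes for the supervised features, or `NULL`
#'   (default) for the compact feature set (length + HMM scores), which is
#'   better suited to the screen-scale sample sizes
#' @param reference id whose bit score normalizes each fold-tuned HMM's
#'   scores before pooling (default: the first base id), so scores from
#'   different splits are comparable
#' @param seed RNG seed for folds and model fitting
#' @return list: `auroc` (named: base, tuned, supervised), `predictions`
#'   (pooled data.frame), `folds`
#' @export
condition_predictor_experiment <- function(seqs, labels, base_ids,
                                           k_folds = 5,
                                           model = model_ridge(0.01),
                                           kmer_k = NULL,
                                           reference = base_ids[[1]],
                                           seed = 1) {
  labels <- labels[setdiff(names(labels), base_ids)]
  eval_ids <- names(labels)
  if (length(unique(labels)) < 2) stop("need both classes in evaluation set")
  base_hmm <- tune_hmm(seqs[base_ids])
  base_scores <- score_sequences(base_hmm, seqs[eval_ids])
  folds <- make_folds(eval_ids, k_folds, seed = seed)
  Xk <- if (is.null(kmer_k)) {
    cbind(length = nchar(seqs[eval_ids]))
  } else {
    cbind(kmer_features(seqs[eval_ids], k = kmer_k),
          length = nchar(seqs[eval_ids]))
  }
  tuned_scores <- setNames(numeric(length(eval_ids)), eval_ids)
  sup <- vector("list", k_folds)
  for (k in sort(unique(folds$fold))) {
    test_ids <- folds$id[folds$fold == k]
    train_ids <- folds$id[folds$fold != k]
    cond_active <- train_ids[labels[train_ids] == 1]
    tuned <- tune_hmm(seqs[base_ids], seqs[cond_active])
    fold_scores <- score_sequences(tuned, seqs[eval_ids])
    ref_bits <- forward_bitscore(tuned, seqs[[reference]])
    norm_scores <- if (ref_bits != 0) fold_scores / ref_bits else fold_scores
    tuned_scores[test_ids] <- norm_scores[test_ids]
    X <- cbind(Xk, hmm_base = base_scores, hmm_tuned = fold_scores)
    fitted <- .with_seed(seed + k, model$fit(X[train_ids, , drop = FALSE],
                                             labels[train_ids]))
    sup[[k]] <- data.frame(id = test_ids, fold = k,
                           score = model$predict(fitted,
                                                 X[test_ids, , drop = FALSE]),
                           label = unname(labels[test_ids]),
                           stringsAsFactors = FALSE)
  }
  sup <- do.call(rbind, sup)
  list(auroc = c(base = auroc(base_scores, labels[eval_ids]),
                 tuned = auroc(tuned_scores, labels[eval_ids]),
                 supervised = auroc(sup$score, sup$label)),
       predictions = sup, folds = folds,
       base_scores = base_scores, tuned_scores = tuned_scores)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with half credit for ties:
#' `U / (n1 * n0)`.
#'
#' @param scores numeric prediction scores
#' @param labels 0/1 labels (both classes must be present)
#' @return AUROC in \[0, 1\]
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # average ranks handle ties with half credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification and ranking metrics for pooled predictions
#'
#' Precision among predictions above 0.5 (the default decision boundary) and
#' the Spearman correlation of the prediction score against a continuous
#' activity when provided.
#'
#' @param predictions scores in \[0, 1\]
#' @param labels 0/1 labels
#' @param activity optional continuous activity values
#' @param boundary decision boundary (default 0.5; predictions strictly
#'   above are called positive)
#' @return list with `precision` (NA if no positive predictions),
#'   `spearman` (NA if `activity` missing), `n_positive_pred`
#' @export
score_metrics <- function(predictions, labels, activity = NULL,
                          boundary = 0.5) {
  pos <- predictions > boundary
  precision <- if (!any(pos)) NA_real_ else mean(labels[pos] == 1)
  spearman <- if (is.null(activity)) NA_real_ else
    suppressWarnings(cor(predictions, activity, method = "spearman"))
  list(precision = precision, spearman = spearman,
       n_positive_pred = sum(pos))
}
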
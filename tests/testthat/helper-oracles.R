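# Independent oracles used across the suite.  These deliberately avoid the
# package's own algorithms: path enumeration instead of dynamic programming,
# pair counting instead of rank sums, recursive alignment enumeration
# instead of Gotoh, direct tabulation instead of vectorized summaries.

# --- profile HMM: random tiny model and full path enumeration -------------

rand_tiny_hmm <- function(L) {
  norm <- function(x) x / sum(x)
  me <- sapply(seq_len(L), function(k) norm(runif(20)))
  rownames(me) <- AA_ALPHABET
  mm <- mi <- md <- im <- ii <- dm <- dd <- numeric(L + 1)
  for (k in 0:L) {
    t3 <- norm(runif(3)); t2 <- norm(runif(2)); d2 <- norm(runif(2))
    if (k == L) { t3 <- c(norm(runif(2)), 0); d2 <- c(1, 0) }
    mm[k + 1] <- t3[1]; mi[k + 1] <- t3[2]; md[k + 1] <- t3[3]
    im[k + 1] <- t2[1]; ii[k + 1] <- t2[2]
    dm[k + 1] <- d2[1]; dd[k + 1] <- d2[2]
  }
  structure(list(L = L, match_emissions = me,
                 insert_emissions = setNames(norm(runif(20)), AA_ALPHABET),
                 background = setNames(rep(1 / 20, 20), AA_ALPHABET),
                 mm = mm, mi = mi, md = md, im = im, ii = ii,
                 dm = dm, dd = dd, mode = "global",
                 match_cols = seq_len(L), alignment = NULL),
            class = "profile_hmm")
}

# sum of odds over every Begin..End state path emitting exactly `seq`
enum_forward_logprob <- function(h, seq) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x); L <- h$L
  bg <- h$background
  total <- 0
  rec <- function(state, k, i, w) {
    if (k == L) {
      tE <- switch(state, M = h$mm[L + 1], I = h$im[L + 1], D = h$dm[L + 1])
      if (i == n) total <<- total + w * tE
    }
    if (k < L && i < n) {
      t <- switch(state, M = h$mm[k + 1], I = h$im[k + 1], D = h$dm[k + 1])
      e <- h$match_emissions[x[i + 1], k + 1] / bg[[x[i + 1]]]
      rec("M", k + 1, i + 1, w * t * e)
    }
    if (i < n && state %in% c("M", "I")) {
      t <- if (state == "M") h$mi[k + 1] else h$ii[k + 1]
      e <- h$insert_emissions[[x[i + 1]]] / bg[[x[i + 1]]]
      rec("I", k, i + 1, w * t * e)
    }
    if (k < L && state %in% c("M", "D")) {
      t <- if (state == "M") h$md[k + 1] else h$dd[k + 1]
      rec("D", k + 1, i, w * t)
    }
  }
  rec("M", 0, 0, 1)
  log(unname(total))
}

# --- AUROC: concordant/discordant pair counting ---------------------------

auroc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# --- Mann-Whitney: enumeration with direct pair counting ------------------

mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ustat <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    s <- 0
    for (v in a) for (w in b) s <- s + if (v > w) 1 else if (v == w) 0.5 else 0
    s
  }
  u_obs <- ustat(seq_len(n1))
  mu <- n1 * (length(pooled) - n1) / 2
  devs <- apply(combn(length(pooled), n1), 2, function(idx)
    abs(ustat(idx) - mu))
  mean(devs >= abs(u_obs - mu) - 1e-9)
}

# --- pairwise global alignment: exhaustive affine-gap enumeration ---------

enum_align_best <- function(a, b, submat = blosum62(), gap_open = -11,
                            gap_extend = -1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, state, sc) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, sc)
      return()
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, "M", sc + submat[ca[i], cb[j]])
    }
    if (i <= length(ca)) {
      rec(i + 1, j, "X", sc + if (state == "X") gap_extend else gap_open)
    }
    if (j <= length(cb)) {
      rec(i, j + 1, "Y", sc + if (state == "Y") gap_extend else gap_open)
    }
  }
  rec(1, 1, "S", 0)
  best
}

# --- synthetic world: shared fixtures -------------------------------------

# small world used by several module tests (cached per session)
.test_env <- new.env()
small_world <- function(seed = 42, n = 80) {
  key <- paste0("w", seed, "_", n)
  if (is.null(.test_env[[key]])) {
    .test_env[[key]] <- generate_world(world_config(n_enzymes = n, seed = seed))
  }
  .test_env[[key]]
}

# fraction of truly aligned residue pairs recovered by a test alignment
column_pair_recovery <- function(true_aln, test_aln) {
  pair_sets <- function(aln) {
    m <- do.call(rbind, strsplit(unname(aln), ""))
    rownames(m) <- names(aln)
    # per sequence: residue index at each column (0 if gap)
    idx <- t(apply(m != "-", 1, cumsum))
    idx[m == "-"] <- 0L
    pairs <- character(0)
    nr <- nrow(m)
    for (r1 in seq_len(nr - 1)) for (r2 in (r1 + 1):nr) {
      both <- idx[r1, ] > 0 & idx[r2, ] > 0
      pairs <- c(pairs, paste(rownames(m)[r1], idx[r1, both],
                              rownames(m)[r2], idx[r2, both]))
    }
    pairs
  }
  truth <- pair_sets(true_aln)
  got <- pair_sets(test_aln[names(true_aln)])
  mean(truth %in% got)
}
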
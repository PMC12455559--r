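# Comparison of low-pH-active versus neutral-only-active enzymes:
# group splitting, differential conservation, per-position Mann-Whitney
# statistics, hydropathy profiles, factor counting, reference mapping and
# accessory-domain clustering.

#' Split active enzymes into acid-tolerant and neutral groups
#'
#' Acid group: enzymes with a positive activity call at `acid_ph`.  Neutral
#' group: enzymes active overall, tested at `acid_ph`, but inactive there.
#' Active enzymes never tested at `acid_ph` are excluded (they cannot be
#' classified either way).
#'
#' @param summary an `enzyme_summary`
#' @param acid_ph the low-pH condition defining acid tolerance (default 4.5)
#' @return list of class `group_split`: `acid`, `neutral`, `excluded`
#'   (character vectors of enzyme ids)
#' @export
split_groups <- function(summary, acid_ph = 4.5) {
  cond <- summary$conditions
  enz <- summary$enzymes
  active_ids <- enz$enzyme_id[enz$active]
  tested_acid <- vapply(active_ids, function(i)
    any(cond$enzyme_id == i & cond$pH == acid_ph), logical(1))
  acid <- vapply(active_ids, function(i)
    any(cond$enzyme_id == i & cond$pH == acid_ph & cond$active), logical(1))
  out <- list(acid = active_ids[acid],
              neutral = active_ids[tested_acid & !acid],
              excluded = active_ids[!tested_acid])
  if (!length(out$acid) || !length(out$neutral)) {
    stop("acid or neutral group is empty; group comparison is undefined")
  }
  class(out) <- "group_split"
  out
}

#' Mann-Whitney U test (exact for small samples, tie-corrected normal
#' otherwise)
#'
#' Two-sided test of location difference between `x` and `y`.  For combined
#' n at most `exact_max`, the exact two-sided p-value is computed by full
#' enumeration of group assignments (which handles ties naturally);
#' otherwise a tie-corrected normal approximation with continuity correction
#' is used.  All-tied data give p = 1.
#'
#' @param x,y numeric samples
#' @param exact_max maximum combined sample size for exact enumeration
#'   (default 12)
#' @return list: `U1`, `U2`, `p`, `method`
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be nonempty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  if (length(unique(pooled)) == 1) {
    return(list(U1 = U1, U2 = U2, p = 1, method = "degenerate"))
  }
  N <- n1 + n2
  if (N <= exact_max) {
    combs <- combn(N, n1)
    dev_obs <- abs(U1 - n1 * n2 / 2)
    rr <- rank(pooled)
    devs <- apply(combs, 2, function(idx) {
      u <- sum(rr[idx]) - n1 * (n1 + 1) / 2
      abs(u - n1 * n2 / 2)
    })
    p <- mean(devs >= dev_obs - 1e-9)
    return(list(U1 = U1, U2 = U2, p = p, method = "exact"))
  }
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U1 = U1, U2 = U2, p = 1, method = "normal"))
  z <- (abs(U1 - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p <- min(1, 2 * pnorm(-z))
  list(U1 = U1, U2 = U2, p = p, method = "normal")
}

#' Differential conservation of physicochemical classes between groups
#'
#' For each alignment column and residue class, computes the class frequency
#' in each group (gaps count as not-in-class) and flags columns conserved in
#' one group (frequency >= `hi`) but not the other (<= `lo`), in either
#' direction.
#'
#' @param aln named character vector alignment containing all group members
#' @param split a `group_split`
#' @param classes residue-class taxonomy (default [RESIDUE_CLASSES])
#' @param hi,lo conservation thresholds (defaults 0.9 and 0.5)
#' @return data.frame: `column`, `class`, `freq_acid`, `freq_neutral`,
#'   `conserved_in`
#' @export
differential_conservation <- function(aln, split, classes = RESIDUE_CLASSES,
                                      hi = 0.9, lo = 0.5) {
  miss <- setdiff(c(split$acid, split$neutral), names(aln))
  if (length(miss)) stop("group members missing from alignment: ",
                         paste(head(miss, 5), collapse = ", "))
  m <- aln_matrix(aln)
  ma <- m[split$acid, , drop = FALSE]
  mn <- m[split$neutral, , drop = FALSE]
  res <- list()
  for (cl in names(classes)) {
    fa <- colMeans(matrix(ma %in% classes[[cl]], nrow(ma)))
    fn <- colMeans(matrix(mn %in% classes[[cl]], nrow(mn)))
    up <- fa >= hi & fn <= lo
    dn <- fn >= hi & fa <= lo
    hitcols <- which(up | dn)
    if (length(hitcols)) {
      res[[cl]] <- data.frame(
        column = hitcols, class = cl,
        freq_acid = fa[hitcols], freq_neutral = fn[hitcols],
        conserved_in = ifelse(up[hitcols], "acid", "neutral"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(column = integer(0), class = character(0),
               freq_acid = numeric(0), freq_neutral = numeric(0),
               conserved_in = character(0))
  rownames(out) <- NULL
  out
}

#' Per-position property tests between groups
#'
#' Runs a two-sided Mann-Whitney U test for every (alignment column,
#' property) with at least `min_group` values in each group, and returns the
#' significant factors at `alpha` with their group means and mean difference
#' (acid minus neutral).  No multiple-testing correction is applied by
#' default (set `adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param properties data.frame: `enzyme_id`, `column`, `property`, `value`
#' @param split a `group_split`
#' @param alpha significance level (default 0.05)
#' @param min_group minimum group size per test (default 3)
#' @param adjust `"none"` (default) or `"BH"`
#' @param exact_max passed to [mann_whitney_u()]
#' @return data.frame of significant factors: `column`, `property`,
#'   `mean_acid`, `mean_neutral`, `mean_diff`, `p`
#' @export
position_property_test <- function(properties, split, alpha = 0.05,
                                   min_group = 3, adjust = c("none", "BH"),
                                   exact_max = 12) {
  adjust <- match.arg(adjust)
  keep <- properties$enzyme_id %in% c(split$acid, split$neutral)
  pr <- properties[keep, ]
  pr$grp <- ifelse(pr$enzyme_id %in% split$acid, "acid", "neutral")
  out <- list()
  for (prop in unique(pr$property)) {
    pp <- pr[pr$property == prop, ]
    for (col in unique(pp$column)) {
      x <- pp$value[pp$column == col & pp$grp == "acid"]
      y <- pp$value[pp$column == col & pp$grp == "neutral"]
      if (length(x) < min_group || length(y) < min_group) next
      mw <- mann_whitney_u(x, y, exact_max = exact_max)
      out[[length(out) + 1]] <- data.frame(
        column = col, property = prop,
        mean_acid = mean(x), mean_neutral = mean(y),
        mean_diff = mean(x) - mean(y), p = mw$p,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(column = integer(0), property = character(0),
               mean_acid = numeric(0), mean_neutral = numeric(0),
               mean_diff = numeric(0), p = numeric(0))
  if (adjust == "BH" && nrow(res)) res$p <- stats::p.adjust(res$p, "BH")
  res <- res[res$p < alpha, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Kyte-Doolittle hydropathy profile
#'
#' Windowed mean of the Kyte-Doolittle scale, centered on each residue;
#' ends use truncated windows.  'X' contributes nothing to a window.
#'
#' @param seq residue string
#' @param window odd window size, at most the sequence length (default 9)
#' @return numeric vector, one value per residue
#' @export
kyte_doolittle_profile <- function(seq, window = 9) {
  ch <- strsplit(toupper(seq), "")[[1]]
  if (window %% 2 != 1) stop("window must be odd")
  if (window > length(ch)) stop("window exceeds sequence length")
  vals <- KYTE_DOOLITTLE[ch]  # NA for X
  half <- (window - 1) / 2
  vapply(seq_along(vals), function(i) {
    w <- vals[max(1, i - half):min(length(vals), i + half)]
    mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Factor profiles: which significant factors does each enzyme exhibit?
#'
#' An enzyme exhibits a factor when its value at that (column, property) is
#' strictly closer to the acid-group mean than to the neutral-group mean;
#' equidistant or missing values do not count.
#'
#' @param properties data.frame: `enzyme_id`, `column`, `property`, `value`
#' @param factors data.frame from [position_property_test()]
#' @return data.frame: `enzyme_id`, `n_factors` (with per-factor flags in
#'   attribute `"flags"`)
#' @export
factor_profile <- function(properties, factors) {
  ids <- unique(properties$enzyme_id)
  if (!nrow(factors)) {
    return(data.frame(enzyme_id = ids, n_factors = 0L))
  }
  flags <- matrix(FALSE, length(ids), nrow(factors),
                  dimnames = list(ids, paste0(factors$property, "@",
                                              factors$column)))
  for (f in seq_len(nrow(factors))) {
    sel <- properties$column == factors$column[f] &
      properties$property == factors$property[f]
    v <- properties$value[sel]
    who <- properties$enzyme_id[sel]
    da <- abs(v - factors$mean_acid[f])
    dn <- abs(v - factors$mean_neutral[f])
    flags[who[da < dn], f] <- TRUE
  }
  out <- data.frame(enzyme_id = ids, n_factors = as.integer(rowSums(flags)),
                    stringsAsFactors = FALSE)
  attr(out, "flags") <- flags
  out
}

#' Spearman correlation of factor count against measured activity
#'
#' @param profile data.frame from [factor_profile()]
#' @param activity named numeric vector of per-enzyme activity (e.g. at the
#'   low-pH condition); enzymes missing from it are dropped
#' @return Spearman rho
#' @export
factor_activity_spearman <- function(profile, activity) {
  common <- intersect(profile$enzyme_id, names(activity))
  if (length(common) < 3) stop("need at least 3 enzymes with activity")
  cts <- profile$n_factors[match(common, profile$enzyme_id)]
  suppressWarnings(cor(cts, activity[common], method = "spearman"))
}

#' Map alignment columns to reference residue numbers
#'
#' @param aln named character vector alignment
#' @param reference id of the reference row
#' @return integer vector over columns: 1-based residue number in the
#'   (degapped) reference, `NA` where the reference is gapped
#' @export
map_to_reference <- function(aln, reference) {
  if (!reference %in% names(aln)) stop("reference '", reference,
                                       "' not in alignment")
  ch <- strsplit(aln[[reference]], "")[[1]]
  out <- rep(NA_integer_, length(ch))
  out[ch != "-"] <- seq_len(sum(ch != "-"))
  out
}

#' Cluster accessory (non-catalytic) domains and their low-pH hit rates
#'
#' Aligns each sequence to the catalytic-domain profile (uni-local Viterbi);
#' residues outside the matched span form accessory segments, which are
#' clustered by single linkage at a pairwise-identity threshold.  Each
#' cluster is annotated with the fraction of its members active at the
#' low-pH condition when activity flags are supplied.
#'
#' @param seqs named character vector of full-length sequences
#' @param hmm catalytic-domain `profile_hmm`
#' @param identity_threshold single-linkage identity threshold (default
#'   0.35)
#' @param min_length minimum accessory-segment length (default 40)
#' @param acid_active optional named logical: active at the low-pH condition
#' @return data.frame: `cluster`, `n`, `members`, `acid_hit_rate`; empty when
#'   no accessory segments exist
#' @export
cluster_accessory_domains <- function(seqs, hmm, identity_threshold = 0.35,
                                      min_length = 40, acid_active = NULL) {
  segs <- character(0)
  for (i in seq_along(seqs)) {
    v <- align_to_profile(hmm, seqs[[i]], mode = "unilocal")
    n <- nchar(seqs[[i]])
    if (v$span[1] == 0) next  # nothing matched
    pre <- if (v$span[1] > 1) substr(seqs[[i]], 1, v$span[1] - 1) else ""
    post <- if (v$span[2] < n) substr(seqs[[i]], v$span[2] + 1, n) else ""
    if (nchar(pre) >= min_length) segs[[paste0(names(seqs)[i], "|N")]] <- pre
    if (nchar(post) >= min_length) segs[[paste0(names(seqs)[i], "|C")]] <- post
  }
  if (!length(segs)) {
    return(data.frame(cluster = integer(0), n = integer(0),
                      members = character(0), acid_hit_rate = numeric(0)))
  }
  if (length(segs) == 1) {
    cl <- setNames(1L, names(segs))
  } else {
    n <- length(segs)
    D <- matrix(0, n, n, dimnames = list(names(segs), names(segs)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- 1 - pairwise_identity(segs[[i]], segs[[j]])
    }
    hc <- hclust(as.dist(D), method = "single")
    cl <- cutree(hc, h = 1 - identity_threshold)
  }
  out <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    mem <- names(cl)[cl == k]
    enz <- sub("\\|[NC]$", "", mem)
    hr <- if (is.null(acid_active)) NA_real_ else
      mean(acid_active[enz], na.rm = TRUE)
    data.frame(cluster = k, n = length(mem),
               members = paste(mem, collapse = ","),
               acid_hit_rate = hr, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
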
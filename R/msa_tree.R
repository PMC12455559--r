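# Progressive multiple alignment and distance trees.

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment under an affine gap model: a gap of length k
#' costs `gap_open + (k - 1) * gap_extend`.  Traceback ties are broken
#' deterministically: match/mismatch, then gap in `b`, then gap in `a`.
#'
#' @param a,b residue strings
#' @param submat substitution matrix with residue dimnames
#'   (default BLOSUM62 including 'X')
#' @param gap_open,gap_extend gap penalties (negative)
#' @return list with `score` and the two aligned strings `a`, `b`
#' @export
needleman_wunsch <- function(a, b, submat = blosum62(),
                             gap_open = -11, gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  .nw_align_cpp(toupper(a), toupper(b), submat,
                paste(rownames(submat), collapse = ""), gap_open, gap_extend)
}

# character matrix view of an alignment (rows = sequences)
aln_matrix <- function(aln) {
  if (length(unique(nchar(aln))) != 1) stop("unequal alignment row lengths")
  m <- do.call(rbind, strsplit(unname(aln), ""))
  rownames(m) <- names(aln)
  m
}

# column frequency profile (20 standard residues; gaps/X carry no weight)
.profile_freq <- function(aln) {
  m <- aln_matrix(aln)
  nr <- nrow(m)
  idx <- match(m, AA_ALPHABET)  # NA for gaps/X
  f <- matrix(0, ncol(m), 20, dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(ncol(m))) {
    v <- idx[(j - 1) * nr + seq_len(nr)]
    f[j, ] <- tabulate(v[!is.na(v)], 20) / nr
  }
  f
}

# k-mer similarity distance used for the guide tree (MUSCLE-style):
# d = 1 - (shared k-mer count) / (smaller k-mer total)
.kmer_distance <- function(seqs, k = 3) {
  n <- length(seqs)
  counts <- lapply(seqs, function(s) {
    s <- gsub("-", "", s)
    if (nchar(s) < k) return(table(character(0)))
    table(substring(s, seq_len(nchar(s) - k + 1),
                    seq_len(nchar(s) - k + 1) + k - 1))
  })
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ci <- counts[[i]]; cj <- counts[[j]]
      common <- intersect(names(ci), names(cj))
      shared <- if (length(common)) sum(pmin(ci[common], cj[common])) else 0
      tot <- min(sum(ci), sum(cj))
      d <- if (tot == 0) 1 else 1 - shared / tot
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Progressive multiple sequence alignment
#'
#' Aligns sequences progressively: a UPGMA guide tree is built on k-mer
#' distances, then profiles are merged up the tree with affine-gap
#' profile-profile alignment (occupancy-weighted expected BLOSUM62 column
#' scores).
#'
#' @param seqs named character vector of ungapped sequences
#' @param submat substitution matrix (20x20 part is used)
#' @param gap_open,gap_extend gap penalties (negative)
#' @param guide_k k-mer size for guide-tree distances
#' @return named character vector of equal-length gapped rows, in input order
#' @export
progressive_align <- function(seqs, submat = blosum62(),
                              gap_open = -11, gap_extend = -1, guide_k = 3) {
  .check_ids(names(seqs))
  seqs <- toupper(seqs)
  if (length(seqs) == 1) return(seqs)
  sm20 <- submat[AA_ALPHABET, AA_ALPHABET]
  merge_profiles <- function(aln_a, aln_b) {
    pa <- .profile_freq(aln_a)
    pb <- .profile_freq(aln_b)
    res <- .profile_align_cpp(pa, pb, sm20, gap_open, gap_extend)
    expand <- function(aln, map) {
      m <- aln_matrix(aln)
      out <- matrix("-", nrow(m), length(map), dimnames = list(rownames(m), NULL))
      out[, map > 0] <- m[, map[map > 0], drop = FALSE]
      setNames(apply(out, 1, paste, collapse = ""), rownames(m))
    }
    c(expand(aln_a, res$map_a), expand(aln_b, res$map_b))
  }
  if (length(seqs) == 2) {
    ali <- needleman_wunsch(seqs[[1]], seqs[[2]], submat, gap_open, gap_extend)
    return(setNames(c(ali$a, ali$b), names(seqs)))
  }
  D <- .kmer_distance(seqs, k = guide_k)
  hc <- hclust(as.dist(D), method = "average")  # UPGMA
  profiles <- lapply(seqs, function(s) s)  # leaves: single-row alignments
  nodes <- vector("list", nrow(hc$merge))
  for (r in seq_len(nrow(hc$merge))) {
    get <- function(k) {
      if (k < 0) setNames(seqs[-k], names(seqs)[-k]) else nodes[[k]]
    }
    nodes[[r]] <- merge_profiles(get(hc$merge[r, 1]), get(hc$merge[r, 2]))
  }
  out <- nodes[[length(nodes)]]
  out[names(seqs)]
}

#' Remove gap-rich alignment columns
#'
#' Drops columns whose gap fraction exceeds `max_gap_fraction`.  The retained
#' columns' original indices are kept in the `"colmap"` attribute.
#'
#' @param aln named character vector alignment
#' @param max_gap_fraction columns with gap fraction strictly above this are
#'   removed (default 0.5)
#' @return the filtered alignment with attribute `colmap`
#' @export
strip_gappy_columns <- function(aln, max_gap_fraction = 0.5) {
  m <- aln_matrix(aln)
  gapfrac <- colMeans(m == "-")
  keep <- which(gapfrac <= max_gap_fraction)
  if (!length(keep)) stop("all columns exceed the gap-fraction threshold")
  out <- setNames(apply(m[, keep, drop = FALSE], 1, paste, collapse = ""),
                  rownames(m))
  attr(out, "colmap") <- keep
  out
}

#' Pairwise identity distance matrix from an alignment
#'
#' Distance is `1 - identity`, with identity computed over columns where both
#' rows are ungapped ('X' never matches).  Pairs with no shared columns get
#' distance 1.
#'
#' @param aln named character vector alignment
#' @return symmetric numeric matrix with zero diagonal
#' @export
identity_distance <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(both)) { D[i, j] <- D[j, i] <- 1; next }
      ident <- sum(m[i, both] == m[j, both] & m[i, both] != "X")
      D[i, j] <- D[j, i] <- 1 - ident / sum(both)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Builds an unrooted neighbor-joining tree (the standard greedy
#' minimum-evolution heuristic).  Rows are ordered lexicographically by label
#' before joining so ties resolve deterministically.
#'
#' @param D symmetric distance matrix with zero diagonal and labels
#' @return Newick string (unrooted, with branch lengths)
#' @export
nj_tree <- function(D) {
  if (nrow(D) < 3) stop("need at least 3 taxa")
  if (is.null(rownames(D))) stop("distance matrix must have labels")
  if (max(abs(D - t(D))) > 1e-9 || any(diag(D) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  ord <- order(rownames(D))
  tr <- ape::nj(as.dist(D[ord, ord]))
  ape::write.tree(tr)
}
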
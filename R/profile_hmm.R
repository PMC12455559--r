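# Profile hidden Markov models: construction from alignments, forward and
# Viterbi scoring in bits against a background model, condition tuning, and
# reference normalization.

.seq_to_idx <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  idx <- match(ch, AA_ALPHABET) - 1L
  bad <- is.na(idx) & ch != "X"
  if (any(bad)) stop("residue outside alphabet: ", paste(unique(ch[bad]), collapse = ""))
  idx[is.na(idx)] <- -1L  # X: background emission
  idx
}

#' Build a profile HMM from a multiple sequence alignment
#'
#' Columns whose gap fraction is at most `match_gap_threshold` become match
#' states; other columns feed insert states.  Emissions are residue counts
#' plus a Laplace pseudocount, normalized over the 20-letter alphabet;
#' transitions are counted from each row's implied state path with a
#' pseudocount of 1 on every allowed transition.  Insert emissions are pooled
#' across the model.
#'
#' @param aln named character vector alignment (>= 2 rows)
#' @param match_gap_threshold columns with gap fraction <= this are match
#'   columns (default 0.5)
#' @param pseudocount Laplace emission pseudocount alpha (default 1)
#' @param background residue background distribution (default uniform 1/20)
#' @param mode default scoring mode, `"unilocal"` (uniform entry/exit over
#'   match states, flanking residues free) or `"global"`
#' @return object of class `profile_hmm`
#' @export
build_profile <- function(aln, match_gap_threshold = 0.5, pseudocount = 1,
                          background = .uniform_background(),
                          mode = c("unilocal", "global")) {
  mode <- match.arg(mode)
  if (length(aln) < 2) stop("need at least 2 alignment rows")
  m <- aln_matrix(aln)
  gapfrac <- colMeans(m == "-")
  match_cols <- which(gapfrac <= match_gap_threshold)
  L <- length(match_cols)
  if (L == 0) stop("no match columns at gap threshold ", match_gap_threshold)
  a <- pseudocount

  me <- matrix(a, 20, L, dimnames = list(AA_ALPHABET, NULL))
  for (k in seq_len(L)) {
    tb <- table(factor(m[, match_cols[k]], levels = AA_ALPHABET))
    me[, k] <- me[, k] + as.numeric(tb)
  }
  me <- sweep(me, 2, colSums(me), "/")

  ins_cols <- setdiff(seq_len(ncol(m)), match_cols)
  ie <- rep(a, 20)
  names(ie) <- AA_ALPHABET
  if (length(ins_cols)) {
    tb <- table(factor(m[, ins_cols], levels = AA_ALPHABET))
    ie <- ie + as.numeric(tb)
  }
  ie <- ie / sum(ie)

  # transition counts from implied state paths; node 0 is Begin.
  # allowed: M->{M,I,D}, I->{M,I}, D->{M,D}; at node L targets are End.
  cmm <- cmi <- cmd <- cim <- cii <- cdm <- cdd <- rep(1, L + 1)  # pseudocount
  cmd[L + 1] <- cdd[L + 1] <- 0  # no D_{L+1}
  node_of_col <- integer(ncol(m))  # match node index for match cols
  node_of_col[match_cols] <- seq_len(L)
  is_match <- node_of_col > 0L
  for (r in seq_len(nrow(m))) {
    state <- "M"; node <- 0L
    for (j in seq_len(ncol(m))) {
      ch <- m[r, j]
      if (is_match[j]) {
        k <- node_of_col[j]
        new_state <- if (ch == "-") "D" else "M"
        if (state == "M") {
          if (new_state == "M") cmm[node + 1] <- cmm[node + 1] + 1
          else cmd[node + 1] <- cmd[node + 1] + 1
        } else if (state == "I") {
          # I->D is not in the allowed set; fold it into I->M
          cim[node + 1] <- cim[node + 1] + 1
        } else {
          if (new_state == "M") cdm[node + 1] <- cdm[node + 1] + 1
          else cdd[node + 1] <- cdd[node + 1] + 1
        }
        state <- new_state; node <- k
      } else if (ch != "-") {
        if (state == "M") cmi[node + 1] <- cmi[node + 1] + 1
        else if (state == "I") cii[node + 1] <- cii[node + 1] + 1
        # D->I is not in the allowed set: emit with no transition count
        state <- "I"
      }
    }
    # exit to End from the final state at node L
    if (state == "M") cmm[L + 1] <- cmm[L + 1] + 1
    else if (state == "I") cim[L + 1] <- cim[L + 1] + 1
    else cdm[L + 1] <- cdm[L + 1] + 1
  }
  smm <- cmm + cmi + cmd
  sim <- cim + cii
  sdm <- cdm + cdd
  hmm <- list(
    L = L,
    match_emissions = me,
    insert_emissions = ie,
    background = background,
    mm = cmm / smm, mi = cmi / smm, md = cmd / smm,
    im = cim / sim, ii = cii / sim,
    dm = cdm / sdm, dd = cdd / sdm,
    mode = mode,
    match_cols = match_cols,
    alignment = aln
  )
  class(hmm) <- "profile_hmm"
  hmm
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("Profile HMM:", x$L, "match states,", length(x$alignment),
      "training rows, mode =", x$mode, "\n")
  invisible(x)
}

#' Forward log-odds score of a sequence in bits
#'
#' Computes `log2 P(seq | model) / P(seq | background)` with the forward
#' algorithm in log space.  In `"global"` mode the whole sequence is emitted
#' by the model; in `"unilocal"` mode entry is uniform over match states,
#' exit is free from any match state, and flanking residues are emitted at
#' background (zero log-odds).  'X' emits with background probability.
#'
#' @param hmm a `profile_hmm`
#' @param seq residue string
#' @param mode override the model's scoring mode
#' @return bit score (numeric scalar)
#' @export
forward_bitscore <- function(hmm, seq, mode = hmm$mode) {
  if (!nzchar(seq)) stop("empty sequence")
  .hmm_forward_cpp(hmm, .seq_to_idx(seq), mode)
}

#' Viterbi alignment of a sequence to a profile
#'
#' Most probable state path (ties broken M > D > I), giving each residue's
#' match-column assignment and the matched span.
#'
#' @inheritParams forward_bitscore
#' @return list: `bits` (Viterbi bit score), `colmap` (per-residue match node,
#'   0 for insert/flank), `span` (first and last matched residue, 1-based)
#' @export
align_to_profile <- function(hmm, seq, mode = hmm$mode) {
  if (!nzchar(seq)) stop("empty sequence")
  .hmm_viterbi_cpp(hmm, .seq_to_idx(seq), mode)
}

#' Score many sequences against a profile HMM
#'
#' @param hmm a `profile_hmm`
#' @param seqs named character vector
#' @param mode scoring mode
#' @return named numeric vector of bit scores
#' @export
score_sequences <- function(hmm, seqs, mode = hmm$mode) {
  vapply(seqs, function(s) forward_bitscore(hmm, s, mode), numeric(1))
}

#' Tune a profile HMM with condition-active sequences
#'
#' Rebuilds the profile after augmenting the training set with sequences
#' active at a target condition.  By default the union is re-aligned from
#' scratch with [progressive_align()]; `method = "map"` instead aligns each
#' new sequence to the existing profile (Viterbi) and appends its
#' match-column residues as a new alignment row.
#'
#' @param base_actives named character vector of ungapped training sequences
#' @param new_actives named character vector of condition-active sequences
#'   (disjoint from any evaluation set; the caller must enforce this under
#'   cross-validation)
#' @param method `"realign"` (default) or `"map"`
#' @param ... passed to [build_profile()]
#' @return a `profile_hmm`
#' @export
tune_hmm <- function(base_actives, new_actives = character(0),
                     method = c("realign", "map"), ...) {
  method <- match.arg(method)
  if (!length(new_actives) || method == "realign") {
    aln <- progressive_align(c(base_actives, new_actives))
    return(build_profile(aln, ...))
  }
  base <- build_profile(progressive_align(base_actives), ...)
  aln <- base$alignment
  m <- aln_matrix(aln)
  for (i in seq_along(new_actives)) {
    v <- align_to_profile(base, new_actives[[i]])
    row <- rep("-", ncol(m))
    ch <- strsplit(toupper(new_actives[[i]]), "")[[1]]
    hit <- v$colmap > 0
    row[base$match_cols[v$colmap[hit]]] <- ch[hit]
    aln <- c(aln, setNames(paste(row, collapse = ""), names(new_actives)[i]))
  }
  build_profile(aln, ...)
}

#' Normalize bit scores to a reference sequence
#'
#' Scores are divided by the reference's bit score so that scores from HMMs
#' built on different data splits are comparable (the reference scores
#' exactly 1).
#'
#' @param scores named numeric vector of bit scores
#' @param reference id of the reference sequence (must be present)
#' @return list with `bits`, `normalized`, and `reference`
#' @export
normalize_scores <- function(scores, reference) {
  if (!reference %in% names(scores)) stop("reference '", reference, "' not scored")
  ref <- scores[[reference]]
  if (ref == 0) stop("reference bit score is zero; cannot normalize")
  list(bits = scores, normalized = scores / ref, reference = reference)
}

#' Serialize a profile HMM to JSON
#' @param hmm a `profile_hmm`
#' @param path output path
#' @export
write_profile_json <- function(hmm, path) {
  x <- unclass(hmm)
  x$match_emissions <- as.data.frame(x$match_emissions)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a profile HMM from JSON
#' @param path file written by [write_profile_json()]
#' @export
read_profile_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$match_emissions <- as.matrix(x$match_emissions)
  dimnames(x$match_emissions) <- list(AA_ALPHABET, NULL)
  x$insert_emissions <- setNames(as.numeric(x$insert_emissions), AA_ALPHABET)
  x$background <- setNames(as.numeric(x$background), AA_ALPHABET)
  x$alignment <- unlist(x$alignment)
  class(x) <- "profile_hmm"
  x
}
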
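# Sequence and alignment I/O, pairwise identity and redundancy filtering.
#
# Sequence sets are represented as named character vectors (names = ids,
# values = residue strings).  Alignments are named character vectors of
# equal-length gapped strings with gap character '-'.

.check_ids <- function(ids) {
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  invisible(ids)
}

.check_residues <- function(seqs) {
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX-]*$", seqs)
  if (!all(ok)) stop("invalid residue characters in: ",
                     paste(names(seqs)[!ok], collapse = ", "))
  if (any(!nzchar(gsub("-", "", seqs)))) {
    stop("empty sequence record: ",
         paste(names(seqs)[!nzchar(gsub("-", "", seqs))], collapse = ", "))
  }
  invisible(seqs)
}

#' Read protein sequences from a FASTA file
#'
#' @param path file path (plain or gzipped FASTA)
#' @return named character vector of residue strings; ids are the
#'   whitespace-delimited first token of each header
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  .check_ids(names(seqs))
  .check_residues(seqs)
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line width for wrapping
#' @export
write_fasta <- function(seqs, path, width = 60) {
  .check_ids(names(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read an alignment in Stockholm format
#'
#' Minimal Stockholm 1.0 reader: sequence lines and `//` terminator;
#' annotation lines (`#=..`) are ignored.  Gap characters `.` are converted
#' to `-`.
#' @param path file path
#' @return named character vector of equal-length gapped strings
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[[1]])) {
    stop("not a Stockholm file: ", path)
  }
  rows <- list()
  for (ln in lines[-1]) {
    if (grepl("^\\s*$", ln) || grepl("^#", ln) || grepl("^//", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed Stockholm line: ", ln)
    id <- parts[[1]]
    rows[[id]] <- paste0(if (is.null(rows[[id]])) "" else rows[[id]],
                         chartr(".", "-", toupper(parts[[2]])))
  }
  aln <- unlist(rows)
  if (!length(aln)) stop("no sequences in Stockholm file: ", path)
  if (length(unique(nchar(aln))) != 1) stop("unequal row lengths in ", path)
  .check_residues(aln)
  aln
}

#' Write an alignment in Stockholm format
#'
#' @param aln named character vector of equal-length gapped strings
#' @param path output path
#' @export
write_stockholm <- function(aln, path) {
  .check_ids(names(aln))
  if (length(unique(nchar(aln))) != 1) stop("unequal alignment row lengths")
  wid <- max(nchar(names(aln)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  writeLines(sprintf("%-*s %s", wid, names(aln), unname(aln)), con)
  writeLines("//", con)
  invisible(path)
}

#' Screening-round label from a sequence id
#'
#' Ids are prefixed by the discovery round: `DP` (round 1), `TEP` (round 2),
#' `ESM` (round 3).  Unrecognized prefixes give `NA`.
#' @param ids character vector of sequence ids
#' @return character vector of round labels
#' @export
round_label <- function(ids) {
  lab <- rep(NA_character_, length(ids))
  lab[startsWith(ids, "DP")] <- "DP"
  lab[startsWith(ids, "TEP")] <- "TEP"
  lab[startsWith(ids, "ESM")] <- "ESM"
  lab
}

#' Remove gap characters from sequences
#' @param x character vector of (possibly gapped) sequences
#' @export
degap <- function(x) {
  out <- gsub("-", "", x)
  names(out) <- names(x)
  out
}

#' Global pairwise sequence identity
#'
#' Aligns two sequences globally (affine gaps, BLOSUM62 by default) and
#' returns the fraction of identical aligned positions.  The denominator is
#' the length of the shorter sequence by default (standard for redundancy
#' filtering; insensitive to accessory-domain length differences), or the
#' number of alignment columns.  'X' never counts as identical.
#'
#' @param a,b residue strings (single sequences)
#' @param denominator `"shorter"` (default) or `"alignment"`
#' @param gap_open,gap_extend affine gap penalties (negative)
#' @return identity fraction in \[0, 1\]
#' @export
pairwise_identity <- function(a, b, denominator = c("shorter", "alignment"),
                              gap_open = -11, gap_extend = -1) {
  denominator <- match.arg(denominator)
  a <- toupper(a[[1]]); b <- toupper(b[[1]])
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  ali <- needleman_wunsch(a, b, gap_open = gap_open, gap_extend = gap_extend)
  ca <- strsplit(ali$a, "")[[1]]
  cb <- strsplit(ali$b, "")[[1]]
  ident <- sum(ca == cb & ca != "-" & ca != "X")
  denom <- if (denominator == "shorter") min(nchar(a), nchar(b)) else length(ca)
  ident / denom
}

#' Greedy redundancy filter on pairwise identity
#'
#' Scans `candidates` in input order and drops any sequence whose identity to
#' a reference or to an already-retained candidate is at or above
#' `threshold`.  The retained set is therefore pairwise below the threshold
#' and below it against all references.
#'
#' @param candidates named character vector of sequences
#' @param references named character vector of known sequences (may be empty)
#' @param threshold identity threshold in (0, 1\]
#' @param ... passed to [pairwise_identity()]
#' @return the retained subset of `candidates`
#' @export
greedy_identity_filter <- function(candidates, references = character(0),
                                   threshold, ...) {
  stopifnot(threshold > 0, threshold <= 1)
  kept <- character(0)
  kept_names <- character(0)
  for (i in seq_along(candidates)) {
    s <- candidates[[i]]
    pool <- c(references, kept)
    drop <- FALSE
    for (r in pool) {
      if (pairwise_identity(s, r, ...) >= threshold) { drop <- TRUE; break }
    }
    if (!drop) {
      kept <- c(kept, s)
      kept_names <- c(kept_names, names(candidates)[i])
    }
  }
  setNames(kept, kept_names)
}
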
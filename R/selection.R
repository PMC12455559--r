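# Candidate prioritization rules for screening rounds 2 and 3.

#' Multi-objective candidate selection (round-2 rule)
#'
#' Keeps candidates that are the argmax of any individual score, or at or
#' above the given percentile for all three scores (percentiles computed
#' with linear interpolation over the candidate pool itself), then applies a
#' greedy identity filter against known sequences and retained candidates.
#'
#' @param candidates data.frame with columns `id`, `activity`, `tm`,
#'   `acid_tolerance`, `sequence`
#' @param percentile percentile cutoff applied to all three scores
#'   (default 50)
#' @param identity_threshold drop candidates at or above this identity
#'   (default 0.90)
#' @param known named character vector of known sequences
#' @return the selected subset with an `admitted_by` column; dropped-by-
#'   identity ids in attribute `"dropped_identity"`
#' @export
multiobjective_select <- function(candidates, percentile = 50,
                                  identity_threshold = 0.90,
                                  known = character(0)) {
  stopifnot(nrow(candidates) >= 1,
            all(c("id", "activity", "tm", "acid_tolerance", "sequence")
                %in% names(candidates)))
  sc <- candidates[c("activity", "tm", "acid_tolerance")]
  if (!all(vapply(sc, function(x) all(is.finite(x)), logical(1)))) {
    stop("scores must be finite")
  }
  argmax <- lapply(sc, function(x) candidates$id[which.max(x)])
  cuts <- vapply(sc, quantile, numeric(1), probs = percentile / 100,
                 type = 7, names = FALSE)
  above <- sc$activity >= cuts[[1]] & sc$tm >= cuts[[2]] &
    sc$acid_tolerance >= cuts[[3]]
  admitted_by <- character(nrow(candidates))
  for (nm in names(argmax)) {
    i <- match(argmax[[nm]], candidates$id)
    admitted_by[i] <- paste(c(admitted_by[i][nzchar(admitted_by[i])],
                              paste0("argmax:", nm)), collapse = ",")
  }
  admitted_by[above & !nzchar(admitted_by)] <- "percentile"
  admitted_by[above & admitted_by == "percentile"] <- "percentile"
  keep <- nzchar(admitted_by) | above
  pool <- candidates[keep, , drop = FALSE]
  pool$admitted_by <- ifelse(nzchar(admitted_by[keep]),
                             admitted_by[keep], "percentile")
  retained <- greedy_identity_filter(setNames(pool$sequence, pool$id),
                                     known, identity_threshold)
  out <- pool[pool$id %in% names(retained), , drop = FALSE]
  attr(out, "dropped_identity") <- setdiff(pool$id, names(retained))
  rownames(out) <- NULL
  out
}

#' Threshold-based candidate selection (round-3 rule)
#'
#' Keeps candidates with predicted activity at or above `activity_min` and
#' predicted melting temperature strictly above `tm_min`, then applies the
#' greedy identity filter.
#'
#' @param candidates data.frame as in [multiobjective_select()]
#' @param activity_min minimum predicted activity (default 10, in the
#'   assay's activity unit)
#' @param tm_min melting-temperature cutoff in deg C, strict (default 55)
#' @param identity_threshold identity cutoff (default 0.95)
#' @param known named character vector of known sequences
#' @return the selected subset; dropped ids in attribute
#'   `"dropped_identity"`
#' @export
threshold_select <- function(candidates, activity_min = 10, tm_min = 55,
                             identity_threshold = 0.95,
                             known = character(0)) {
  stopifnot(is.finite(activity_min), is.finite(tm_min))
  keep <- candidates$activity >= activity_min & candidates$tm > tm_min
  pool <- candidates[keep, , drop = FALSE]
  if (!nrow(pool)) {
    attr(pool, "dropped_identity") <- character(0)
    return(pool)
  }
  retained <- greedy_identity_filter(setNames(pool$sequence, pool$id),
                                     known, identity_threshold)
  out <- pool[pool$id %in% names(retained), , drop = FALSE]
  attr(out, "dropped_identity") <- setdiff(pool$id, names(retained))
  rownames(out) <- NULL
  out
}
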
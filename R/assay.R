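# Plate-assay and melt-curve processing: product quantification, activity
# calls, per-enzyme summaries, hit rates, condition contingency tables, and
# melting-temperature extraction.

#' Aromatic product released, from UV absorbance
#'
#' `umol = max(0, A260 - blank) * dilution / (epsilon * path_length) *
#' reaction_volume`, with `epsilon` in 1/(mM cm) and volume in mL, yielding
#' micromoles.
#'
#' @param A260,blank_A260 sample and matched-blank absorbance at 260 nm
#' @param epsilon molar absorptivity, 1/(mM cm)
#' @param path_length optical path, cm
#' @param reaction_volume reaction volume, mL
#' @param dilution dilution factor applied before reading
#' @return micromoles of aromatic product (vectorized)
#' @export
quantify_product <- function(A260, blank_A260, epsilon = 17,
                             path_length = 1, reaction_volume = 0.5,
                             dilution = 10) {
  if (epsilon <= 0 || path_length <= 0 || reaction_volume <= 0) {
    stop("epsilon, path_length and reaction_volume must be positive")
  }
  pmax(0, A260 - blank_A260) * dilution / (epsilon * path_length) *
    reaction_volume
}

#' Per-condition activity call
#'
#' Active means an A260 reading at least `delta` (default 0.05) above the
#' matched blank; the boundary is inclusive.
#'
#' @param A260,blank_A260 absorbances
#' @param delta call threshold above blank
#' @return logical vector
#' @export
call_activity <- function(A260, blank_A260, delta = 0.05) {
  stopifnot(all(is.finite(A260)), all(is.finite(blank_A260)))
  # tolerance keeps the inclusive boundary exact under floating point
  A260 - blank_A260 >= delta - 1e-12
}

#' Specific activity from product amount
#'
#' @param umol micromoles of product
#' @param enzyme_mg enzyme loading in mg (default 0.005, i.e. 5 ug per well)
#' @return micromol product per mg enzyme
#' @export
specific_activity <- function(umol, enzyme_mg = 0.005) {
  if (any(enzyme_mg <= 0)) stop("enzyme_mg must be positive")
  umol / enzyme_mg
}

#' Summarize an assay table into per-enzyme and per-condition results
#'
#' Replicate wells are averaged (mean A260 per enzyme x condition) before
#' the activity call and quantification.  An enzyme is active overall iff it
#' is active in at least one tested condition; its pH optimum is the pH of
#' its maximum specific activity (ties broken toward lower pH).
#'
#' @param assay data.frame with columns `enzyme_id`, `round`, `substrate`,
#'   `pH`, `temperature`, `replicate`, `A260`, `A280`, `blank_A260`
#' @param melt optional data.frame `enzyme_id`, `temperature`,
#'   `fluorescence` for Tm extraction
#' @param yields optional data.frame `enzyme_id`, `yield_ug`, `purified`
#' @param delta activity-call threshold above blank
#' @param epsilon,path_length,reaction_volume,dilution,enzyme_mg passed to
#'   [quantify_product()] and [specific_activity()]
#' @return list of class `enzyme_summary`: `conditions` (one row per enzyme
#'   x condition) and `enzymes` (one row per enzyme)
#' @export
summarize_enzymes <- function(assay, melt = NULL, yields = NULL,
                              delta = 0.05, epsilon = 17, path_length = 1,
                              reaction_volume = 0.5, dilution = 10,
                              enzyme_mg = 0.005) {
  need <- c("enzyme_id", "substrate", "pH", "temperature", "A260",
            "blank_A260")
  if (!all(need %in% names(assay))) {
    stop("assay table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(assay$A260 < 0 | assay$blank_A260 < 0)) {
    stop("absorbances must be nonnegative")
  }
  grp <- assay[c("enzyme_id", "substrate", "pH", "temperature")]
  cond <- aggregate(assay[c("A260", "blank_A260")], grp, mean)
  cond$n_replicates <- aggregate(assay$A260, grp, length)$x
  umol <- quantify_product(cond$A260, cond$blank_A260, epsilon, path_length,
                           reaction_volume, dilution)
  cond$specific_activity <- specific_activity(umol, enzyme_mg)
  cond$active <- call_activity(cond$A260, cond$blank_A260, delta)
  if ("round" %in% names(assay)) {
    cond$round <- assay$round[match(cond$enzyme_id, assay$enzyme_id)]
  } else {
    cond$round <- round_label(cond$enzyme_id)
  }

  ids <- unique(cond$enzyme_id)
  enz <- data.frame(enzyme_id = ids, stringsAsFactors = FALSE)
  enz$round <- cond$round[match(ids, cond$enzyme_id)]
  enz$n_conditions_tested <- as.integer(table(cond$enzyme_id)[ids])
  enz$active <- vapply(ids, function(i)
    any(cond$active[cond$enzyme_id == i]), logical(1))
  enz$ph_optimum <- vapply(ids, function(i) {
    ci <- cond[cond$enzyme_id == i, ]
    best <- max(ci$specific_activity)
    min(ci$pH[ci$specific_activity == best])  # ties toward lower pH
  }, numeric(1))
  enz$max_activity <- vapply(ids, function(i)
    max(cond$specific_activity[cond$enzyme_id == i]), numeric(1))
  if (!is.null(melt)) {
    enz$tm <- vapply(ids, function(i) {
      mi <- melt[melt$enzyme_id == i, ]
      if (!nrow(mi)) return(NA_real_)
      extract_tm(mi$temperature, mi$fluorescence)
    }, numeric(1))
  }
  if (!is.null(yields)) {
    j <- match(ids, yields$enzyme_id)
    enz$yield_ug <- yields$yield_ug[j]
    if ("purified" %in% names(yields)) enz$purified <- yields$purified[j]
  }
  out <- list(conditions = cond, enzymes = enz)
  class(out) <- "enzyme_summary"
  out
}

#' @export
print.enzyme_summary <- function(x, ...) {
  cat("Enzyme summary:", nrow(x$enzymes), "enzymes,",
      nrow(x$conditions), "enzyme x condition results;",
      sum(x$enzymes$active), "active overall\n")
  invisible(x)
}

#' Condition contingency triple
#'
#' Restricts to enzymes tested at both values of the chosen axis (in at
#' least one combination of the remaining axes), classifies each by its
#' activity marginalized over the other axes, and returns the counts
#' (active only at `value1`, active at both, active only at `value2`).
#' Enzymes tested at both but active at neither are part of the co-tested
#' denominator and none of the three cells.
#'
#' @param summary an `enzyme_summary`
#' @param axis one of `"pH"`, `"temperature"`, `"substrate"`
#' @param value1,value2 the two axis values to compare
#' @return named integer vector `(only1, both, only2)` with attribute
#'   `n_cotested`
#' @export
condition_contingency <- function(summary, axis = c("pH", "temperature",
                                                    "substrate"),
                                  value1, value2) {
  axis <- match.arg(axis)
  cond <- summary$conditions
  at <- function(i, v) cond$enzyme_id == i & cond[[axis]] == v
  ids <- unique(cond$enzyme_id)
  tested_both <- vapply(ids, function(i)
    any(at(i, value1)) && any(at(i, value2)), logical(1))
  ids <- ids[tested_both]
  a1 <- vapply(ids, function(i) any(cond$active[at(i, value1)]), logical(1))
  a2 <- vapply(ids, function(i) any(cond$active[at(i, value2)]), logical(1))
  out <- c(only1 = sum(a1 & !a2), both = sum(a1 & a2), only2 = sum(!a1 & a2))
  attr(out, "n_cotested") <- length(ids)
  out
}

#' Hit rate: fraction of tested enzymes with a positive activity call
#'
#' With a `condition` filter, the denominator is the enzymes tested at a
#' matching condition and the numerator those active at a matching
#' condition; without one, each enzyme's own tested set is used ("any
#' condition" mode).
#'
#' @param summary an `enzyme_summary`
#' @param round optional round label (`"DP"`, `"TEP"`, `"ESM"`) to restrict
#'   to
#' @param condition optional named list, e.g.
#'   `list(substrate = "cryPow", pH = 5.5, temperature = 40)`
#' @return fraction active, or `NA` if no enzyme matches
#' @export
hit_rate <- function(summary, round = NULL, condition = NULL) {
  cond <- summary$conditions
  if (!is.null(round)) cond <- cond[cond$round %in% round, ]
  if (!is.null(condition)) {
    for (nm in names(condition)) cond <- cond[cond[[nm]] %in% condition[[nm]], ]
  }
  ids <- unique(cond$enzyme_id)
  if (!length(ids)) return(NA_real_)
  active <- vapply(ids, function(i) any(cond$active[cond$enzyme_id == i]),
                   logical(1))
  mean(active)
}

#' Melting temperature from a DSF melt curve
#'
#' Smooths the fluorescence trace with a centered moving average, takes the
#' temperature derivative, and finds local maxima that stand out from the
#' baseline (at least `prominence` of the tallest peak and well above the
#' median derivative).  The highest-temperature qualifying maximum is
#' returned, matching the convention of reporting the highest unfolding
#' transition.  Flat or featureless curves give `NA` (no-Tm), not an error.
#'
#' @param temperature strictly increasing temperatures, deg C
#' @param fluorescence fluorescence readings
#' @param window moving-average window for the fluorescence trace (odd,
#'   default 11); the derivative is additionally smoothed with a window of
#'   `ceiling(window / 2)`
#' @param prominence qualifying maxima must reach this fraction of the
#'   tallest derivative peak (default 0.25)
#' @return Tm in deg C, or `NA_real_`
#' @export
extract_tm <- function(temperature, fluorescence, window = 11,
                       prominence = 0.25) {
  if (length(temperature) < 10 || diff(range(temperature)) < 10) {
    stop("need >= 10 points spanning >= 10 degrees")
  }
  if (any(diff(temperature) <= 0)) stop("temperatures must be strictly increasing")
  smooth_ma <- function(x, k) {
    if (k < 2) return(x)
    as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  }
  sm <- smooth_ma(fluorescence, window)
  ok <- !is.na(sm)
  tt <- temperature[ok]; ss <- sm[ok]
  if (length(tt) < 5) return(NA_real_)
  d <- diff(ss) / diff(tt)
  tm_grid <- (tt[-1] + tt[-length(tt)]) / 2
  d2 <- smooth_ma(d, max(3, ceiling(window / 2)))
  ok2 <- !is.na(d2)
  d2 <- d2[ok2]; tm_grid <- tm_grid[ok2]
  if (!length(d2) || max(d2) <= 0) return(NA_real_)
  # noise floor: a real transition towers over the typical derivative level
  floor_d <- 5 * median(abs(d2))
  if (max(d2) < floor_d) return(NA_real_)
  locmax <- which(diff(sign(diff(d2))) < 0) + 1
  if (!length(locmax)) locmax <- which.max(d2)
  qual <- locmax[d2[locmax] >= prominence * max(d2) & d2[locmax] >= floor_d]
  if (!length(qual)) return(NA_real_)
  tm_grid[max(qual)]
}
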
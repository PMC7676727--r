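#' Classify participants into behavioral types from posterior intervals
#'
#' Applies the interval rules for behavioral types to each participant's
#' 95% compatibility intervals of the predicted cooperation probability
#' after mutual cooperation, `p(C|CC)_i`, and of its differences from the
#' other three conditional probabilities. "Greater than c" holds only when
#' the interval's lower bound exceeds `c` (a bound exactly at the cutoff
#' counts as not greater):
#' \describe{
#'   \item{Type 4}{`p(C|CC)_i` not resolvably above 0.50 (any difference
#'     pattern).}
#'   \item{Type 1 (TFT-like)}{`p(C|CC)_i > .50`; `p(C|CC)_i - p(C|DC)_i`
#'     not resolvably above 0; both differences versus CD and DD above 0.}
#'   \item{Type 2 (WSLS-like)}{`p(C|CC)_i > .50`; differences versus DC
#'     and CD both above 0 (difference versus DD unconstrained).}
#'   \item{Type 3}{`p(C|CC)_i > .50` with any other difference pattern.}
#' }
#'
#' @param ind An `individual_prob_summary` from an OPA-design fit (its
#'   conditions must include CC, DC, CD, DD).
#' @return A data frame of class `type_assignment`: `participant_id`,
#'   `type` (integer 1-4), `label`, and the interval bounds the decision
#'   used (`pcc_lo`, `pcc_hi`, `d_dc_lo`, `d_dc_hi`, `d_cd_lo`, `d_cd_hi`,
#'   `d_dd_lo`, `d_dd_hi`).
#' @export
classify_types <- function(ind) {
  stopifnot(inherits(ind, "individual_prob_summary"))
  conds <- dimnames(ind$draws)[[3]]
  if (!all(c("CC", "DC", "CD", "DD") %in% conds)) {
    stop("classification needs conditions CC, DC, CD, DD ",
         "(an OPA-design fit)")
  }
  ids <- dimnames(ind$draws)[[2]]
  K <- length(ids)
  out <- data.frame(participant_id = ids, type = NA_integer_,
                    label = NA_character_,
                    pcc_lo = NA_real_, pcc_hi = NA_real_,
                    d_dc_lo = NA_real_, d_dc_hi = NA_real_,
                    d_cd_lo = NA_real_, d_cd_hi = NA_real_,
                    d_dd_lo = NA_real_, d_dd_hi = NA_real_)
  labels <- c("TFT-like", "WSLS-like", "other", "non-cooperative")
  for (k in seq_len(K)) {
    pcc <- ind$draws[, k, "CC"]
    ci <- function(x) quantile(x, c(0.025, 0.975), names = FALSE, type = 1)
    b_cc <- ci(pcc)
    b_dc <- ci(pcc - ind$draws[, k, "DC"])
    b_cd <- ci(pcc - ind$draws[, k, "CD"])
    b_dd <- ci(pcc - ind$draws[, k, "DD"])
    gt <- function(b, c) b[1] > c
    type <- if (!gt(b_cc, 0.5)) {
      4L
    } else if (!gt(b_dc, 0) && gt(b_cd, 0) && gt(b_dd, 0)) {
      1L
    } else if (gt(b_dc, 0) && gt(b_cd, 0)) {
      2L
    } else {
      3L
    }
    out[k, -(1:3)] <- c(b_cc, b_dc, b_cd, b_dd)
    out$type[k] <- type
    out$label[k] <- labels[type]
  }
  class(out) <- c("type_assignment", "data.frame")
  out
}

#' Classify directly from interval bounds
#'
#' The same decision rule as [classify_types()], applied to pre-computed
#' 95% interval bounds. Every interval configuration maps to exactly one
#' type.
#'
#' @param pcc,d_dc,d_cd,d_dd Length-2 numeric vectors `c(lo, hi)`: the
#'   interval of `p(C|CC)_i` and of its differences versus the DC, CD and
#'   DD probabilities.
#' @return Integer type in 1-4.
#' @export
classify_from_intervals <- function(pcc, d_dc, d_cd, d_dd) {
  stopifnot(length(pcc) == 2, length(d_dc) == 2, length(d_cd) == 2,
            length(d_dd) == 2)
  if (!(pcc[1] > 0.5)) return(4L)
  if (!(d_dc[1] > 0) && d_cd[1] > 0 && d_dd[1] > 0) return(1L)
  if (d_dc[1] > 0 && d_cd[1] > 0) return(2L)
  3L
}

#' Cross-tabulate behavioral types by game
#'
#' @param ... Named `type_assignment` data frames, one per game (e.g.
#'   `direct = ..., generalized = ...`).
#' @return A games x 4 integer matrix of counts with class `type_counts`;
#'   proportions in `attr(, "proportions")`.
#' @export
type_counts <- function(...) {
  groups <- list(...)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("type_counts() requires named arguments, one per game")
  }
  m <- t(vapply(groups, function(a) {
    tabulate(a$type, nbins = 4L)
  }, integer(4)))
  colnames(m) <- c("type1_tft", "type2_wsls", "type3_other", "type4_noncoop")
  attr(m, "proportions") <- m / rowSums(m)
  class(m) <- c("type_counts", class(m))
  m
}

#' Exact test of independence between game and behavioral type
#'
#' Fisher's exact test for the games x types contingency table: the exact
#' conditional p-value over all tables with the observed margins, using
#' the probability-ordering criterion (two-sided).
#'
#' @param counts A `type_counts` matrix (or any nonnegative integer
#'   contingency matrix). Empty columns are dropped before testing.
#' @return The exact p-value.
#' @export
exact_type_test <- function(counts) {
  m <- unclass(counts)
  attr(m, "proportions") <- NULL
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(m) == 0)) stop("empty row margin")
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2) return(1)
  fisher.test(m)$p.value
}

#' Write behavioral-type assignments as CSV
#'
#' @param assignments A `type_assignment` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_type_assignments <- function(assignments, path) {
  stopifnot(inherits(assignments, "type_assignment"))
  write.csv(as.data.frame(assignments), path, row.names = FALSE, na = "NA")
  invisible(path)
}
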
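#' Widely applicable information criterion from a log-likelihood matrix
#'
#' Given the S x N matrix of pointwise log-likelihoods (S posterior draws,
#' N observations), computes
#' `lppd = sum_n log( mean_s exp(loglik[s, n]) )` via log-sum-exp,
#' `p_waic = sum_n var_s(loglik[s, n])` (sample variance, 1/(S-1) divisor),
#' `WAIC = -2 (lppd - p_waic)`, and the standard error
#' `SE = sqrt(N * var_n(pointwise))` over the pointwise WAIC contributions
#' `-2 (lppd_n - p_waic_n)`.
#'
#' @param loglik_matrix Numeric matrix, draws in rows, observations in
#'   columns; all entries finite.
#' @return A list of class `waic_fit`: `waic`, `lppd`, `p_waic`, `se`,
#'   `n_obs` and `pointwise` (data frame with per-observation `lppd`,
#'   `p_waic`, `waic`).
#' @export
waic <- function(loglik_matrix) {
  ll <- as.matrix(loglik_matrix)
  if (nrow(ll) < 2) stop("need at least 2 draws")
  if (any(!is.finite(ll))) stop("log-likelihood matrix has non-finite entries")
  S <- nrow(ll)
  # log(mean(exp(x))) per column, stabilized by the column maximum
  mx <- apply(ll, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2, mx))))
  p_i <- apply(ll, 2, var)
  waic_i <- -2 * (lppd_i - p_i)
  N <- ncol(ll)
  structure(
    list(
      waic = sum(waic_i), lppd = sum(lppd_i), p_waic = sum(p_i),
      se = sqrt(N * var(waic_i)), n_obs = N,
      pointwise = data.frame(lppd = lppd_i, p_waic = p_i, waic = waic_i)
    ),
    class = "waic_fit"
  )
}

#' @export
print.waic_fit <- function(x, ...) {
  cat(sprintf("WAIC %.2f (SE %.2f), lppd %.2f, p_WAIC %.2f, N = %d\n",
              x$waic, x$se, x$lppd, x$p_waic, x$n_obs))
  invisible(x)
}

#' Akaike-type weights from WAIC differences
#'
#' `w_k = exp(-0.5 dWAIC_k) / sum_j exp(-0.5 dWAIC_j)`.
#'
#' @param dwaic Vector of WAIC differences from the best model
#'   (non-negative, at least one zero).
#' @return Probability vector summing to 1.
#' @export
waic_weights <- function(dwaic) {
  if (length(dwaic) == 0) stop("empty dWAIC vector")
  if (any(dwaic < 0) || !any(dwaic == 0)) {
    stop("dWAIC values must be >= 0 with at least one 0")
  }
  w <- exp(-0.5 * dwaic)
  w / sum(w)
}

#' Compare fitted models by WAIC
#'
#' Builds the comparison table: per model WAIC, p_WAIC and SE; dWAIC
#' relative to the lowest-WAIC model; dSE, the standard error of the
#' pointwise WAIC difference (`sqrt(N * var_n(pointwise_k - pointwise_best))`,
#' undefined for the best model); and the Akaike-type weight. All models
#' must have been evaluated on the identical observation set in the same
#' order.
#'
#' @param fits Named list of inputs, each either a `coop_fit`, a
#'   `waic_fit`, or a log-likelihood matrix.
#' @return A data frame of class `waic_table`, sorted by WAIC: columns
#'   `model, waic, p_waic, dwaic, se, dse, weight`. Per-model pointwise
#'   contributions are kept in `attr(, "pointwise")`.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  ws <- lapply(fits, function(f) {
    if (inherits(f, "coop_fit")) waic(log_lik_matrix(f))
    else if (inherits(f, "waic_fit")) f
    else waic(f)
  })
  n_obs <- vapply(ws, function(w) w$n_obs, numeric(1))
  if (length(unique(n_obs)) != 1) {
    stop("models were evaluated on different numbers of observations: ",
         paste(n_obs, collapse = ", "))
  }
  N <- n_obs[[1]]
  tab <- data.frame(
    model = names(ws),
    waic = vapply(ws, function(w) w$waic, numeric(1)),
    p_waic = vapply(ws, function(w) w$p_waic, numeric(1)),
    se = vapply(ws, function(w) w$se, numeric(1))
  )
  best <- which.min(tab$waic)
  tab$dwaic <- tab$waic - tab$waic[best]
  best_pw <- ws[[best]]$pointwise$waic
  tab$dse <- vapply(seq_along(ws), function(k) {
    if (k == best) return(NA_real_)
    sqrt(N * var(ws[[k]]$pointwise$waic - best_pw))
  }, numeric(1))
  tab$weight <- waic_weights(tab$dwaic)
  tab <- tab[order(tab$waic), c("model", "waic", "p_waic", "dwaic",
                                "se", "dse", "weight")]
  rownames(tab) <- NULL
  attr(tab, "pointwise") <- lapply(ws, function(w) w$pointwise$waic)
  class(tab) <- c("waic_table", "data.frame")
  tab
}

#' @export
print.waic_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a WAIC comparison table as CSV
#'
#' Values are rounded to `digits` decimals for presentation; the unrounded
#' table is what [compare_models()] returns.
#'
#' @param tab A `waic_table`.
#' @param path Output CSV path.
#' @param digits Decimal places used in the file.
#' @return `path`, invisibly.
#' @export
write_waic_table <- function(tab, path, digits = 2) {
  stopifnot(inherits(tab, "waic_table"))
  y <- as.data.frame(tab)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  write.csv(y, path, row.names = FALSE, na = "NA")
  invisible(path)
}
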
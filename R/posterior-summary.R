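# Conditioning states summarized for each model design, as rows of the
# basis matrix (intercept first). Own action is the first letter, partner
# action the second, for the OPA family.
cond_designs <- function(spec) {
  switch(spec$model_id,
    PA  = rbind(C = c(1, 1), D = c(1, 0)),
    OA  = rbind(C = c(1, 1), D = c(1, 0)),
    "NULL" = rbind(overall = 1),
    rbind(CC = c(1, 1, 1, 1), DC = c(1, 0, 1, 0),
          CD = c(1, 1, 0, 0), DD = c(1, 0, 0, 0))
  )
}

# Gauss-Hermite nodes/weights for the probabilist's weight exp(-z^2/2),
# via the Golub-Welsch eigendecomposition of the Jacobi matrix.
gauss_hermite_norm <- function(n = 21) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(seq_len(n - 1), 2:n)] <- off
  J[cbind(2:n, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}

# Interval endpoints use inverse-ECDF (type 1) quantiles: order statistics
# commute with monotone transforms, so probability intervals are exactly
# the inverse logit of linear-predictor intervals.
summarize_prob_draws <- function(p) {
  qs <- quantile(p, c(0.025, 0.5, 0.975), names = FALSE, type = 1)
  c(median = qs[2], lo = qs[1], hi = qs[3])
}

#' Group-level predicted conditional cooperation probabilities
#'
#' For each retained draw, evaluates the inverse logit of the group-level
#' (hyper-mean) linear predictor at each conditioning state of the model —
#' e.g. for the OPA model, `p(C|CC) = invlogit(mu_b1 + mu_b2 + mu_b3 +
#' mu_b4)` — and summarizes the draws by the median and the equal-tailed
#' 95% compatibility interval.
#'
#' With `marginal = TRUE`, each draw instead gives the cooperation
#' probability of a hypothetical new participant, averaging the inverse
#' logit over the group-level normal distribution of the varying effects
#' (the linear predictor of a new individual is normal with mean `x'mu`
#' and SD `sqrt(sum(x_b^2 sigma_b^2))`; the average is computed by
#' Gauss-Hermite quadrature). The default, non-marginal summary describes
#' the group-level mean itself.
#'
#' @param fit A `coop_fit` of a multilevel or pooling model.
#' @param marginal Average over new-participant variation (multilevel only).
#' @param gh_points Number of quadrature nodes for the marginal variant.
#' @return A `group_prob_summary`: list with `draws` (S x conditions matrix
#'   of probabilities) and `summary` (condition, median, lo, hi).
#' @export
group_probs <- function(fit, marginal = FALSE, gh_points = 21) {
  stopifnot(inherits(fit, "coop_fit"))
  spec <- fit$model$spec
  if (spec$pooling == "nonpool") {
    stop("non-pooling fits have no group-level parameters")
  }
  if (marginal && spec$pooling != "multilevel") {
    stop("marginal summaries require a multilevel fit")
  }
  D <- cond_designs(spec)
  B <- spec$n_coef
  mu <- fit$draws[, seq_len(B), drop = FALSE]
  p <- matrix(NA_real_, nrow(mu), nrow(D), dimnames = list(NULL, rownames(D)))
  if (!marginal) {
    for (j in seq_len(nrow(D))) p[, j] <- inv_logit(drop(mu %*% D[j, ]))
  } else {
    sigma <- fit$draws[, B + seq_len(B), drop = FALSE]
    gh <- gauss_hermite_norm(gh_points)
    for (j in seq_len(nrow(D))) {
      m <- drop(mu %*% D[j, ])
      s <- sqrt(drop(sigma^2 %*% D[j, ]^2))
      acc <- 0
      for (q in seq_along(gh$nodes)) {
        acc <- acc + gh$weights[q] * inv_logit(m + s * gh$nodes[q])
      }
      p[, j] <- acc
    }
  }
  summ <- data.frame(condition = rownames(D),
                     t(apply(p, 2, summarize_prob_draws)))
  rownames(summ) <- NULL
  structure(list(draws = p, summary = summ, model_id = spec$model_id,
                 marginal = marginal),
            class = "group_prob_summary")
}

#' @export
print.group_prob_summary <- function(x, ...) {
  cat(sprintf("Group-level predicted cooperation probabilities (%s model%s):\n",
              x$model_id, if (x$marginal) ", marginal over new participants" else ""))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-participant predicted conditional cooperation probabilities
#'
#' As [group_probs()], but evaluated with each participant's own varying
#' effects `coef_i = mu + z_i sigma` per draw, yielding one probability
#' distribution per participant and condition.
#'
#' @param fit A `coop_fit`.
#' @return An `individual_prob_summary`: list with `draws`
#'   (S x participants x conditions array) and `summary` (participant_id,
#'   condition, median, lo, hi).
#' @export
individual_probs <- function(fit) {
  stopifnot(inherits(fit, "coop_fit"))
  spec <- fit$model$spec
  D <- cond_designs(spec)
  coefs <- participant_coefs(fit)            # S x K x B
  S <- dim(coefs)[1]; K <- dim(coefs)[2]
  p <- array(NA_real_, c(S, K, nrow(D)),
             dimnames = list(NULL, fit$model$participants, rownames(D)))
  for (j in seq_len(nrow(D))) {
    eta <- matrix(0, S, K)
    for (b in seq_len(spec$n_coef)) {
      if (D[j, b] != 0) eta <- eta + D[j, b] * coefs[, , b]
    }
    p[, , j] <- inv_logit(eta)
  }
  summ <- expand.grid(participant_id = fit$model$participants,
                      condition = rownames(D), stringsAsFactors = FALSE)
  qs <- t(vapply(seq_len(nrow(summ)), function(r) {
    k <- match(summ$participant_id[r], fit$model$participants)
    summarize_prob_draws(p[, k, summ$condition[r]])
  }, numeric(3)))
  summ$median <- qs[, 1]; summ$lo <- qs[, 2]; summ$hi <- qs[, 3]
  structure(list(draws = p, summary = summ, model_id = spec$model_id),
            class = "individual_prob_summary")
}

#' Posterior differences between conditional cooperation probabilities
#'
#' For each ordered pair of conditions, subtracts the per-draw predicted
#' probabilities and reports the median, the 95% compatibility interval,
#' and `P(diff > 0)`, the fraction of draws strictly greater than zero
#' (draws exactly at zero count as not greater).
#'
#' @param summary A `group_prob_summary`.
#' @param pairs List of length-2 character vectors `c(a, b)` giving the
#'   ordered differences `a - b`; defaults to all ordered pairs of the
#'   first condition versus the others, then the remaining ordered pairs.
#' @return A `diff_summary`: list with `draws` (S x pairs matrix) and
#'   `summary` (pair, median, lo, hi, p_gt0).
#' @export
prob_diffs <- function(summary, pairs = NULL) {
  stopifnot(inherits(summary, "group_prob_summary"))
  conds <- colnames(summary$draws)
  if (is.null(pairs)) {
    pairs <- list()
    for (a in seq_along(conds)) {
      for (b in seq_along(conds)) {
        if (a < b) pairs[[length(pairs) + 1]] <- c(conds[a], conds[b])
      }
    }
  }
  bad <- vapply(pairs, function(pr) !all(pr %in% conds), logical(1))
  if (any(bad)) {
    stop("unknown condition(s) in pairs: ",
         paste(unlist(pairs[bad]), collapse = ", "))
  }
  lab <- vapply(pairs, function(pr) paste0(pr[1], "-", pr[2]), character(1))
  d <- vapply(pairs, function(pr) {
    summary$draws[, pr[1]] - summary$draws[, pr[2]]
  }, numeric(nrow(summary$draws)))
  colnames(d) <- lab
  summ <- data.frame(
    pair = lab,
    t(apply(d, 2, summarize_prob_draws)),
    p_gt0 = apply(d, 2, function(x) mean(x > 0))
  )
  rownames(summ) <- NULL
  structure(list(draws = d, summary = summ), class = "diff_summary")
}

#' @export
print.diff_summary <- function(x, ...) {
  cat("Posterior differences between cooperation probabilities:\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
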
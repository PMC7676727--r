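#' MCMC sampler settings
#'
#' Defaults follow the analysis protocol: 4 chains of 5,000 iterations with
#' the first 2,000 discarded as warm-up, retaining 12,000 draws in total.
#'
#' @param chains Number of independent chains.
#' @param iter Iterations per chain (including warm-up).
#' @param warmup Warm-up iterations discarded per chain.
#' @param seed Master seed; per-chain seeds are derived from it.
#' @param sim_time Nominal integration time of each Hamiltonian trajectory;
#'   the leapfrog step count is `sim_time` divided by the adapted step size.
#' @param target_accept Dual-averaging acceptance target.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(chains = 4, iter = 5000, warmup = 2000, seed = 1L,
                           sim_time = 1.2, target_accept = 0.8) {
  stopifnot(chains >= 1, iter > warmup, warmup >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 sim_time = sim_time, target_accept = target_accept),
            class = "sampler_config")
}

# One derived seed per chain, kept inside the 32-bit integer range.
chain_seeds <- function(seed, chains) {
  vapply(seq_len(chains), function(ch) {
    as.integer((as.numeric(seed) * 1009 + 7919 * ch) %% 2147483647)
  }, integer(1))
}

pooling_code <- function(spec) {
  switch(spec$pooling, multilevel = 0L, nonpool = 1L, pool = 2L)
}

#' Fit a strategy model by Hamiltonian Monte Carlo
#'
#' Runs `config$chains` independent HMC chains on the model's posterior
#' (non-centered parameterization for multilevel variants; group-level SDs
#' sampled on the log scale), with dual-averaging step-size adaptation and
#' a diagonal mass matrix estimated during warm-up. Retained draws are
#' reported on the constrained scale (`sigma_*` columns are standard
#' deviations). Convergence is summarized by split-chain R-hat; any R-hat
#' above 1.05 triggers a warning and marks the fit, but the draws remain
#' inspectable.
#'
#' @param model A `coop_model` from [build_model()].
#' @param config A `sampler_config`.
#' @return A `coop_fit` with elements `draws` (S_total x P matrix, columns
#'   named), `chain_id`, `model`, `config`, `rhat`, `divergences`,
#'   `step_size` and `convergence_ok`.
#' @export
fit_model <- function(model, config = sampler_config()) {
  stopifnot(inherits(model, "coop_model"), inherits(config, "sampler_config"))
  spec <- model$spec
  seeds <- chain_seeds(config$seed, config$chains)
  chains <- vector("list", config$chains)
  divergences <- integer(config$chains)
  step_size <- numeric(config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(seeds[ch])
    res <- hmc_chain(
      X = model$cell_X, pid = model$cell_pid, miss = model$cell_miss,
      n = model$cell_n, ysum = model$cell_ysum,
      K = length(model$participants), pooling = pooling_code(spec),
      has_v = spec$has_v,
      mu_sd = model$priors$mu_sd, sigma_sd = model$priors$sigma_sd,
      v_sd = model$priors$v_sd, coef_sd = model$priors$coef_sd,
      iter = config$iter, warmup = config$warmup,
      sim_time = config$sim_time, target_accept = config$target_accept
    )
    draws <- res$draws
    if (spec$pooling == "multilevel") {
      B <- spec$n_coef
      draws[, (B + 1):(2 * B)] <- exp(draws[, (B + 1):(2 * B), drop = FALSE])
    }
    colnames(draws) <- model$param_names
    chains[[ch]] <- draws
    divergences[ch] <- res$divergences
    step_size[ch] <- res$step_size
  }
  rh <- rhat(chains)
  all_draws <- do.call(rbind, chains)
  chain_id <- rep(seq_len(config$chains), each = config$iter - config$warmup)
  ok <- all(is.na(rh) | rh < 1.05)
  fit <- structure(
    list(draws = all_draws, chain_id = chain_id, model = model,
         config = config, rhat = rh, divergences = sum(divergences),
         step_size = step_size, convergence_ok = ok),
    class = "coop_fit"
  )
  if (!ok) {
    warning("some parameters have split R-hat >= 1.05 (max ",
            sprintf("%.3f", max(rh, na.rm = TRUE)),
            "); inspect fit$rhat before using this fit")
  }
  fit
}

#' @export
print.coop_fit <- function(x, ...) {
  cat(sprintf(
    "coop_fit: %s model, %d chains x %d retained draws (%d total), %d parameters\n",
    x$model$spec$model_id, x$config$chains, x$config$iter - x$config$warmup,
    nrow(x$draws), ncol(x$draws)
  ))
  cat(sprintf("  max split R-hat %.3f, divergences %d\n",
              max(x$rhat, na.rm = TRUE), x$divergences))
  invisible(x)
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half and the classic potential-scale-reduction
#' statistic `sqrt(((n-1)/n W + B/n) / W)` is computed over the resulting
#' half-chains, per parameter. Values near 1 indicate well-mixed chains.
#' Parameters that are constant across all draws yield `NA` (flagged, not
#' an error).
#'
#' @param draws_by_chain A list with one element per chain: a draws matrix
#'   (iterations x parameters) or a numeric vector for a single parameter.
#' @return Named numeric vector of R-hat values, one per parameter.
#' @export
rhat <- function(draws_by_chain) {
  stopifnot(is.list(draws_by_chain), length(draws_by_chain) >= 2)
  mats <- lapply(draws_by_chain, function(x) {
    if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
  })
  n_iter <- unique(vapply(mats, nrow, integer(1)))
  if (length(n_iter) != 1) stop("all chains must have the same length")
  if (n_iter < 4) stop("need at least 4 draws per chain to split")
  half <- n_iter %/% 2L
  halves <- list()
  for (m in mats) {
    halves <- c(halves, list(m[seq_len(half), , drop = FALSE],
                             m[(n_iter - half + 1):n_iter, , drop = FALSE]))
  }
  P <- ncol(mats[[1]])
  out <- numeric(P)
  for (p in seq_len(P)) {
    ch <- vapply(halves, function(h) mean(h[, p]), numeric(1))
    wv <- vapply(halves, function(h) var(h[, p]), numeric(1))
    W <- mean(wv)
    B <- half * var(ch)
    if (!is.finite(W) || W <= 0) {
      out[p] <- NA_real_
    } else {
      out[p] <- sqrt(((half - 1) / half * W + B / half) / W)
    }
  }
  names(out) <- colnames(mats[[1]])
  out
}

#' Pointwise log-likelihood matrix of a fitted model
#'
#' Evaluates the Bernoulli log-likelihood of every observation under every
#' retained draw, the S x N matrix that WAIC needs pointwise.
#'
#' @param fit A `coop_fit`.
#' @return Matrix with one row per retained draw and one column per
#'   observation, in the fitted table's row order.
#' @export
log_lik_matrix <- function(fit) {
  stopifnot(inherits(fit, "coop_fit"))
  m <- fit$model
  cpp_loglik_matrix(
    draws = fit$draws, X = m$cell_X, pid = m$cell_pid, miss = m$cell_miss,
    obs_cell = m$obs_cell, y = m$y,
    K = length(m$participants), pooling = pooling_code(m$spec),
    has_v = m$spec$has_v
  )
}

#' Per-participant coefficient draws from a fitted model
#'
#' Reconstructs `coef_i = mu + z_i sigma` per draw for multilevel fits, or
#' extracts the independent (non-pooling) or shared (pooling) coefficients.
#'
#' @param fit A `coop_fit`.
#' @return A 3-d array S x K x B (draws, participants, coefficients).
#' @export
participant_coefs <- function(fit) {
  stopifnot(inherits(fit, "coop_fit"))
  spec <- fit$model$spec
  K <- length(fit$model$participants)
  B <- spec$n_coef
  S <- nrow(fit$draws)
  out <- array(NA_real_, c(S, K, B),
               dimnames = list(NULL, fit$model$participants, spec$coef_names))
  for (b in seq_len(B)) {
    if (spec$pooling == "multilevel") {
      mu <- fit$draws[, b]
      sigma <- fit$draws[, B + b]
      z <- fit$draws[, (2 * B + (b - 1) * K + 1):(2 * B + b * K), drop = FALSE]
      out[, , b] <- mu + z * sigma
    } else if (spec$pooling == "nonpool") {
      out[, , b] <- fit$draws[, ((b - 1) * K + 1):(b * K), drop = FALSE]
    } else {
      out[, , b] <- fit$draws[, b]
    }
  }
  out
}
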
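# Shared fixtures: everything is generated in code at test time.

# Population of agents drawn from the OPA generative model:
# beta_i ~ Normal(mu, sigma) coordinate-wise, shared v on the logit scale.
opa_population <- function(K, mu = c(-1, 0.5, 1.5, 1.0), sigma = 0.5,
                           v = 0, seed = 1) {
  set.seed(seed)
  lapply(seq_len(K), function(i) {
    strategy_from_opa(mu + rnorm(length(mu), 0, sigma), v = v)
  })
}

# Reduced sampler settings used throughout the fit-based tests.
quick_sampler <- function(seed, chains = 2, iter = 1500, warmup = 500) {
  sampler_config(chains = chains, iter = iter, warmup = warmup, seed = seed)
}

fit_quick <- function(model_id, tab, seed, ...) {
  suppressWarnings(fit_model(
    build_model(model_spec(model_id), prior_spec(), tab),
    quick_sampler(seed, ...)
  ))
}

# Small hand-specified decision table (one participant).
hand_table <- function(own, displayed, decision) {
  n <- length(decision)
  as_tbl <- data.frame(
    game_kind = "direct", session_id = 1L, chain_id = NA_integer_,
    participant_id = 1L, round_index = seq_len(n) - 1L,
    own_prev = own, partner_prev_displayed = displayed,
    partner_prev_actual = displayed, decision = decision,
    payoff_delta = ifelse(decision == 1, 0, 20)
  )
  class(as_tbl) <- c("decision_table", "data.frame")
  as_tbl
}

# Naive WAIC: literal loops over draws and observations (independent oracle).
waic_naive <- function(ll) {
  S <- nrow(ll); N <- ncol(ll)
  lppd <- 0; p <- 0; pw <- numeric(N)
  for (n in seq_len(N)) {
    m <- 0
    for (s in seq_len(S)) m <- m + exp(ll[s, n])
    lppd_n <- log(m / S)
    mean_ll <- 0
    for (s in seq_len(S)) mean_ll <- mean_ll + ll[s, n]
    mean_ll <- mean_ll / S
    v <- 0
    for (s in seq_len(S)) v <- v + (ll[s, n] - mean_ll)^2
    v <- v / (S - 1)
    lppd <- lppd + lppd_n; p <- p + v
    pw[n] <- -2 * (lppd_n - v)
  }
  list(waic = -2 * (lppd - p), lppd = lppd, p_waic = p, pointwise = pw)
}
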
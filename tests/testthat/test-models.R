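test_that("inverse logit is exact and saturates stably", {
  expect_equal(inv_logit(0), 0.5)
  expect_equal(inv_logit(log(3)), 0.75)
  expect_equal(inv_logit(800), 1)
  expect_equal(inv_logit(-800), 0)
  expect_equal(inv_logit(c(-1, 0, 1)), 1 - inv_logit(c(1, 0, -1)))
})

test_that("linear predictors follow the indicator algebra of each design", {
  tab <- hand_table(own = c(NA, 1, 0, 1, 0), displayed = c(NA, 1, 1, 0, 0),
                    decision = c(1, 1, 0, 1, 0))
  beta <- matrix(c(0.3, -0.7, 1.1, 2.3), nrow = 1)
  eta <- linear_predictor(model_spec("OPA"), list(coef = beta, v = 9), tab)
  expect_equal(eta, c(9, sum(beta), 0.3 + 1.1, 0.3 - 0.7, 0.3))

  alpha <- matrix(c(0.5, -1), nrow = 1)
  eta_pa <- linear_predictor(model_spec("PA"), list(coef = alpha, v = 9), tab)
  expect_equal(eta_pa, c(9, -0.5, -0.5, 0.5, 0.5))

  gam <- matrix(c(0.25, 2), nrow = 1)
  eta_oa <- linear_predictor(model_spec("OA"), list(coef = gam, v = 9), tab)
  expect_equal(eta_oa, c(9, 2.25, 0.25, 2.25, 0.25))

  eta_null <- linear_predictor(model_spec("NULL"), list(coef = matrix(0.4)), tab)
  expect_equal(eta_null, rep(0.4, 5))

  # zero coefficients put the cooperation probability at chance
  expect_equal(inv_logit(linear_predictor(model_spec("PA"),
                                          list(coef = matrix(c(0, 0), 1), v = 0),
                                          tab)),
               rep(0.5, 5))
  expect_error(linear_predictor(model_spec("OPA"), list(coef = beta), tab),
               "params\\$v")
})

test_that("log-likelihood matches a hand Bernoulli computation and keeps order", {
  tab <- hand_table(own = c(NA, 1, 0), displayed = c(NA, 1, 1),
                    decision = c(1, 0, 1))
  params <- list(coef = matrix(c(0, 1, -1, 0.5), nrow = 1), v = 0)
  spec <- model_spec("OPA")
  eta <- c(0, 0 + 1 - 1 + 0.5, 0 - 1)
  p <- inv_logit(eta)
  hand <- c(log(p[1]), log(1 - p[2]), log(p[3]))
  ll <- log_likelihood(spec, params, tab)
  expect_equal(ll, hand)
  expect_length(ll, nrow(tab))
  # the total is permutation invariant; the vector preserves table order
  perm <- c(2, 3, 1)
  tab_perm <- tab[perm, ]
  tab_perm$round_index <- 0:2
  expect_equal(sum(log_likelihood(spec, params, tab_perm)), sum(ll))
  expect_equal(log_likelihood(spec, params, tab_perm), ll[perm])
})

test_that("free-parameter counts match each parameterization", {
  tab <- simulate_direct(game_config("direct", n_participants = 10, seed = 20),
                         build_population(10))
  K <- 10
  expect_equal(build_model(model_spec("NULL"), prior_spec(), tab)$n_free_params,
               K + 2)
  expect_equal(build_model(model_spec("OPA"), prior_spec(), tab)$n_free_params,
               4 * K + 4 + 4 + 1)
  expect_equal(build_model(model_spec("OPA_POOL"), prior_spec(), tab)$n_free_params,
               5)
  expect_equal(build_model(model_spec("OPA_NONPOOL"), prior_spec(), tab)$n_free_params,
               4 * K + 1)
  expect_equal(build_model(model_spec("PA"), prior_spec(), tab)$n_free_params,
               2 * K + 2 + 2 + 1)
})

test_that("OPA nests PA and OA, and collapses to pooling when sigmas vanish", {
  tab <- simulate_direct(game_config("direct", n_participants = 8, seed = 21),
                         build_population(8))
  K <- 8
  set.seed(22)
  a <- matrix(rnorm(2 * K), K, 2)
  v <- 0.7
  # PA's likelihood is OPA's with the own-action columns zeroed
  beta_pa <- cbind(a[, 1], 0, a[, 2], 0)
  expect_equal(
    log_likelihood(model_spec("OPA"), list(coef = beta_pa, v = v), tab),
    log_likelihood(model_spec("PA"), list(coef = a, v = v), tab)
  )
  # OA's likelihood is OPA's with the partner columns zeroed, except on
  # rows where OA conditions (own present) but OPA falls back to v
  beta_oa <- cbind(a[, 1], a[, 2], 0, 0)
  both <- !is.na(tab$own_prev) & !is.na(tab$partner_prev_displayed)
  expect_equal(
    log_likelihood(model_spec("OPA"), list(coef = beta_oa, v = v), tab)[both],
    log_likelihood(model_spec("OA"), list(coef = a, v = v), tab)[both]
  )
  # all participants equal -> multilevel coefficient matrix acts pooled
  shared <- c(0.2, -0.4, 0.9, 0.1)
  coef_ml <- matrix(shared, K, 4, byrow = TRUE)
  expect_equal(
    log_likelihood(model_spec("OPA"), list(coef = coef_ml, v = v), tab),
    log_likelihood(model_spec("OPA_POOL"), list(coef = matrix(shared, 1), v = v), tab)
  )
})

test_that("relabeling participants leaves the joint likelihood unchanged", {
  tab <- simulate_direct(game_config("direct", n_participants = 6, seed = 23),
                         build_population(6))
  set.seed(24)
  coef <- matrix(rnorm(6 * 4), 6, 4)
  spec <- model_spec("OPA")
  base <- sum(log_likelihood(spec, list(coef = coef, v = 0.2), tab))
  perm <- sample(6)
  tab2 <- tab
  tab2$participant_id <- perm[tab$participant_id]
  tab2 <- tab2[order(tab2$participant_id, tab2$round_index), ]
  # rows of coef follow sorted participant ids: new id j was old id
  # match(j, perm), so reorder the rows accordingly
  coef2 <- coef[match(seq_len(6), perm), , drop = FALSE]
  expect_equal(sum(log_likelihood(spec, list(coef = coef2, v = 0.2), tab2)), base)
})

test_that("build_model aggregates observations into faithful binomial cells", {
  tab <- simulate_direct(game_config("direct", n_participants = 10, seed = 25),
                         build_population(10))
  m <- build_model(model_spec("OPA"), prior_spec(), tab)
  expect_equal(sum(m$cell_n), nrow(tab))
  expect_equal(sum(m$cell_ysum), sum(tab$decision))
  # reconstruct each observation's design from its cell
  expect_equal(m$cell_X[m$obs_cell, , drop = FALSE], m$X,
               ignore_attr = TRUE)
  expect_equal(m$cell_miss[m$obs_cell], m$miss)
})
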
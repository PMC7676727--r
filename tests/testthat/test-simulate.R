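test_that("strategy presets satisfy their definitions and validate inputs", {
  tft <- preset_strategy("TFT")
  expect_equal(unlist(tft[c("p_cc", "p_dc", "p_cd", "p_dd")]),
               c(p_cc = 1, p_dc = 1, p_cd = 0, p_dd = 0))
  wsls <- preset_strategy("WSLS")
  expect_equal(unlist(wsls[c("p_cc", "p_dc", "p_cd", "p_dd")]),
               c(p_cc = 1, p_dc = 0, p_cd = 0, p_dd = 1))
  expect_equal(unlist(preset_strategy("ALLC")[2:5], use.names = FALSE),
               rep(1, 4))
  expect_equal(unlist(preset_strategy("ALLD")[2:5], use.names = FALSE),
               rep(0, 4))
  noisy <- preset_strategy("TFT", noise = 0.05)
  expect_equal(noisy$p_cc, 0.95)
  expect_equal(noisy$p_cd, 0.05)
  expect_error(agent_strategy(0.5, 1.2, 0, 0, 0), "\\[0, 1\\]")
  # OPA coefficients and conditional probabilities are two views of the
  # same strategy
  s <- strategy_from_opa(c(-1, 0.5, 1.5, 1), v = 0.3)
  expect_equal(s$p_dd, inv_logit(-1))
  expect_equal(s$p_cc, inv_logit(2))
  expect_equal(s$p_dc, inv_logit(0.5))
  expect_equal(s$p_cd, inv_logit(-0.5))
  expect_equal(s$v_prob, inv_logit(0.3))
})

test_that("both simulators emit exactly 42 decisions per participant by default", {
  pop <- build_population(40)
  direct <- simulate_direct(game_config("direct", seed = 1), pop)
  expect_equal(nrow(direct), 40 * 42)
  expect_true(all(table(direct$participant_id) == 42))
  gen <- simulate_generalized(game_config("generalized", seed = 1), pop)
  expect_equal(nrow(gen), 40 * 42)
  expect_true(all(table(gen$participant_id) == 42))
  # 2 decisions x 7 rotations x 3 chains per participant
  expect_true(all(table(gen$participant_id, gen$chain_id) == 14))
})

test_that("missing conditioning info appears exactly where no prior info exists", {
  pop <- build_population(10)
  direct <- simulate_direct(game_config("direct", n_participants = 10, seed = 2), pop)
  r0 <- direct$round_index == 0
  expect_true(all(is.na(direct$own_prev[r0])))
  expect_true(all(is.na(direct$partner_prev_displayed[r0])))
  expect_true(all(!is.na(direct$own_prev[!r0])))
  expect_true(all(!is.na(direct$partner_prev_displayed[!r0])))

  gen <- simulate_generalized(game_config("generalized", n_participants = 10,
                                          seed = 2), pop)
  # own_prev missing only at each participant's very first decision overall
  expect_true(all(is.na(gen$own_prev[gen$round_index == 0])))
  expect_true(all(!is.na(gen$own_prev[gen$round_index > 0])))
  # partner info missing only for the opening donor of each chain
  miss_p <- gen[is.na(gen$partner_prev_displayed), ]
  expect_equal(nrow(miss_p), length(unique(gen$session_id)) * 3)
  expect_true(all(miss_p$participant_id %in%
                    (5 * (unique(gen$session_id) - 1) + 1)))
})

test_that("with error_prob = 0 the displayed action equals the actual one", {
  pop <- build_population(10)
  for (kind in c("direct", "generalized")) {
    cfg <- game_config(kind, n_participants = 10, error_prob = 0, seed = 3)
    tab <- simulate_game(cfg, pop)
    sel <- !is.na(tab$partner_prev_actual)
    expect_equal(tab$partner_prev_displayed[sel], tab$partner_prev_actual[sel])
  }
})

test_that("two unconditional defectors never cooperate and keep every endowment", {
  cfg <- game_config("direct", n_participants = 2, error_prob = 0, seed = 4)
  tab <- simulate_direct(cfg, list(preset_strategy("ALLD", v_prob = 0),
                                   preset_strategy("ALLD", v_prob = 0)))
  expect_true(all(tab$decision == 0))
  expect_true(all(tab$payoff_delta == cfg$endowment))
  # all 41 informative rounds per agent sit in the DD condition
  ep <- empirical_probs(tab)
  dd <- ep$per_participant[ep$per_participant$condition == "DD", ]
  expect_equal(dd$n, c(41L, 41L))
})

test_that("a ring of unconditional cooperators keeps the gift chain alive", {
  cfg <- game_config("generalized", n_participants = 5, error_prob = 0, seed = 5)
  tab <- simulate_generalized(cfg, replicate(5, preset_strategy("ALLC", v_prob = 1),
                                             simplify = FALSE))
  expect_true(all(tab$decision == 1))
  expect_true(all(tab$partner_prev_displayed[!is.na(tab$partner_prev_displayed)] == 1))
})

test_that("flip_with_error flips at the configured rate", {
  expect_equal(flip_with_error(1, 0), 1)
  expect_equal(flip_with_error(0, 1), 1)
  expect_equal(flip_with_error(c(0, 1, 1), 0), c(0, 1, 1))
  set.seed(6)
  draws <- flip_with_error(rep(1, 10000), 0.25)
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(mean(draws) - 0.75), 3 * se)
  expect_error(flip_with_error(1, 1.5), "\\[0, 1\\]")
  expect_error(flip_with_error(2, 0.5))
})

test_that("displayed-vs-actual disagreement rate matches error_prob on 1e5 displays", {
  cfg <- game_config("direct", n_participants = 2500, error_prob = 0.25, seed = 7)
  tab <- simulate_direct(cfg, build_population(2500))
  sel <- !is.na(tab$partner_prev_actual)
  n_disp <- sum(sel)
  expect_gte(n_disp, 1e5)
  flips <- sum(tab$partner_prev_displayed[sel] != tab$partner_prev_actual[sel])
  # exact binomial test at alpha = 0.001 must not reject H0: rate = 0.25
  expect_gt(binom.test(flips, n_disp, p = 0.25)$p.value, 0.001)
})

test_that("cooperation transfers the doubled endowment and money is conserved", {
  cfg <- game_config("direct", n_participants = 6, seed = 8)
  tab <- simulate_direct(cfg, build_population(6))
  n_coop <- sum(tab$decision == 1)
  # keeper ledger entries plus doubled transfers account for every payout
  expect_equal(total_payout(tab, cfg),
               sum(tab$payoff_delta) + n_coop * cfg$endowment * cfg$multiplier)
  expect_equal(cfg$endowment * cfg$multiplier, 40)
})

test_that("identical seed, config and strategies reproduce the record stream", {
  pop <- build_population(10)
  for (kind in c("direct", "generalized")) {
    cfg <- game_config(kind, n_participants = 10, seed = 9)
    expect_identical(simulate_game(cfg, pop), simulate_game(cfg, pop))
  }
  cfg2 <- game_config("direct", n_participants = 10, seed = 10)
  expect_false(identical(simulate_game(game_config("direct", n_participants = 10,
                                                   seed = 9), pop),
                         simulate_game(cfg2, pop)))
})

test_that("config validation rejects impossible designs", {
  expect_error(game_config("direct", n_participants = 7), "even")
  expect_error(game_config("generalized", n_participants = 12), "divisible")
  expect_error(game_config("direct", error_prob = -0.1), "\\[0, 1\\]")
  cfg <- game_config("direct", n_participants = 4, seed = 1)
  expect_error(simulate_direct(cfg, build_population(6)), "length")
  cfgg <- game_config("generalized", n_participants = 10, seed = 1)
  expect_error(simulate_generalized(cfgg, build_population(5)), "length")
})
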
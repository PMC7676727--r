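#' Configuration of a simulated reciprocity experiment
#'
#' Defaults reproduce the experimental protocols: 40 participants per game,
#' 42 decisions per participant (42 simultaneous rounds with a fixed partner
#' in the direct game; 2 decisions x 7 rotations x 3 chains on five-player
#' rings in the generalized game), a 20-unit endowment doubled on transfer,
#' and a 25% chance that the displayed partner action is the opposite of the
#' actual one.
#'
#' @param game_kind `"direct"` or `"generalized"`.
#' @param n_participants Number of participants (even for the direct game;
#'   a multiple of `ring_size` for the generalized game).
#' @param rounds_direct Rounds per pair in the direct game.
#' @param n_chains Number of independent decision chains (generalized game).
#' @param n_rotations Rotations per chain (generalized game).
#' @param decisions_per_rotation Decisions per player per rotation
#'   (generalized game).
#' @param ring_size Players per ring (generalized game).
#' @param error_prob Probability that a displayed partner action is flipped.
#' @param endowment Currency units received before each decision.
#' @param multiplier Factor applied to a transferred endowment.
#' @param seed RNG seed used by the simulators.
#' @return A `game_config` list.
#' @export
game_config <- function(game_kind = c("direct", "generalized"),
                        n_participants = 40,
                        rounds_direct = 42,
                        n_chains = 3,
                        n_rotations = 7,
                        decisions_per_rotation = 2,
                        ring_size = 5,
                        error_prob = 0.25,
                        endowment = 20,
                        multiplier = 2,
                        seed = 1L) {
  game_kind <- match.arg(game_kind)
  cfg <- list(
    game_kind = game_kind, n_participants = as.integer(n_participants),
    rounds_direct = as.integer(rounds_direct), n_chains = as.integer(n_chains),
    n_rotations = as.integer(n_rotations),
    decisions_per_rotation = as.integer(decisions_per_rotation),
    ring_size = as.integer(ring_size), error_prob = error_prob,
    endowment = endowment, multiplier = multiplier, seed = as.integer(seed)
  )
  if (!is.finite(error_prob) || error_prob < 0 || error_prob > 1) {
    stop("error_prob must lie in [0, 1]")
  }
  if (cfg$n_participants < 2) stop("need at least two participants")
  if (game_kind == "direct" && cfg$n_participants %% 2L != 0L) {
    stop("direct game requires an even number of participants")
  }
  if (game_kind == "generalized" && cfg$n_participants %% cfg$ring_size != 0L) {
    stop("generalized game requires n_participants divisible by ring_size")
  }
  structure(cfg, class = "game_config")
}

#' Flip a displayed action with the perception-error probability
#'
#' Implements the error channel of the experiments: with probability
#' `error_prob` the opposite of the actual decision is displayed.
#' Vectorized over `actual`; consumes one uniform draw per element.
#'
#' @param actual 0/1 vector of actual decisions.
#' @param error_prob Flip probability in \[0, 1\].
#' @return 0/1 vector of displayed decisions.
#' @export
flip_with_error <- function(actual, error_prob) {
  if (!is.finite(error_prob) || error_prob < 0 || error_prob > 1) {
    stop("error_prob must lie in [0, 1]")
  }
  stopifnot(all(actual %in% c(0, 1)))
  flip <- runif(length(actual)) < error_prob
  ifelse(flip, 1 - actual, actual)
}

#' Simulate the direct reciprocity game (iterated prisoner's dilemma)
#'
#' Participants are paired in list order (1-2, 3-4, ...) and pairs stay
#' fixed for `rounds_direct` simultaneous rounds. Before each round after
#' the first, each player is shown the partner's previous decision, flipped
#' independently with probability `error_prob`. Each player then cooperates
#' with the probability their strategy assigns to the (own previous,
#' displayed partner previous) state. A defector keeps the endowment
#' (`payoff_delta = endowment`); a cooperator keeps nothing and the partner
#' receives `endowment * multiplier`.
#'
#' Randomness is consumed round by round: all display flips for the round
#' first (participant order), then all decisions (participant order), so a
#' given seed, config and strategy list reproduce the record stream exactly.
#'
#' @param config A `game_config` with `game_kind = "direct"`.
#' @param strategies List of `agent_strategy`, one per participant.
#' @return A `decision_table` data frame, one row per decision:
#'   `game_kind, session_id, chain_id, participant_id, round_index,
#'   own_prev, partner_prev_displayed, partner_prev_actual, decision,
#'   payoff_delta`. `session_id` is the pair index; `chain_id` is `NA`.
#' @export
simulate_direct <- function(config, strategies) {
  stopifnot(inherits(config, "game_config"))
  if (config$game_kind != "direct") stop("config$game_kind must be 'direct'")
  n <- config$n_participants
  if (n %% 2L != 0L) stop("direct game requires an even number of participants")
  if (length(strategies) != n) {
    stop("length(strategies) must equal n_participants")
  }
  set.seed(config$seed)
  rounds <- config$rounds_direct
  partner <- ifelse(seq_len(n) %% 2L == 1L, seq_len(n) + 1L, seq_len(n) - 1L)
  pair_id <- (seq_len(n) + 1L) %/% 2L

  prev <- rep(NA_real_, n)          # own previous actual decision
  out <- vector("list", rounds)
  for (t in seq_len(rounds) - 1L) {
    if (t == 0L) {
      disp <- rep(NA_real_, n)
      actual <- rep(NA_real_, n)
    } else {
      actual <- prev[partner]
      disp <- flip_with_error(actual, config$error_prob)
    }
    p <- strategy_prob(strategies, prev, disp)
    dec <- as.integer(runif(n) < p)
    out[[t + 1L]] <- data.frame(
      game_kind = "direct", session_id = pair_id, chain_id = NA_integer_,
      participant_id = seq_len(n), round_index = t,
      own_prev = prev, partner_prev_displayed = disp,
      partner_prev_actual = actual, decision = dec,
      payoff_delta = ifelse(dec == 1L, 0, config$endowment)
    )
    prev <- as.numeric(dec)
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$participant_id, tab$round_index), , drop = FALSE]
  rownames(tab) <- NULL
  as_decision_table(tab)
}

#' Simulate the generalized reciprocity game (gift-giving rings)
#'
#' Participants are split in list order into rings of `ring_size` players.
#' Within a chain, players take turns in fixed ring order; player `j` gives
#' (or not) to the next player on the ring and is conditioned on the
#' displayed most recent gift decision of the previous player toward them.
#' One rotation consists of `decisions_per_rotation` consecutive passes
#' around the ring; `n_rotations` rotations form a chain and `n_chains`
#' chains are run per ring (ring membership and order fixed across chains),
#' so each participant makes
#' `decisions_per_rotation * n_rotations * n_chains` decisions (42 with
#' defaults). The opening donor of each chain sees no partner information;
#' a player's own previous action is their immediately preceding actual
#' decision across chains. The display error applies once per display, to
#' the partner's action only.
#'
#' @inheritParams simulate_direct
#' @return A `decision_table`; `session_id` is the ring index and
#'   `chain_id` the chain within the ring.
#' @export
simulate_generalized <- function(config, strategies) {
  stopifnot(inherits(config, "game_config"))
  if (config$game_kind != "generalized") {
    stop("config$game_kind must be 'generalized'")
  }
  n <- config$n_participants
  m <- config$ring_size
  if (n %% m != 0L) stop("n_participants must be a multiple of ring_size")
  if (length(strategies) != n) {
    stop("length(strategies) must equal n_participants")
  }
  set.seed(config$seed)
  passes <- config$decisions_per_rotation * config$n_rotations
  n_rings <- n %/% m
  total <- n * passes * config$n_chains
  col_session <- integer(total); col_chain <- integer(total)
  col_id <- integer(total); col_round <- integer(total)
  col_own <- numeric(total); col_disp <- numeric(total)
  col_actual <- numeric(total); col_dec <- integer(total)
  r <- 0L
  own_prev <- rep(NA_real_, n)      # last actual decision, across chains
  n_done <- integer(n)              # decisions made so far, across chains
  for (ring in seq_len(n_rings)) {
    members <- ((ring - 1L) * m + 1L):(ring * m)
    for (chain in seq_len(config$n_chains)) {
      last_gift <- rep(NA_real_, m)  # actual last decision of each member, this chain
      for (pass in seq_len(passes)) {
        for (pos in seq_len(m)) {
          id <- members[pos]
          upstream <- if (pos == 1L) m else pos - 1L
          actual <- last_gift[upstream]
          disp <- if (is.na(actual)) NA_real_ else {
            flip_with_error(actual, config$error_prob)
          }
          p <- strategy_prob(strategies[id], own_prev[id], disp)
          dec <- as.integer(runif(1) < p)
          r <- r + 1L
          col_session[r] <- ring; col_chain[r] <- chain
          col_id[r] <- id; col_round[r] <- n_done[id]
          col_own[r] <- own_prev[id]; col_disp[r] <- disp
          col_actual[r] <- actual; col_dec[r] <- dec
          last_gift[pos] <- as.numeric(dec)
          own_prev[id] <- as.numeric(dec)
          n_done[id] <- n_done[id] + 1L
        }
      }
    }
  }
  tab <- data.frame(
    game_kind = "generalized", session_id = col_session, chain_id = col_chain,
    participant_id = col_id, round_index = col_round,
    own_prev = col_own, partner_prev_displayed = col_disp,
    partner_prev_actual = col_actual, decision = col_dec,
    payoff_delta = ifelse(col_dec == 1L, 0, config$endowment)
  )
  tab <- tab[order(tab$participant_id, tab$round_index), , drop = FALSE]
  rownames(tab) <- NULL
  as_decision_table(tab)
}

#' Simulate either game from its configuration
#'
#' @inheritParams simulate_direct
#' @return A `decision_table`.
#' @export
simulate_game <- function(config, strategies) {
  switch(config$game_kind,
    direct = simulate_direct(config, strategies),
    generalized = simulate_generalized(config, strategies)
  )
}

#' Total money disbursed in a simulated session
#'
#' A defector keeps the endowment; a cooperator's transfer is doubled for
#' the recipient, so each decision pays out either `endowment` (kept) or
#' `endowment * multiplier` (received by the partner).
#'
#' @param table A `decision_table`.
#' @param config The `game_config` the table was generated under.
#' @return Total currency units paid out over the session.
#' @export
total_payout <- function(table, config) {
  give <- table$decision == 1
  sum(ifelse(give, config$endowment * config$multiplier, config$endowment))
}
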
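#' Define a conditional cooperation strategy for a simulated player
#'
#' An agent strategy is a set of five cooperation probabilities: `v_prob`
#' applies when no information about the partner's (or own) previous action
#' is available, and `p_cc`, `p_dc`, `p_cd`, `p_dd` apply when the pair
#' (own previous action, displayed partner previous action) equals (C,C),
#' (D,C), (C,D), (D,D) respectively, with C = cooperate, D = defect.
#'
#' @param v_prob Probability of cooperating with no partner information.
#' @param p_cc,p_dc,p_cd,p_dd Conditional cooperation probabilities for the
#'   four (own, partner) previous-action states.
#' @return An object of class `agent_strategy`.
#' @examples
#' agent_strategy(0.5, p_cc = 1, p_dc = 1, p_cd = 0, p_dd = 0)  # exact TFT
#' @export
agent_strategy <- function(v_prob = 0.5, p_cc, p_dc, p_cd, p_dd) {
  p <- c(v_prob = v_prob, p_cc = p_cc, p_dc = p_dc, p_cd = p_cd, p_dd = p_dd)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("all strategy probabilities must lie in [0, 1]")
  }
  structure(as.list(p), class = "agent_strategy")
}

#' Named strategy presets
#'
#' Classic deterministic strategies of the iterated prisoner's dilemma:
#' \describe{
#'   \item{TFT}{tit-for-tat: copy the partner's displayed previous action.}
#'   \item{WSLS}{win-stay lose-shift (Pavlov): cooperate after mutual
#'     cooperation or mutual defection, defect otherwise.}
#'   \item{ALLC}{unconditional cooperator.}
#'   \item{ALLD}{unconditional defector.}
#' }
#'
#' @param name One of `"TFT"`, `"WSLS"`, `"ALLC"`, `"ALLD"`.
#' @param v_prob Cooperation probability when no information is shown.
#' @param noise Execution noise: each conditional probability is pulled from
#'   \{0,1\} to \{`noise`, 1 − `noise`\}, giving a near-deterministic agent.
#' @return An `agent_strategy`.
#' @export
preset_strategy <- function(name = c("TFT", "WSLS", "ALLC", "ALLD"),
                            v_prob = 0.5, noise = 0) {
  name <- match.arg(name)
  stopifnot(noise >= 0, noise <= 0.5)
  p <- switch(name,
    TFT  = c(1, 1, 0, 0),
    WSLS = c(1, 0, 0, 1),
    ALLC = c(1, 1, 1, 1),
    ALLD = c(0, 0, 0, 0)
  )
  p <- p * (1 - noise) + (1 - p) * noise
  agent_strategy(v_prob, p_cc = p[1], p_dc = p[2], p_cd = p[3], p_dd = p[4])
}

#' Strategy implied by own-and-partner-action (OPA) model coefficients
#'
#' Converts a participant's logit-scale coefficient vector
#' (intercept, own effect, partner effect, interaction) and the
#' no-information parameter `v` into the equivalent conditional
#' cooperation probabilities, so that simulating agents with this strategy
#' is exactly simulating from the OPA generative model.
#'
#' @param beta Numeric length-4 vector (b1, b2, b3, b4) on the logit scale.
#' @param v No-information cooperative tendency on the logit scale.
#' @return An `agent_strategy`.
#' @export
strategy_from_opa <- function(beta, v = 0) {
  stopifnot(length(beta) == 4, is.finite(beta), is.finite(v))
  agent_strategy(
    v_prob = inv_logit(v),
    p_cc = inv_logit(sum(beta)),
    p_dc = inv_logit(beta[1] + beta[3]),
    p_cd = inv_logit(beta[1] + beta[2]),
    p_dd = inv_logit(beta[1])
  )
}

#' @export
print.agent_strategy <- function(x, ...) {
  cat(sprintf(
    "agent_strategy: v=%.3f  p(C|CC)=%.3f  p(C|DC)=%.3f  p(C|CD)=%.3f  p(C|DD)=%.3f\n",
    x$v_prob, x$p_cc, x$p_dc, x$p_cd, x$p_dd
  ))
  invisible(x)
}

# Cooperation probability for a vector of agents given their conditioning
# state. own/partner are 0/1/NA vectors; NA in either -> v_prob.
strategy_prob <- function(strategies, own, partner) {
  stopifnot(length(own) == length(partner))
  p <- vapply(seq_along(strategies), function(i) {
    s <- strategies[[i]]
    o <- own[i]
    a <- partner[i]
    if (is.na(o) || is.na(a)) return(s$v_prob)
    if (o == 1 && a == 1) s$p_cc
    else if (o == 0 && a == 1) s$p_dc
    else if (o == 1 && a == 0) s$p_cd
    else s$p_dd
  }, numeric(1))
  p
}
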
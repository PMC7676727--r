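#' Numerically stable inverse logit
#'
#' @param x Numeric vector on the logit scale.
#' @return `exp(x) / (1 + exp(x))`, evaluated stably for large `|x|`.
#' @export
inv_logit <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  out[!pos] <- exp(x[!pos]) / (1 + exp(x[!pos]))
  out[is.na(x)] <- NA_real_
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

MODEL_IDS <- c("PA", "OPA", "OA", "NULL", "OPA_NONPOOL", "OPA_POOL")

# Basis terms of the linear predictor for each model, evaluated on
# (own_prev = O, partner_prev_displayed = P). The first term is always the
# intercept. `needs` lists the conditioning fields whose absence routes the
# observation to the shared no-information parameter v.
model_basis <- function(model_id) {
  switch(model_id,
    PA  = list(coef = c("a1", "a2"), needs = "P"),
    OA  = list(coef = c("g1", "g2"), needs = "O"),
    "NULL" = list(coef = "e", needs = character(0)),
    # OPA and its non-multilevel variants share the OPA design
    list(coef = c("b1", "b2", "b3", "b4"), needs = c("O", "P"))
  )
}

#' Specify a conditional-cooperation strategy model
#'
#' Six Bernoulli-logit models of the per-decision cooperation probability:
#' \describe{
#'   \item{PA}{partner's action model: varying intercept and varying slope
#'     on the partner's displayed previous action.}
#'   \item{OPA}{own-and-partner's action model: varying intercept, own
#'     effect, partner effect and own-by-partner interaction.}
#'   \item{OA}{own action model: varying intercept and slope on the
#'     player's own previous action.}
#'   \item{NULL}{varying intercept only.}
#'   \item{OPA_NONPOOL}{the OPA design with independent per-participant
#'     coefficients and no group-level distribution (no pooling).}
#'   \item{OPA_POOL}{the OPA design with one coefficient vector shared by
#'     all participants (complete pooling).}
#' }
#' Whenever the model's conditioning information is missing for a decision
#' (first round of the direct game, the opening donor of a chain), the
#' linear predictor is the single shared no-information parameter `v`
#' (the NULL model conditions on nothing and has no `v`).
#'
#' @param model_id One of `"PA"`, `"OPA"`, `"OA"`, `"NULL"`,
#'   `"OPA_NONPOOL"`, `"OPA_POOL"`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(model_id = c("PA", "OPA", "OA", "NULL",
                                    "OPA_NONPOOL", "OPA_POOL")) {
  model_id <- match.arg(model_id)
  basis <- model_basis(model_id)
  pooling <- switch(model_id,
    OPA_NONPOOL = "nonpool", OPA_POOL = "pool", "multilevel"
  )
  structure(
    list(model_id = model_id, coef_names = basis$coef, needs = basis$needs,
         n_coef = length(basis$coef), pooling = pooling,
         has_v = length(basis$needs) > 0),
    class = "model_spec"
  )
}

#' Priors for the strategy models
#'
#' Normal(0, 10) on each group-level mean and on `v` (the stated prior for
#' the no-information parameter), half-Normal(0, 5) on each group-level
#' standard deviation, and standard-normal offsets in the non-centered
#' parameterization. Non-pooling and pooling coefficients take the
#' group-level-mean prior.
#'
#' @param mu_sd Prior SD of the group-level means (logit scale).
#' @param sigma_sd Scale of the half-normal prior on group-level SDs.
#' @param v_sd Prior SD of the no-information parameter `v`.
#' @param coef_sd Prior SD of per-participant (non-pooling) or shared
#'   (pooling) coefficients.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(mu_sd = 10, sigma_sd = 5, v_sd = 10, coef_sd = 10) {
  stopifnot(mu_sd > 0, sigma_sd > 0, v_sd > 0, coef_sd > 0)
  structure(list(mu_sd = mu_sd, sigma_sd = sigma_sd, v_sd = v_sd,
                 coef_sd = coef_sd), class = "prior_spec")
}

# Design matrix rows over the basis (1, [O], [P], [O*P]) for a model,
# plus the missing-information indicator.
model_design <- function(spec, table) {
  O <- table$own_prev
  P <- table$partner_prev_displayed
  miss <- rep(FALSE, nrow(table))
  if ("O" %in% spec$needs) miss <- miss | is.na(O)
  if ("P" %in% spec$needs) miss <- miss | is.na(P)
  O0 <- ifelse(is.na(O), 0, O)
  P0 <- ifelse(is.na(P), 0, P)
  X <- switch(spec$model_id,
    PA  = cbind(1, P0),
    OA  = cbind(1, O0),
    "NULL" = cbind(rep(1, nrow(table))),
    cbind(1, O0, P0, O0 * P0)
  )
  colnames(X) <- spec$coef_names
  list(X = X, miss = miss)
}

#' Evaluate the linear predictor of a model on a decision table
#'
#' For each row, the logit-scale predictor implied by the model design:
#' e.g. for OPA, `b1_i + b2_i O + b3_i P + b4_i O P` where `O` is the
#' participant's own previous action and `P` the displayed partner action.
#' Rows whose conditioning information is missing receive the shared
#' no-information value `v`.
#'
#' @param spec A `model_spec`.
#' @param params List with `coef` (a K x n_coef matrix of per-participant
#'   coefficients, rows indexed by participant in sorted id order; for
#'   `OPA_POOL` a single row is recycled) and `v` (scalar; required when
#'   the model conditions on previous actions).
#' @param table A `decision_table`.
#' @return Numeric vector of logit values, one per row of `table`.
#' @export
linear_predictor <- function(spec, params, table) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(params$coef)) stop("params$coef is required")
  coef <- params$coef
  if (is.null(dim(coef))) coef <- matrix(coef, nrow = 1)
  if (ncol(coef) != spec$n_coef) {
    stop("params$coef must have ", spec$n_coef, " columns for model ",
         spec$model_id)
  }
  ids <- sort(unique(table$participant_id))
  if (nrow(coef) == 1) {
    k <- rep(1L, nrow(table))
  } else {
    if (nrow(coef) != length(ids)) {
      stop("params$coef must have one row per participant")
    }
    k <- match(table$participant_id, ids)
  }
  d <- model_design(spec, table)
  eta <- rowSums(d$X * coef[k, , drop = FALSE])
  if (any(d$miss)) {
    if (is.null(params$v)) stop("params$v required: table has rows with ",
                                "missing conditioning information")
    eta[d$miss] <- params$v
  }
  eta
}

#' Pointwise Bernoulli log-likelihood for fixed parameter values
#'
#' @inheritParams linear_predictor
#' @param clip Probabilities are clipped to `[clip, 1 - clip]` before
#'   taking logs.
#' @return Numeric vector: `y log p + (1 - y) log(1 - p)` per row, in
#'   table order.
#' @export
log_likelihood <- function(spec, params, table, clip = 1e-12) {
  p <- inv_logit(linear_predictor(spec, params, table))
  p <- pmin(pmax(p, clip), 1 - clip)
  y <- table$decision
  y * log(p) + (1 - y) * log1p(-p)
}

#' Assemble a fittable model from a spec, priors and data
#'
#' Binds the model design to a decision table: builds the basis matrix,
#' participant index and missing-information indicator, and records the
#' parameterization. Multilevel models use the non-centered form
#' `coef_i = mu + z_i sigma` with `z_i ~ Normal(0, 1)`; the non-pooling
#' variant gives every participant independent coefficients with the
#' group-mean prior and no shared distribution; the pooling variant has a
#' single shared coefficient vector.
#'
#' @param spec A `model_spec`.
#' @param priors A `prior_spec`.
#' @param table A `decision_table`.
#' @return A `coop_model` object with elements `spec`, `priors`, `table`,
#'   `X`, `pid`, `miss`, `y`, `participants`, `n_free_params` and
#'   `param_names`.
#' @export
build_model <- function(spec, priors = prior_spec(), table) {
  stopifnot(inherits(spec, "model_spec"), inherits(priors, "prior_spec"))
  validate_decision_table(table)
  ids <- sort(unique(table$participant_id))
  K <- length(ids)
  B <- spec$n_coef
  d <- model_design(spec, table)
  param_names <- switch(spec$pooling,
    multilevel = c(
      paste0("mu_", spec$coef_names),
      paste0("sigma_", spec$coef_names),
      as.vector(t(outer(spec$coef_names, ids,
                        function(b, k) paste0("z_", b, "[", k, "]")))),
      if (spec$has_v) "v"
    ),
    nonpool = c(
      as.vector(t(outer(spec$coef_names, ids,
                        function(b, k) paste0(b, "[", k, "]")))),
      if (spec$has_v) "v"
    ),
    pool = c(spec$coef_names, if (spec$has_v) "v")
  )
  pid <- match(table$participant_id, ids)
  y <- as.integer(table$decision)
  # Aggregate observations into binomial cells: the likelihood depends on
  # an observation only through (participant, basis row, missing flag).
  key <- paste(ifelse(d$miss, 0L, pid), d$miss,
               apply(d$X, 1, paste, collapse = ","))
  cell_of <- match(key, unique(key))
  first <- !duplicated(key)
  structure(
    list(spec = spec, priors = priors, table = table,
         X = d$X, pid = pid, miss = d$miss, y = y,
         cell_X = d$X[first, , drop = FALSE], cell_pid = pid[first],
         cell_miss = d$miss[first],
         cell_n = as.numeric(tabulate(cell_of, nbins = sum(first))),
         cell_ysum = as.numeric(rowsum(as.numeric(y), cell_of)[, 1]),
         obs_cell = cell_of,
         participants = ids, n_free_params = length(param_names),
         param_names = param_names),
    class = "coop_model"
  )
}

#' @export
print.coop_model <- function(x, ...) {
  cat(sprintf(
    "coop_model: %s (%s), %d participants, %d observations, %d free parameters\n",
    x$spec$model_id, x$spec$pooling, length(x$participants), nrow(x$table),
    x$n_free_params
  ))
  invisible(x)
}
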
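DECISION_COLS <- c(
  "game_kind", "session_id", "chain_id", "participant_id", "round_index",
  "own_prev", "partner_prev_displayed", "partner_prev_actual", "decision",
  "payoff_delta"
)

as_decision_table <- function(df) {
  class(df) <- c("decision_table", "data.frame")
  df
}

validate_decision_table <- function(df) {
  missing_cols <- setdiff(DECISION_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("decision table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!(df$decision %in% c(0, 1)))
  if (length(bad) > 0) {
    stop("non-binary decision in row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  for (col in c("own_prev", "partner_prev_displayed", "partner_prev_actual")) {
    bad <- which(!(is.na(df[[col]]) | df[[col]] %in% c(0, 1)))
    if (length(bad) > 0) {
      stop("column ", col, " must be 0, 1 or NA; bad row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  for (id in unique(df$participant_id)) {
    ri <- df$round_index[df$participant_id == id]
    if (any(diff(ri) <= 0)) {
      stop("round_index not strictly increasing for participant ", id)
    }
  }
  invisible(df)
}

#' Read a decision table from CSV
#'
#' Expects the schema written by [write_decisions()]: one row per decision
#' with columns `game_kind, session_id, chain_id, participant_id,
#' round_index, own_prev, partner_prev_displayed, partner_prev_actual,
#' decision, payoff_delta`, with `NA` marking missing previous-action
#' information. Schema violations are rejected with row-level messages.
#'
#' @param path Path to a CSV file.
#' @return A `decision_table` data frame.
#' @export
read_decisions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  missing_cols <- setdiff(DECISION_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("decision table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df$game_kind <- as.character(df$game_kind)
  for (col in c("session_id", "chain_id", "participant_id", "round_index",
                "decision")) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("own_prev", "partner_prev_displayed", "partner_prev_actual",
                "payoff_delta")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  validate_decision_table(df)
  df <- df[order(df$participant_id, df$round_index), DECISION_COLS,
           drop = FALSE]
  rownames(df) <- NULL
  as_decision_table(df)
}

#' Write a decision table to CSV
#'
#' @param table A `decision_table`.
#' @param path Output CSV path; missing values written as `"NA"`.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(table, path) {
  validate_decision_table(table)
  write.csv(table, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Empirical conditional cooperation probabilities
#'
#' For each participant, the fraction of cooperative decisions conditional
#' on the partner's displayed previous action (conditions `C`, `D`) and on
#' the combination of the participant's own and the partner's displayed
#' previous actions (conditions `CC`, `DC`, `CD`, `DD`; own action first).
#' Rows whose conditioning fields are missing are excluded from the
#' relevant conditional. Group summaries are unweighted means of the
#' per-participant fractions over participants with a defined fraction,
#' with 95% normal-approximation confidence intervals
#' (mean +/- 1.96 standard errors across participants).
#'
#' @param table A `decision_table`.
#' @return A list of class `cond_freq` with components
#'   `per_participant` (participant_id, condition, n, n_coop, frac; `frac`
#'   is `NA` when the condition was never observed) and
#'   `group` (condition, n_participants, mean, ci_lo, ci_hi).
#' @export
empirical_probs <- function(table) {
  validate_decision_table(table)
  if (nrow(table) == 0) stop("empty decision table")
  ids <- sort(unique(table$participant_id))
  conds <- c("C", "D", "CC", "DC", "CD", "DD")

  cond_rows <- function(df, cond) {
    P <- df$partner_prev_displayed
    O <- df$own_prev
    switch(cond,
      C  = !is.na(P) & P == 1,
      D  = !is.na(P) & P == 0,
      CC = !is.na(P) & !is.na(O) & O == 1 & P == 1,
      DC = !is.na(P) & !is.na(O) & O == 0 & P == 1,
      CD = !is.na(P) & !is.na(O) & O == 1 & P == 0,
      DD = !is.na(P) & !is.na(O) & O == 0 & P == 0
    )
  }

  per <- expand.grid(participant_id = ids, condition = conds,
                     stringsAsFactors = FALSE)
  per$n <- 0L
  per$n_coop <- 0L
  for (j in seq_len(nrow(per))) {
    df <- table[table$participant_id == per$participant_id[j], ]
    sel <- cond_rows(df, per$condition[j])
    per$n[j] <- sum(sel)
    per$n_coop[j] <- sum(df$decision[sel] == 1)
  }
  per$frac <- ifelse(per$n > 0, per$n_coop / per$n, NA_real_)

  group <- do.call(rbind, lapply(conds, function(cond) {
    f <- per$frac[per$condition == cond]
    f <- f[!is.na(f)]
    k <- length(f)
    m <- if (k > 0) mean(f) else NA_real_
    se <- if (k > 1) stats::sd(f) / sqrt(k) else NA_real_
    data.frame(condition = cond, n_participants = k, mean = m,
               ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se)
  }))
  structure(list(per_participant = per, group = group), class = "cond_freq")
}

#' @export
print.cond_freq <- function(x, ...) {
  cat("Empirical conditional cooperation probabilities (group means):\n")
  print(x$group, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write the group-level empirical summary as CSV
#'
#' @param freqs A `cond_freq` object from [empirical_probs()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cond_freq <- function(freqs, path) {
  stopifnot(inherits(freqs, "cond_freq"))
  write.csv(freqs$group, path, row.names = FALSE, na = "NA")
  invisible(path)
}
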
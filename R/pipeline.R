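#' Build a population of agents from a mixture specification
#'
#' @param n Number of agents.
#' @param mix Data frame (or list of lists) with columns/fields `preset`,
#'   `weight`, and optionally `noise` and `v_prob`; agents are allocated
#'   proportionally to `weight` in order. The default mixture is an equal
#'   split of near-deterministic TFT, WSLS, ALLC and ALLD agents
#'   (execution noise 0.05).
#' @return A list of `agent_strategy` of length `n`.
#' @export
build_population <- function(n, mix = NULL) {
  if (is.null(mix)) {
    mix <- data.frame(preset = c("TFT", "WSLS", "ALLC", "ALLD"),
                      weight = 1, noise = 0.05, v_prob = 0.5)
  }
  if (!is.data.frame(mix)) {
    mix <- do.call(rbind, lapply(mix, function(x) {
      data.frame(preset = x$preset,
                 weight = if (is.null(x$weight)) 1 else x$weight,
                 noise = if (is.null(x$noise)) 0.05 else x$noise,
                 v_prob = if (is.null(x$v_prob)) 0.5 else x$v_prob)
    }))
  }
  counts <- floor(n * mix$weight / sum(mix$weight))
  i <- 1L
  while (sum(counts) < n) {   # distribute the remainder in order
    counts[i] <- counts[i] + 1L
    i <- i %% nrow(mix) + 1L
  }
  strategies <- list()
  for (r in seq_len(nrow(mix))) {
    strategies <- c(strategies, replicate(
      counts[r],
      preset_strategy(mix$preset[r], v_prob = mix$v_prob[r],
                      noise = mix$noise[r]),
      simplify = FALSE
    ))
  }
  strategies
}

#' Read and validate a pipeline run configuration
#'
#' The YAML file mirrors the argument structure of the package functions:
#' a `game` block ([game_config()] fields), an optional `strategies` list
#' (mixture rows for [build_population()]), a `models` list of model ids,
#' `priors` and `sampler` blocks, and `output_dir`.
#'
#' @param path Path to a YAML file, or a list with the same structure.
#' @return A validated `run_config` list.
#' @export
run_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(raw$game)) stop("config is missing required block: game")
  game <- do.call(game_config, raw$game)
  models <- unlist(raw$models %||% list("PA", "OPA", "OA", "NULL"))
  bad <- setdiff(models, MODEL_IDS)
  if (length(bad) > 0) stop("unknown model id(s): ", paste(bad, collapse = ", "))
  priors <- do.call(prior_spec, raw$priors %||% list())
  sampler <- do.call(sampler_config, raw$sampler %||% list())
  structure(
    list(game = game, strategies = raw$strategies, models = models,
         priors = priors, sampler = sampler,
         output_dir = raw$output_dir %||% "coopstrat-out"),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

out_path <- function(cfg, file) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(cfg$output_dir, file)
}

log_stage <- function(stage, ...) {
  message(sprintf("[coopstrat] %s %s", stage,
                  paste(sprintf("%s=%s", names(list(...)), list(...)),
                        collapse = " ")))
}

write_provenance <- function(cfg) {
  prov <- list(
    package = "coopstrat",
    version = as.character(utils::packageVersion("coopstrat")),
    r_version = R.version.string,
    seed = cfg$game$seed,
    sampler_seed = cfg$sampler$seed,
    game = unclass(cfg$game),
    models = cfg$models,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  yaml::write_yaml(prov, out_path(cfg, "provenance.yaml"))
}

#' Simulate a decision table from a run configuration
#'
#' @param cfg A `run_config`.
#' @return The simulated `decision_table`, after writing it to
#'   `output_dir/decisions.csv`.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  strategies <- build_population(cfg$game$n_participants, cfg$strategies)
  tab <- simulate_game(cfg$game, strategies)
  path <- out_path(cfg, "decisions.csv")
  write_decisions(tab, path)
  log_stage("simulate", game = cfg$game$game_kind, seed = cfg$game$seed,
            rows = nrow(tab), file = path)
  tab
}

#' Fit the configured models to a decision table
#'
#' @param table A `decision_table`.
#' @param cfg A `run_config`.
#' @return Named list of `coop_fit` objects; convergence diagnostics are
#'   written to `output_dir/diagnostics.csv`.
#' @export
run_fit <- function(table, cfg) {
  stopifnot(inherits(cfg, "run_config"))
  fits <- list()
  diag_rows <- list()
  for (mid in cfg$models) {
    model <- build_model(model_spec(mid), cfg$priors, table)
    fit <- fit_model(model, cfg$sampler)
    fits[[mid]] <- fit
    diag_rows[[mid]] <- data.frame(
      model = mid, max_rhat = max(fit$rhat, na.rm = TRUE),
      divergences = fit$divergences,
      converged = fit$convergence_ok
    )
    log_stage("fit", model = mid, seed = cfg$sampler$seed,
              draws = nrow(fit$draws),
              max_rhat = sprintf("%.3f", max(fit$rhat, na.rm = TRUE)))
  }
  write.csv(do.call(rbind, diag_rows), out_path(cfg, "diagnostics.csv"),
            row.names = FALSE)
  fits
}

#' Compare fitted models and write the WAIC table
#'
#' @param fits Named list of `coop_fit` objects.
#' @param cfg A `run_config`.
#' @return The `waic_table`, after writing `output_dir/waic.csv`.
#' @export
run_compare <- function(fits, cfg) {
  tab <- compare_models(fits)
  write_waic_table(tab, out_path(cfg, "waic.csv"))
  log_stage("compare", best = tab$model[1],
            waic = sprintf("%.2f", tab$waic[1]))
  tab
}

#' Summarize group-level probabilities and their differences
#'
#' @param fit A `coop_fit` (typically the OPA or PA fit).
#' @param cfg A `run_config`.
#' @return List with `group` ([group_probs()]) and `diffs`
#'   ([prob_diffs()]); writes `group_probs_<model>.csv` and
#'   `prob_diffs_<model>.csv`.
#' @export
run_summarize <- function(fit, cfg) {
  gp <- group_probs(fit)
  dp <- prob_diffs(gp)
  mid <- fit$model$spec$model_id
  write.csv(gp$summary, out_path(cfg, paste0("group_probs_", mid, ".csv")),
            row.names = FALSE)
  write.csv(dp$summary, out_path(cfg, paste0("prob_diffs_", mid, ".csv")),
            row.names = FALSE)
  log_stage("summarize", model = mid, conditions = nrow(gp$summary))
  list(group = gp, diffs = dp)
}

#' Classify participants from an OPA-design fit
#'
#' @param fit A `coop_fit` with the OPA design.
#' @param cfg A `run_config`.
#' @return The `type_assignment` data frame; writes
#'   `output_dir/type_assignments.csv`.
#' @export
run_classify <- function(fit, cfg) {
  assignments <- classify_types(individual_probs(fit))
  write_type_assignments(assignments, out_path(cfg, "type_assignments.csv"))
  log_stage("classify", n = nrow(assignments),
            types = paste(tabulate(assignments$type, 4), collapse = "/"))
  assignments
}

#' Run the full simulate-fit-compare-summarize-classify pipeline
#'
#' Composes [run_simulate()], [run_fit()], [run_compare()],
#' [run_summarize()] and [run_classify()]; every output file is
#' regenerable from the configuration and seeds alone, and a provenance
#' record (package version, seeds, config) is written alongside them.
#'
#' @param cfg A `run_config`, or a path to a YAML configuration.
#' @return List with `table`, `fits`, `waic`, `summary`, `assignments`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  write_provenance(cfg)
  table <- run_simulate(cfg)
  fits <- run_fit(table, cfg)
  waic_tab <- if (length(fits) > 1) run_compare(fits, cfg) else NULL
  opa_like <- intersect(c("OPA", "OPA_NONPOOL", "OPA_POOL"), names(fits))
  summary <- assignments <- NULL
  if (length(opa_like) > 0) {
    fit <- fits[[opa_like[1]]]
    if (fit$model$spec$pooling != "nonpool") {
      summary <- run_summarize(fit, cfg)
    }
    assignments <- run_classify(fit, cfg)
  }
  list(table = table, fits = fits, waic = waic_tab, summary = summary,
       assignments = assignments)
}
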
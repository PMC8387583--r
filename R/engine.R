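# Iterated-learning chains: seed -> fit -> regenerate -> ... with early
# stopping when the token-weighted mean reduction crosses a threshold, and
# replicate ensembles with deterministic per-chain substreams.

OUTCOME_LEVELS <- c("sputtered", "completed", "stable")

#' Chain configuration
#'
#' @param seed_params A [seed_params()] object (the generative constants).
#' @param learner A [learner_spec()].
#' @param max_generations Generation horizon (the studies use 20, 100, or
#'   300).
#' @param upper_stop Stop (change "runs to completion") when the
#'   token-weighted mean reduction reaches this value (default 0.99).
#' @param lower_stop Stop (change "sputters out") at or below this value
#'   (default 0.01).
#' @param master_seed Integer master seed; every chain and generation draws
#'   from a substream keyed on it (see [substream_seed()]).
#' @param n_quad Quadrature order for the learner fits.
#' @param keep_states Which generation states to retain in results:
#'   `"all"`, `"tail"` (a rolling window of the last `tail_window`
#'   generations), `"last"`, or `"none"`.
#' @param tail_window Window size for `keep_states = "tail"` (default 10,
#'   matching the default tail of [stable_state_signature()]).
#' @param keep_fits Retain the full per-generation `learner_fit` objects
#'   (conditional modes included)? Scalar fit summaries are always kept.
#' @return A `chain_config` object.
#' @export
chain_config <- function(seed_params, learner = learner_spec(),
                         max_generations = 20, upper_stop = 0.99,
                         lower_stop = 0.01, master_seed = 1L,
                         n_quad = 15,
                         keep_states = c("all", "tail", "last", "none"),
                         tail_window = 10, keep_fits = TRUE) {
  keep_states <- match.arg(keep_states)
  stopifnot(inherits(seed_params, "seed_params"),
            inherits(learner, "learner_spec"),
            max_generations >= 1)
  if (!(lower_stop > 0 && lower_stop < upper_stop && upper_stop < 1)) {
    abort("need 0 < lower_stop < upper_stop < 1", class = "lexdrift_error")
  }
  structure(list(seed_params = seed_params, learner = learner,
                 max_generations = as.integer(max_generations),
                 upper_stop = upper_stop, lower_stop = lower_stop,
                 master_seed = as.integer(master_seed),
                 n_quad = n_quad, keep_states = keep_states,
                 tail_window = as.integer(tail_window),
                 keep_fits = isTRUE(keep_fits)),
            class = "chain_config")
}

#' Token-weighted mean reduction of a generation
#'
#' Total reduced tokens over total tokens; the quantity monitored by the
#' stopping rules.
#'
#' @param state A `generation_state`.
#' @return A probability in `[0, 1]`.
#' @examples
#' token_weighted_mean(seed_generation(headless_eth_lexicon(),
#'                     seed_params(-1, 0, 0), seed = 1))
#' @export
token_weighted_mean <- function(state) {
  sum(state$n_red) / sum(state$freq)
}

classify_outcome <- function(final_mean, cfg) {
  if (final_mean >= cfg$upper_stop) "completed"
  else if (final_mean <= cfg$lower_stop) "sputtered"
  else "stable"
}

#' Run one iterated-learning chain
#'
#' Generation 1 is seeded from the generative model; every later generation
#' fits the learner to the previous generation's counts and regenerates the
#' corpus from the fitted model plus the original automatization pressure.
#' The stop check is applied to every generated state, including the seed:
#' iteration ends as soon as the token-weighted mean reduction reaches
#' `upper_stop` (completion) or `lower_stop` (sputtering out); a chain that
#' reaches the horizon without crossing is classified as stable (polarized)
#' variation.
#'
#' @param lex A `lexicon`.
#' @param cfg A [chain_config()].
#' @param chain_index Index of this chain within an ensemble (keys the
#'   random substreams; default 1).
#' @return A `chain_result`: `trajectory` (tibble of `generation`,
#'   `mean_p`), `fit_trajectory` (per-generation scalar fit summaries),
#'   `states` (list, per `keep_states`), `fits` (list or `NULL`),
#'   `outcome`, `generations_run`, `final_state`.
#' @examples
#' cfg <- chain_config(seed_params(-3, 0.02, 0.4), max_generations = 5,
#'                     master_seed = 7)
#' run_chain(headless_eth_lexicon(), cfg)$outcome
#' @export
run_chain <- function(lex, cfg, chain_index = 1L) {
  stopifnot(inherits(cfg, "chain_config"))
  params <- cfg$seed_params
  spec <- cfg$learner

  states <- list()
  fits <- list()
  fit_rows <- vector("list", cfg$max_generations)
  mean_p <- numeric(0)
  state <- NULL

  keep_state <- function(g, st) {
    switch(cfg$keep_states,
           all = { states[[as.character(g)]] <<- st },
           tail = {
             states[[as.character(g)]] <<- st
             if (length(states) > cfg$tail_window) {
               states[[1]] <<- NULL
             }
           },
           last = { states <<- list(); states[[as.character(g)]] <<- st },
           none = NULL)
  }

  for (g in seq_len(cfg$max_generations)) {
    sub <- substream_seed(cfg$master_seed, chain_index, g)
    if (g == 1) {
      state <- withCallingHandlers(
        seed_generation(lex, params, seed = sub),
        error = function(e) {
          abort(sprintf("chain %d, generation %d: %s", chain_index, g,
                        conditionMessage(e)), class = "lexdrift_error")
        })
    } else {
      set.seed(sub)
      fit <- tryCatch(
        fit_learner(state, spec, params, n_quad = cfg$n_quad),
        error = function(e) {
          abort(sprintf("chain %d, generation %d: %s", chain_index, g,
                        conditionMessage(e)), class = "lexdrift_error")
        })
      fit_rows[[g]] <- glance(fit)
      if (cfg$keep_fits) fits[[as.character(g)]] <- fit
      state <- regenerate(lex, fit, params)
    }
    keep_state(g, state)
    mean_p[g] <- token_weighted_mean(state)
    if (mean_p[g] >= cfg$upper_stop || mean_p[g] <= cfg$lower_stop) break
  }

  generations_run <- length(mean_p)
  fit_trajectory <- dplyr::bind_rows(fit_rows[seq_len(generations_run)],
                                     .id = NULL)
  if (nrow(fit_trajectory) > 0) {
    fit_trajectory <- dplyr::mutate(
      fit_trajectory,
      generation = seq.int(2, generations_run), .before = 1)
  }
  structure(list(
    trajectory = tibble::tibble(generation = seq_len(generations_run),
                                mean_p = mean_p),
    fit_trajectory = fit_trajectory,
    states = states,
    fits = if (cfg$keep_fits) fits else NULL,
    outcome = classify_outcome(mean_p[generations_run], cfg),
    generations_run = generations_run,
    final_state = state,
    chain_index = as.integer(chain_index),
    config = cfg),
    class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("<chain_result: %s after %d generations, final mean %.4f>\n",
              x$outcome, x$generations_run,
              x$trajectory$mean_p[x$generations_run]))
  invisible(x)
}

#' @describeIn run_chain Trajectory as a tibble (`generation`, `mean_p`).
#' @param x A `chain_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.chain_result <- function(x, ...) x$trajectory

#' @describeIn run_chain One-row chain summary.
#' @exportS3Method generics::glance
glance.chain_result <- function(x, ...) {
  tibble::tibble(outcome = x$outcome,
                 generations_run = x$generations_run,
                 final_mean = x$trajectory$mean_p[x$generations_run])
}

#' Run an ensemble of replicate chains
#'
#' Runs `n_chains` independent chains whose substreams are derived
#' deterministically from the master seed and the chain index, so each
#' chain's result is independent of execution order and of how many chains
#' are run.
#'
#' @param lex A `lexicon`.
#' @param cfg A [chain_config()].
#' @param n_chains Number of replicate chains (the studies use 100).
#' @param .progress Print a progress line per chain?
#' @return An `ensemble_result`: `summary` (one row per chain),
#'   `outcome_counts` (named count over sputtered/completed/stable),
#'   `chains` (list of `chain_result`).
#' @export
run_ensemble <- function(lex, cfg, n_chains, .progress = FALSE) {
  stopifnot(n_chains >= 1)
  chains <- purrr::map(seq_len(n_chains), function(i) {
    res <- run_chain(lex, cfg, chain_index = i)
    if (.progress) {
      message(sprintf("chain %d/%d: %s after %d generations (mean %.3f)",
                      i, n_chains, res$outcome, res$generations_run,
                      res$trajectory$mean_p[res$generations_run]))
    }
    res
  })
  summary <- dplyr::bind_rows(purrr::map(chains, glance))
  summary <- dplyr::mutate(summary, chain = dplyr::row_number(),
                           .before = 1)
  counts <- table(factor(summary$outcome, levels = OUTCOME_LEVELS))
  structure(list(summary = summary,
                 outcome_counts = setNames(as.integer(counts),
                                           names(counts)),
                 chains = chains,
                 n_chains = as.integer(n_chains),
                 config = cfg),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result: %d chains; sputtered %d, completed %d, stable %d>\n",
              x$n_chains, x$outcome_counts[["sputtered"]],
              x$outcome_counts[["completed"]],
              x$outcome_counts[["stable"]]))
  invisible(x)
}

#' @describeIn run_ensemble Per-chain summaries as a tibble.
#' @param x An `ensemble_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ensemble_result <- function(x, ...) x$summary

#' @describeIn run_ensemble One-row ensemble summary with outcome counts.
#' @exportS3Method generics::glance
glance.ensemble_result <- function(x, ...) {
  tibble::tibble(n_chains = x$n_chains,
                 sputtered = x$outcome_counts[["sputtered"]],
                 completed = x$outcome_counts[["completed"]],
                 stable = x$outcome_counts[["stable"]])
}

#' Categorical words in the stable tail of a chain
#'
#' For a chain that reached the horizon in stable polarized variation,
#' returns the words that were categorically innovative (empirical
#' reduction probability exactly 1) in every one of the last `tail`
#' generations, and the categorically conservative words (probability
#' exactly 0 throughout the tail). In the headless /dh/ studies the modal
#' stable signature is the top-2 or top-3 most frequent words adopting the
#' innovative variant.
#'
#' @param result A `chain_result` with `outcome == "stable"` and at least
#'   `tail` stored trailing states.
#' @param tail Number of trailing generations to require (default 10).
#' @return A list with character vectors `innovative` and `conservative`.
#' @export
stable_state_signature <- function(result, tail = 10) {
  if (result$outcome != "stable") {
    abort("stable_state_signature requires a stable chain",
          class = "lexdrift_error")
  }
  gens <- as.integer(names(result$states))
  want <- seq(result$generations_run - tail + 1, result$generations_run)
  if (tail > result$generations_run || !all(want %in% gens)) {
    abort(paste0("need the last ", tail, " generation states stored ",
                 "(run with keep_states = 'tail' or 'all')"),
          class = "lexdrift_error")
  }
  tail_states <- result$states[as.character(want)]
  p <- vapply(tail_states, function(s) s$p_hat, numeric(nrow(tail_states[[1]])))
  words <- tail_states[[1]]$word
  list(innovative = words[rowSums(p == 1) == tail],
       conservative = words[rowSums(p == 0) == tail])
}
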
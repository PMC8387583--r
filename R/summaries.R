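# Diagnostics: frequency-effect curves, U-shape detection, variance
# explained by (log) frequency, reduction-probability distribution tables,
# random-effect radicalization traces, and exact outcome comparison.

rank_bins <- function(state, n_bins) {
  ord <- order(state$freq, state$word)
  rank <- integer(nrow(state))
  rank[ord] <- seq_len(nrow(state))
  bin <- as.integer(cut(rank, breaks = round(seq(0, nrow(state),
                                                 length.out = n_bins + 1)),
                        include.lowest = TRUE))
  list(rank = rank, bin = bin)
}

#' Frequency-effect curve of a generation
#'
#' Ranks words by frequency (ties broken by word id), splits them into
#' near-equal rank bins, and summarizes the empirical reduction
#' probabilities per bin. The monotone rising curve of a freshly seeded
#' generation bends into a U once the reduced variant dominates and
#' medium-frequency conservative words persist.
#'
#' @param state A `generation_state`.
#' @param n_bins Number of rank bins (`>= 2`).
#' @return A `frequency_effect_curve` tibble: `bin`, `n_types`,
#'   `freq_min`, `freq_max`, `q1`, `median`, `q3`.
#' @export
frequency_effect_curve <- function(state, n_bins = 10) {
  stopifnot(n_bins >= 2)
  rb <- rank_bins(state, n_bins)
  out <- tibble::tibble(bin = rb$bin, freq = state$freq,
                        p_hat = state$p_hat) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_types = dplyr::n(),
                     freq_min = min(.data$freq),
                     freq_max = max(.data$freq),
                     q1 = quantile(.data$p_hat, 0.25, names = FALSE),
                     median = median(.data$p_hat),
                     q3 = quantile(.data$p_hat, 0.75, names = FALSE),
                     .groups = "drop")
  class(out) <- unique(c("frequency_effect_curve", class(out)))
  out
}

#' U-shape index of the frequency effect
#'
#' Splits words into frequency-rank terciles and reports the tercile
#' medians of the empirical reduction probability. The frequency effect is
#' called U-shaped when the middle tercile's median is below both the
#' low-frequency and high-frequency medians by more than the margin
#' `delta`.
#'
#' @param state A `generation_state` with at least 3 words.
#' @param delta Margin below both outer medians required to call a U
#'   (default 0.01).
#' @return A one-row tibble: `low_med`, `mid_med`, `high_med`, `is_u`.
#' @export
ushape_index <- function(state, delta = 0.01) {
  stopifnot(nrow(state) >= 3)
  rb <- rank_bins(state, 3)
  med <- vapply(1:3, function(b) median(state$p_hat[rb$bin == b]),
                numeric(1))
  tibble::tibble(low_med = med[1], mid_med = med[2], high_med = med[3],
                 is_u = med[2] < med[1] - delta & med[2] < med[3] - delta)
}

#' Variance in reduction probability explained by frequency
#'
#' Squared Pearson correlation between the (raw or log) frequency and the
#' per-word empirical reduction proportion, unweighted across word types.
#' A constant response is defined to explain 0 variance. In data generated
#' with a raw-frequency drive over a Zipfian lexicon, log frequency
#' explains more of this variance than raw frequency (ceiling compression),
#' and the value decays toward 0 as the change advances.
#'
#' @param state A `generation_state` with at least 3 words.
#' @param transform `"raw"` or `"log"` predictor.
#' @param response Optional response vector (one value per word), e.g.
#'   the latent seeded probabilities
#'   `inv_logit(linear_predictor(freq, u, params))`. Defaults to the
#'   empirical proportions `state$p_hat`. Empirical proportions carry
#'   binomial noise that is severe for rare words (a hapax's proportion
#'   is always 0 or 1), which depresses the attainable R-squared relative
#'   to the latent probabilities.
#' @return R-squared in `[0, 1]`.
#' @export
variance_explained <- function(state, transform = c("raw", "log"),
                               response = NULL) {
  transform <- match.arg(transform)
  stopifnot(nrow(state) >= 3)
  if (is.null(response)) response <- state$p_hat
  stopifnot(length(response) == nrow(state))
  x <- freq_predictor(state$freq, transform)
  if (stats::sd(x) == 0) {
    abort("frequency predictor is constant", class = "lexdrift_error")
  }
  if (stats::sd(response) == 0) return(0)
  cor(x, response)^2
}

#' Default reduction-probability bins
#'
#' Singleton bins at exactly 0 ("never reduced") and exactly 1 ("always
#' reduced"), with uniform interior bins `(0, 0.05], (0.05, 0.15], ...,
#' (0.85, 0.95], (0.95, 1)`.
#'
#' @return A tibble of bin `label`, `lower`, `upper` (open/closed encoded
#'   by the singleton rows).
#' @export
default_probability_bins <- function() {
  edges <- c(0.05, seq(0.15, 0.95, by = 0.1))
  tibble::tibble(
    label = c("0", paste0("(0,0.05]"),
              sprintf("(%.2f,%.2f]", edges[-length(edges)], edges[-1]),
              "(0.95,1)", "1"),
    lower = c(0, 0, edges[-length(edges)], 0.95, 1),
    upper = c(0, edges[1], edges[-1], 1, 1))
}

bin_p_hat <- function(p, bins) {
  lab <- character(length(p))
  lab[p == 0] <- "0"
  lab[p == 1] <- "1"
  interior <- p > 0 & p < 1
  if (any(interior)) {
    inner <- bins[bins$lower < bins$upper, ]
    idx <- findInterval(p[interior], inner$lower, left.open = FALSE)
    # intervals are (lower, upper]: boundary values belong to the lower bin
    at_edge <- p[interior] == inner$lower[pmax(idx, 1)]
    idx[at_edge] <- idx[at_edge] - 1
    idx <- pmin(pmax(idx, 1), nrow(inner))
    lab[interior] <- inner$label[idx]
  }
  factor(lab, levels = bins$label)
}

#' Distribution of reduction probabilities across word types
#'
#' Counts word types per empirical-probability bin, per chain, and reports
#' the mean count across chains — the polarized-variation table: in a
#' lexicalized change the mass piles up at exactly 0 and exactly 1.
#'
#' @param states A single `generation_state` or a list of them (one per
#'   chain, sharing a lexicon).
#' @param bins A bin table as from [default_probability_bins()].
#' @return A `distribution_table` tibble: `bin`, `mean_count` (and
#'   `total_count`, `n_chains`).
#' @export
probability_distribution <- function(states,
                                     bins = default_probability_bins()) {
  if (is.data.frame(states)) states <- list(states)
  stopifnot(length(states) >= 1)
  counts <- purrr::map(states, function(s) {
    as.integer(table(bin_p_hat(s$p_hat, bins)))
  })
  tot <- Reduce(`+`, counts)
  out <- tibble::tibble(bin = bins$label, mean_count = tot / length(states),
                        total_count = tot,
                        n_chains = length(states))
  class(out) <- unique(c("distribution_table", class(out)))
  out
}

#' Trace of the inferred word effects across generations
#'
#' Summarizes the per-generation distribution of conditional modes (and of
#' modes in units of the fitted sigma), and flags "radicalized" words:
#' words whose mode sits below `-2 sigma_hat` for at least `k` consecutive
#' generations. Radicalization of exceptionally conservative words is the
#' mechanism that stabilizes polarized variation.
#'
#' @param result A `chain_result` run with `keep_fits = TRUE`.
#' @param k Consecutive-generation run length required to flag a word
#'   (default 3).
#' @return A list with `summary` (per-generation tibble: `generation`,
#'   `sigma_hat`, `u_min`, `u_q1`, `u_med`, `u_q3`, `u_max`, `z_min`),
#'   `u_paths` (long tibble `generation`, `word`, `u_hat`), and
#'   `radicalized` (character vector of flagged words).
#' @export
random_effect_trace <- function(result, k = 3) {
  if (is.null(result$fits) || length(result$fits) == 0) {
    abort("chain was run without keep_fits = TRUE",
          class = "lexdrift_error")
  }
  gens <- as.integer(names(result$fits))
  rows <- purrr::map2(result$fits, gens, function(f, g) {
    u <- unname(f$u_hat)
    tibble::tibble(generation = g, sigma_hat = f$sigma_hat,
                   u_min = min(u),
                   u_q1 = quantile(u, 0.25, names = FALSE),
                   u_med = median(u),
                   u_q3 = quantile(u, 0.75, names = FALSE),
                   u_max = max(u),
                   z_min = if (f$sigma_hat > 0) min(u) / f$sigma_hat else 0)
  })
  u_paths <- purrr::map2(result$fits, gens, function(f, g) {
    tibble::tibble(generation = g, word = names(f$u_hat),
                   u_hat = unname(f$u_hat))
  }) |> dplyr::bind_rows()

  below <- purrr::map(result$fits, function(f) {
    if (f$sigma_hat > 0) names(f$u_hat)[f$u_hat < -2 * f$sigma_hat]
    else character(0)
  })
  words <- names(result$fits[[1]]$u_hat)
  runlen <- setNames(integer(length(words)), words)
  flagged <- character(0)
  for (b in below) {
    runlen[words %in% b] <- runlen[words %in% b] + 1L
    runlen[!(words %in% b)] <- 0L
    flagged <- union(flagged, names(runlen)[runlen >= k])
  }
  list(summary = dplyr::bind_rows(rows), u_paths = u_paths,
       radicalized = flagged)
}

#' Exact comparison of two outcome distributions
#'
#' Two-sided Fisher exact test on the 2 x 3 table of chain outcomes
#' (sputtered / completed / stable) from two ensembles.
#'
#' @param a,b Named or ordered integer vectors of outcome counts over the
#'   same three labels, or `ensemble_result` objects.
#' @return The two-sided exact p-value.
#' @examples
#' outcome_comparison(c(65, 33, 2), c(0, 2, 98))
#' @export
outcome_comparison <- function(a, b) {
  to_counts <- function(x) {
    if (inherits(x, "ensemble_result")) x <- x$outcome_counts
    if (!is.null(names(x))) x <- x[OUTCOME_LEVELS[OUTCOME_LEVELS %in% names(x)]]
    as.integer(x)
  }
  a <- to_counts(a); b <- to_counts(b)
  if (length(a) != 3 || length(b) != 3) {
    abort("outcome counts must have 3 categories", class = "lexdrift_error")
  }
  if (sum(a) == 0 || sum(b) == 0) {
    abort("outcome counts sum to zero", class = "lexdrift_error")
  }
  stats::fisher.test(cbind(a, b))$p.value
}
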
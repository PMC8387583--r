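# The generative side of the model: automatization pressure proportional to
# (possibly log-transformed) token frequency, a per-word effect on the
# log-odds scale, and binomial sampling of reduced-token counts.

#' Inverse-logit link
#'
#' `inv_logit(eta) = 1 / (1 + exp(-eta))`, with `eta` clipped to +/- 30
#' before exponentiation (beyond which the probability is indistinguishable
#' from 0 or 1 in double precision).
#'
#' @param eta Log-odds.
#' @return Probabilities in (0, 1).
#' @examples
#' inv_logit(-1) # about 0.27
#' @export
inv_logit <- function(eta) {
  stats::plogis(clip(eta))
}

#' Generative-model seed parameters
#'
#' The free parameters of the production model: the log-odds of reduction
#' for a word is `b0 + b_freq * T(freq) + u_w`, where `T` is the identity
#' (`transform = "raw"`) or the natural log (`transform = "log"`; a hapax
#' then has predictor 0), and `u_w` is the word's effect. At seeding,
#' `u_w ~ Normal(0, b_w)`; in later generations the learner's inferred
#' conditional modes take its place.
#'
#' @param b0 Baseline log-odds of reduction (e.g. -1 is roughly 27%
#'   reduction for a vanishingly rare word, -3 roughly 5%).
#' @param b_freq Automatization increment per (transformed) token of
#'   practice, on the log-odds scale.
#' @param b_w Standard deviation of the word effect (log-odds), `>= 0`.
#' @param transform `"raw"` or `"log"` frequency drive.
#' @return A `seed_params` object.
#' @examples
#' seed_params(b0 = -1, b_freq = 0.02, b_w = 0.4)
#' @export
seed_params <- function(b0, b_freq, b_w, transform = c("raw", "log")) {
  transform <- match.arg(transform)
  stopifnot(is.numeric(b0), is.numeric(b_freq), is.numeric(b_w))
  if (b_w < 0) abort("b_w must be >= 0", class = "lexdrift_error")
  structure(list(b0 = b0, b_freq = b_freq, b_w = b_w,
                 transform = transform),
            class = "seed_params")
}

#' @export
print.seed_params <- function(x, ...) {
  cat(sprintf("<seed_params: b0 = %g, b_freq = %g, b_w = %g, %s frequency>\n",
              x$b0, x$b_freq, x$b_w, x$transform))
  invisible(x)
}

freq_predictor <- function(freq, transform) {
  switch(transform, raw = as.numeric(freq), log = log(as.numeric(freq)),
         abort(paste0("unknown transform: ", transform),
               class = "lexdrift_error"))
}

#' Linear predictor of the generative model
#'
#' @param freq Token frequency (`>= 1`).
#' @param u Word effect on the log-odds scale.
#' @param params A [seed_params()] object.
#' @return Log-odds `b0 + b_freq * T(freq) + u`.
#' @examples
#' linear_predictor(1, 0, seed_params(-1, 0.02, 0.4))
#' @export
linear_predictor <- function(freq, u, params) {
  params$b0 + params$b_freq * freq_predictor(freq, params$transform) + u
}

new_generation_state <- function(word, freq, u, n_red) {
  stopifnot(all(n_red >= 0), all(n_red <= freq))
  st <- tibble::tibble(word = word, freq = as.integer(freq),
                       u = as.numeric(u), n_red = as.integer(n_red),
                       p_hat = as.numeric(n_red) / as.numeric(freq))
  class(st) <- unique(c("generation_state", class(st)))
  st
}

#' Seed the first generation of a chain
#'
#' Draws each word's effect `u_w ~ Normal(0, b_w)` and its reduced-token
#' count `n_red_w ~ Binomial(freq_w, inv_logit(b0 + b_freq * T(freq_w) +
#' u_w))`.
#'
#' @param lex A `lexicon`.
#' @param params A [seed_params()] object.
#' @param seed Optional integer seed set before sampling.
#' @return A `generation_state` tibble with columns `word`, `freq`, `u`,
#'   `n_red`, `p_hat`.
#' @examples
#' seed_generation(headless_eth_lexicon(), seed_params(-3, 0.02, 0.4),
#'                 seed = 1)
#' @export
seed_generation <- function(lex, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- rnorm(nrow(lex), 0, params$b_w)
  p <- inv_logit(linear_predictor(lex$freq, u, params))
  n_red <- rbinom(nrow(lex), lex$freq, p)
  new_generation_state(lex$word, lex$freq, u, n_red)
}

#' Regenerate the corpus from a learner's estimates
#'
#' Produces the next generation's counts from the previous generation's
#' fitted model plus the ever-present automatization pressure. The learner's
#' conditional modes replace the seeded Normal word effects; an estimated
#' intercept replaces `b0` (or 0 if the learner does not estimate one); and
#' if the learner estimates a frequency effect, that estimate is added to
#' the original `b_freq` (reduction can come either from inferred
#' appropriateness or from articulatory practice). The original `b_freq`
#' drive always applies on the generative transform's scale.
#'
#' @param lex A `lexicon`.
#' @param fit A [fit_learner()] result covering every word of `lex`.
#' @param params The chain's [seed_params()] (supplies the original
#'   `b_freq` and transform).
#' @param seed Optional integer seed.
#' @return A `generation_state`.
#' @export
regenerate <- function(lex, fit, params, seed = NULL) {
  u_hat <- fit$u_hat[lex$word]
  if (anyNA(u_hat)) {
    missing <- lex$word[is.na(u_hat)][1]
    abort(paste0("fit has no conditional mode for word ", missing),
          class = "lexdrift_error")
  }
  eta <- fit$b0_hat +
    params$b_freq * freq_predictor(lex$freq, params$transform) +
    fit$b_freq_hat * freq_predictor(lex$freq, fit$transform) +
    as.numeric(u_hat)
  if (!is.null(seed)) set.seed(seed)
  n_red <- rbinom(nrow(lex), lex$freq, inv_logit(eta))
  new_generation_state(lex$word, lex$freq, as.numeric(u_hat), n_red)
}

#' Write a generation state to TSV
#'
#' @param state A `generation_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_generation_state <- function(state, path) {
  readr::write_tsv(as.data.frame(state), path)
  invisible(path)
}
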
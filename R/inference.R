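# The learner: maximum-likelihood fitting of a binomial model with a
# by-word random intercept. With a single grouping factor the marginal
# likelihood factorizes into one 1-D integral per word, each evaluated by
# adaptive Gauss-Hermite quadrature centred at the word's conditional mode
# (Laplace approximation when n_quad = 1). The outer optimization is over
# the estimated fixed effects and log sigma.

#' Specify which parameters the learner estimates
#'
#' The three learner variants studied are: intercept + word effect
#' (`estimate_intercept = TRUE`, `estimate_freq_effect = FALSE`), word
#' effect only (`FALSE`, `FALSE`), and intercept + word effect + frequency
#' effect (`TRUE`, `TRUE`). A learner that does not estimate the intercept
#' has it constrained to 0.
#'
#' @param estimate_intercept Estimate the fixed intercept?
#' @param estimate_freq_effect Estimate a fixed frequency effect?
#' @param transform Predictor transform for the frequency effect: `"raw"`,
#'   `"log"`, or `"match_generative"` (use the generative model's
#'   transform; the default).
#' @return A `learner_spec` object.
#' @examples
#' learner_spec() # intercept + word effect
#' learner_spec(estimate_freq_effect = TRUE)
#' @export
learner_spec <- function(estimate_intercept = TRUE,
                         estimate_freq_effect = FALSE,
                         transform = c("match_generative", "raw", "log")) {
  transform <- match.arg(transform)
  structure(list(estimate_intercept = isTRUE(estimate_intercept),
                 estimate_freq_effect = isTRUE(estimate_freq_effect),
                 transform = transform),
            class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  terms <- c(if (x$estimate_intercept) "b0", "u_w",
             if (x$estimate_freq_effect) "b_freq")
  cat(sprintf("<learner_spec: estimates %s; %s predictor>\n",
              paste(terms, collapse = ", "), x$transform))
  invisible(x)
}

resolve_transform <- function(spec, params = NULL) {
  if (spec$transform != "match_generative") return(spec$transform)
  if (!is.null(params)) params$transform else "raw"
}

# cached Gauss-Hermite rules (physicists' convention: integrates
# exp(-x^2) f(x))
gh_cache <- new.env(parent = emptyenv())
gauss_hermite_rule <- function(n_quad) {
  key <- as.character(n_quad)
  if (is.null(gh_cache[[key]])) {
    gh_cache[[key]] <- if (n_quad == 1) {
      list(x = 0, w = sqrt(pi)) # single-node rule = Laplace approximation
    } else {
      pracma::gaussHermite(n_quad)
    }
  }
  gh_cache[[key]]
}

#' Marginal log-likelihood of the random-intercept binomial model
#'
#' Evaluates `sum_w log integral Binom(n_red_w | freq_w, inv_logit(b0 +
#' b_freq * T(freq_w) + u)) dnorm(u; 0, sigma) du` over the words of a
#' generation state, each integral by adaptive Gauss-Hermite quadrature.
#'
#' @param state A `generation_state` (or any data frame with `freq` and
#'   `n_red` columns).
#' @param b0 Fixed intercept (log-odds).
#' @param b_freq Fixed frequency effect per transformed token.
#' @param sigma Random-effect standard deviation, `>= 0` (at 0 the
#'   likelihood is the fixed-effects binomial likelihood).
#' @param transform Predictor transform, `"raw"` or `"log"`.
#' @param n_quad Quadrature order (`1` = Laplace; default 15).
#' @return The marginal log-likelihood (includes binomial coefficients).
#' @examples
#' st <- seed_generation(headless_eth_lexicon(), seed_params(-1, 0, 0.4),
#'                       seed = 1)
#' marginal_loglik(st, b0 = -1, sigma = 0.4)
#' @export
marginal_loglik <- function(state, b0 = 0, b_freq = 0, sigma,
                            transform = "raw", n_quad = 15) {
  if (sigma < 0) abort("sigma must be >= 0", class = "lexdrift_error")
  stopifnot(n_quad >= 1)
  eta0 <- b0 + b_freq * freq_predictor(state$freq, transform)
  gh <- gauss_hermite_rule(n_quad)
  cpp_marginal_loglik(as.numeric(state$n_red), as.numeric(state$freq),
                      as.numeric(eta0), sigma, gh$x, gh$w)
}

#' Conditional modes of the word effects
#'
#' For each word, the maximizer over `u` of `log Binom(n_red | freq,
#' inv_logit(fixed_eta + u)) - u^2 / (2 sigma^2)`, found by Newton
#' iteration (the objective is strictly concave). With `sigma = 0` all
#' modes are 0. Words with `n_red = 0` or `n_red = freq` need no special
#' handling: the Normal prior keeps their modes finite.
#'
#' @param state A `generation_state`.
#' @param fixed_eta Fixed-effect linear predictor per word (recycled if
#'   scalar).
#' @param sigma Random-effect standard deviation.
#' @return A named numeric vector of modes, one per word.
#' @export
conditional_modes <- function(state, fixed_eta, sigma) {
  if (sigma < 0) abort("sigma must be >= 0", class = "lexdrift_error")
  fixed_eta <- rep_len(as.numeric(fixed_eta), nrow(state))
  if (sigma == 0) return(setNames(numeric(nrow(state)), state$word))
  m <- cpp_cond_modes(as.numeric(state$n_red), as.numeric(state$freq),
                      fixed_eta, sigma)
  setNames(m[, 1], state$word)
}

LOG_SIGMA_LOWER <- -10
LOG_SIGMA_UPPER <- 5

#' Fit the hierarchical learner to a generation
#'
#' Maximizes the marginal likelihood over the subset of `(b0, b_freq)`
#' named by the learner spec and over `log sigma` (bounded in
#' `[-10, 5]`; hitting the lower bound is reported as `sigma_hat = 0`).
#' The frequency predictor is internally scaled to unit standard deviation
#' (and centred when an intercept is estimated) to keep the optimization
#' well-conditioned, with coefficients back-transformed on return. On
#' optimizer failure the fit is retried from up to `restarts` jittered
#' starts; if none converge the best-found values are returned with
#' `converged = FALSE`.
#'
#' @param state A `generation_state` with at least 2 words.
#' @param spec A [learner_spec()].
#' @param params Optional [seed_params()]; resolves a
#'   `"match_generative"` predictor transform.
#' @param n_quad Quadrature order (default 15).
#' @param init Optional named list of starting values (`b0`, `b_freq`,
#'   `sigma`), e.g. the previous generation's fit for a warm start.
#' @param restarts Number of jittered restarts on non-convergence.
#' @return A `learner_fit` object: `b0_hat`, `b_freq_hat` (0 when not
#'   estimated), `sigma_hat`, named vector `u_hat` of conditional modes,
#'   `loglik`, `converged`, `n_quad`, `transform`.
#' @examples
#' st <- seed_generation(headless_eth_lexicon(), seed_params(-3, 0.02, 0.4),
#'                       seed = 1)
#' fit_learner(st)
#' @export
fit_learner <- function(state, spec = learner_spec(), params = NULL,
                        n_quad = 15, init = NULL, restarts = 3) {
  if (nrow(state) < 2) {
    abort("need at least 2 words to fit the learner",
          class = "lexdrift_error")
  }
  transform <- resolve_transform(spec, params)
  x <- freq_predictor(state$freq, transform)
  n <- as.numeric(state$n_red)
  f <- as.numeric(state$freq)
  gh <- gauss_hermite_rule(n_quad)

  # internal predictor standardization (L3 raw counts span 1..thousands)
  x_scale <- if (spec$estimate_freq_effect && stats::sd(x) > 0) {
    stats::sd(x)
  } else 1
  x_center <- if (spec$estimate_freq_effect && spec$estimate_intercept) {
    mean(x)
  } else 0
  z <- (x - x_center) / x_scale

  par_names <- c(if (spec$estimate_intercept) "b0",
                 if (spec$estimate_freq_effect) "bz",
                 "log_sigma")
  lower <- c(b0 = -30, bz = -100, log_sigma = LOG_SIGMA_LOWER)[par_names]
  upper <- c(b0 = 30, bz = 100, log_sigma = LOG_SIGMA_UPPER)[par_names]

  negll <- function(par) {
    par <- setNames(par, par_names)
    eta0 <- (if (spec$estimate_intercept) par[["b0"]] else 0) +
      (if (spec$estimate_freq_effect) par[["bz"]] * z else 0)
    -cpp_marginal_loglik(n, f, rep_len(as.numeric(eta0), length(n)),
                         exp(par[["log_sigma"]]), gh$x, gh$w)
  }

  start <- default_start(state, spec, init, x_center, x_scale)
  # the profile in log sigma can be bimodal (interior mode vs the sigma -> 0
  # boundary); always try a near-boundary start as well and keep the better
  # optimum
  start_low <- start
  start_low[["log_sigma"]] <- log(0.05)
  best <- NULL
  converged <- FALSE
  for (attempt in seq_len(2 + restarts)) {
    st <- if (attempt == 1) start else if (attempt == 2) start_low else {
      jit <- start + rnorm(length(start), 0, 0.5)
      pmin(pmax(jit, lower + 1e-6), upper - 1e-6)
    }
    res <- tryCatch(
      optim(st, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res)) {
      if (res$convergence == 0) converged <- TRUE
      if (is.null(best) || res$value < best$value) best <- res
    }
    if (attempt >= 2 && converged) break
  }
  if (is.null(best)) {
    abort("learner fit failed at every start", class = "lexdrift_error")
  }

  par <- setNames(best$par, par_names)
  log_sigma <- par[["log_sigma"]]
  sigma_hat <- if (log_sigma <= LOG_SIGMA_LOWER + 1e-8) 0 else exp(log_sigma)
  bz <- if (spec$estimate_freq_effect) par[["bz"]] else 0
  b_freq_hat <- bz / x_scale
  b0_hat <- if (spec$estimate_intercept) {
    par[["b0"]] - bz * x_center / x_scale
  } else 0

  eta0 <- rep_len(b0_hat + b_freq_hat * x, length(n))
  u_hat <- if (sigma_hat == 0) {
    setNames(numeric(nrow(state)), state$word)
  } else {
    setNames(cpp_cond_modes(n, f, as.numeric(eta0), sigma_hat)[, 1],
             state$word)
  }

  structure(list(b0_hat = unname(b0_hat), b_freq_hat = unname(b_freq_hat),
                 sigma_hat = unname(sigma_hat), u_hat = u_hat,
                 loglik = -best$value, converged = converged,
                 n_quad = n_quad, transform = transform, spec = spec,
                 n_words = nrow(state)),
            class = "learner_fit")
}

default_start <- function(state, spec, init, x_center, x_scale) {
  p_pool <- sum(state$n_red) / sum(state$freq)
  b0_start <- stats::qlogis(min(max(p_pool, 1e-3), 1 - 1e-3))
  pl <- stats::qlogis(pmin(pmax(state$p_hat, 0.01), 0.99))
  sigma_start <- min(max(stats::sd(pl), 0.05), 5)
  s <- c(b0 = b0_start, bz = 0, log_sigma = log(sigma_start))
  if (!is.null(init)) {
    if (!is.null(init$b0)) s[["b0"]] <- min(max(init$b0, -29), 29)
    if (!is.null(init$b_freq)) {
      s[["bz"]] <- min(max(init$b_freq * x_scale, -99), 99)
      # re-centre the warm-started intercept onto the internal scale
      if (!is.null(init$b0)) {
        s[["b0"]] <- min(max(init$b0 + init$b_freq * x_center, -29), 29)
      }
    }
    if (!is.null(init$sigma) && init$sigma > 0) {
      s[["log_sigma"]] <- min(max(log(init$sigma), LOG_SIGMA_LOWER + 0.5),
                              LOG_SIGMA_UPPER - 0.5)
    }
  }
  s[c(if (spec$estimate_intercept) "b0",
      if (spec$estimate_freq_effect) "bz", "log_sigma")]
}

#' @export
print.learner_fit <- function(x, ...) {
  cat(sprintf(paste0("<learner_fit: b0 = %.4f, b_freq = %.5f, ",
                     "sigma = %.4f, loglik = %.3f, %d words, %s>\n"),
              x$b0_hat, x$b_freq_hat, x$sigma_hat, x$loglik, x$n_words,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @describeIn fit_learner Per-word conditional modes as a tibble
#'   (`word`, `u_hat`).
#' @param x A `learner_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.learner_fit <- function(x, ...) {
  tibble::tibble(word = names(x$u_hat), u_hat = unname(x$u_hat))
}

#' @describeIn fit_learner One-row model summary.
#' @exportS3Method generics::glance
glance.learner_fit <- function(x, ...) {
  tibble::tibble(b0_hat = x$b0_hat, b_freq_hat = x$b_freq_hat,
                 sigma_hat = x$sigma_hat, loglik = x$loglik,
                 converged = x$converged, n_quad = x$n_quad,
                 n_words = x$n_words)
}

#' Serialize a learner fit
#'
#' Writes the scalar estimates as JSON and, alongside it, the per-word
#' conditional modes as TSV (`<path>` with extension `.u.tsv`).
#'
#' @param fit A `learner_fit`.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_learner_fit <- function(fit, path) {
  jsonlite::write_json(glance(fit), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  readr::write_tsv(tidy(fit), paste0(sub("\\.json$", "", path), ".u.tsv"))
  invisible(path)
}
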
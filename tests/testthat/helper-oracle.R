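# Independent oracles used by the inference tests: brute-force numerical
# integration of the marginal likelihood, and a grid-refined MLE. These are
# deliberately slow and simple, and share no code with the package's
# quadrature path.

make_state <- function(freq, n_red, word = sprintf("w%02d", seq_along(freq)),
                       u = 0) {
  tibble::tibble(word = word, freq = as.integer(freq),
                 u = rep_len(u, length(freq)), n_red = as.integer(n_red),
                 p_hat = n_red / freq)
}

# adaptive numerical integration of one word's marginal likelihood over u
brute_word_lik <- function(n, f, eta0, sigma) {
  if (sigma == 0) {
    return(dbinom(n, f, plogis(eta0)))
  }
  stats::integrate(function(u) dbinom(n, f, plogis(eta0 + u)) *
                     dnorm(u, 0, sigma),
                   -Inf, Inf, rel.tol = 1e-12, abs.tol = 0)$value
}

brute_loglik <- function(state, b0 = 0, b_freq = 0, sigma,
                         transform = "raw") {
  x <- if (transform == "log") log(state$freq) else state$freq
  sum(log(mapply(brute_word_lik, state$n_red, state$freq,
                 b0 + b_freq * x, MoreArgs = list(sigma = sigma))))
}

# 2-D grid search over (b0, sigma) refined around the best cell; the
# likelihood at each grid point uses the brute-force integral
grid_mle <- function(state, b0_range = c(-5, 5), sigma_range = c(0, 3),
                     steps = 3, grid_n = 21) {
  b0s <- seq(b0_range[1], b0_range[2], length.out = grid_n)
  sgs <- seq(sigma_range[1], sigma_range[2], length.out = grid_n)
  best <- c(NA, NA, -Inf)
  for (step in seq_len(steps)) {
    ll <- outer(b0s, sgs, Vectorize(function(b, s) {
      brute_loglik(state, b0 = b, sigma = s)
    }))
    idx <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(b0s[idx[1]], sgs[idx[2]], max(ll))
    db <- diff(b0s)[1]; ds <- diff(sgs)[1]
    b0s <- seq(best[1] - db, best[1] + db, length.out = grid_n)
    sgs <- seq(max(0, best[2] - ds), best[2] + ds, length.out = grid_n)
  }
  list(b0 = best[1], sigma = best[2], loglik = best[3])
}
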
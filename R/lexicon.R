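# Lexicon construction: file IO, constraint-matched skewed generation,
# head removal, and the built-in headless /dh/ fixture.

new_lexicon <- function(word, freq) {
  lex <- tibble::tibble(word = as.character(word), freq = as.integer(freq))
  validate_lexicon(lex)
}

validate_lexicon <- function(lex) {
  if (nrow(lex) == 0) abort("lexicon has no entries", class = "lexdrift_error")
  if (anyNA(lex$freq) || any(lex$freq < 1)) {
    abort("all frequencies must be positive integers",
          class = "lexdrift_error")
  }
  if (anyDuplicated(lex$word)) {
    dup <- lex$word[duplicated(lex$word)][1]
    abort(paste0("duplicate word id: ", dup), class = "lexdrift_error")
  }
  class(lex) <- unique(c("lexicon", class(lex)))
  lex
}

#' Build a lexicon from words and token frequencies
#'
#' A lexicon is an immutable tibble of word types with positive integer token
#' frequencies; it seeds every simulation and is held constant across
#' generations (no word birth or death).
#'
#' @param word Character vector of unique word identifiers.
#' @param freq Integer vector of token frequencies, all `>= 1`.
#' @return A `lexicon` tibble with columns `word` and `freq`.
#' @examples
#' lexicon(c("a", "b"), c(1, 2))
#' @export
lexicon <- function(word, freq) {
  stopifnot(length(word) == length(freq))
  if (any(freq != round(freq))) {
    abort("frequencies must be whole numbers", class = "lexdrift_error")
  }
  new_lexicon(word, freq)
}

#' Read a lexicon from a two-column delimited file
#'
#' Reads TSV or CSV (delimiter auto-detected, header auto-detected) with
#' columns word and frequency, preserving file order. Lines beginning with
#' `#` are treated as comments.
#'
#' @param path Path to the file.
#' @return A `lexicon` tibble.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(paste0("no entries in ", path), class = "lexdrift_error")
  }
  delim <- if (grepl("\t", lines[1])) "\t" else ","
  parts <- strsplit(lines, delim, fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    abort(paste0("malformed line ", bad[1], " in ", path,
                 ": expected 2 fields"), class = "lexdrift_error")
  }
  word <- trimws(vapply(parts, `[[`, "", 1))
  freq_chr <- trimws(vapply(parts, `[[`, "", 2))
  freq <- suppressWarnings(as.numeric(freq_chr))
  # header row: second field does not parse as a number
  if (is.na(freq[1]) && length(freq) > 1) {
    word <- word[-1]; freq <- freq[-1]; freq_chr <- freq_chr[-1]
  }
  if (anyNA(freq)) {
    line <- which(is.na(freq))[1]
    abort(paste0("malformed line ", line, " in ", path,
                 ": frequency '", freq_chr[line], "' is not a number"),
          class = "lexdrift_error")
  }
  if (any(freq < 1) || any(freq != round(freq))) {
    line <- which(freq < 1 | freq != round(freq))[1]
    abort(paste0("line ", line, " in ", path,
                 ": frequency must be a positive integer, got ",
                 freq_chr[line]), class = "lexdrift_error")
  }
  if (length(word) == 0) {
    abort(paste0("no entries in ", path), class = "lexdrift_error")
  }
  new_lexicon(word, freq)
}

#' Write a lexicon to a TSV file
#'
#' @param lex A `lexicon`.
#' @param path Output path.
#' @param comment Optional provenance lines written as `#` comments.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path, comment = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("word\tfreq", con)
  writeLines(paste(lex$word, lex$freq, sep = "\t"), con)
  invisible(path)
}

#' Generate a skewed sublexicon with exact summary constraints
#'
#' Emulates a natural sublexicon (e.g. the flap-eligible words of a
#' conversational corpus) whose only simulation-visible features are its
#' type count, hapax count, and maximum token frequency. Type frequencies
#' are drawn from a heavy-tailed lognormal distribution whose two
#' parameters are solved from the constraints themselves: the hapax share
#' fixes the location (`P(freq = 1) = n_hapax / n_types`) and the target
#' maximum is placed at the median of the largest order statistic of
#' `n_types` draws. The three constraints are then imposed exactly: the
#' head is pinned at `max_freq`, the lowest `n_hapax` ranks are set to
#' frequency 1, and every other rank to at least 2. The resulting
#' rank-frequency profile is Zipf-like over the observed range while
#' keeping a realistic balance of head, mid-band, and hapax tail.
#'
#' @param n_types Number of word types.
#' @param n_hapax Number of hapax legomena (types with frequency 1).
#' @param max_freq Maximum token frequency.
#' @param seed Integer seed; the result is bit-reproducible given
#'   `(n_types, n_hapax, max_freq, seed)`.
#' @return A `lexicon` with exactly `n_types` rows in decreasing-frequency
#'   rank order, exactly `n_hapax` entries of frequency 1, and maximum
#'   frequency exactly `max_freq`.
#' @examples
#' lex <- zipf_lexicon(762, 236, 2793, seed = 1)
#' sum(lex$freq == 1)
#' @export
zipf_lexicon <- function(n_types, n_hapax, max_freq, seed) {
  if (n_hapax < 0 || n_hapax > n_types) {
    abort("n_hapax must be between 0 and n_types", class = "lexdrift_error")
  }
  if (max_freq < 1) abort("max_freq must be >= 1", class = "lexdrift_error")
  if (n_hapax == n_types && max_freq > 1) {
    abort("infeasible: all types hapax but max_freq > 1",
          class = "lexdrift_error")
  }
  if (n_types > 1 && max_freq == 1 && n_hapax < n_types) {
    abort("infeasible: max_freq 1 forces every type to be a hapax",
          class = "lexdrift_error")
  }
  word <- sprintf("w%0*d", nchar(n_types), seq_len(n_types))
  if (n_types == 1) {
    return(new_lexicon(word, max_freq))
  }
  if (n_hapax == n_types) {
    return(new_lexicon(word, rep(1L, n_types)))
  }

  # lognormal parameters solved from the constraints: a rounded draw is a
  # hapax when log(freq) < log(1.5), and the head quantile carries the
  # target maximum
  h <- max(n_hapax, 0.5) / n_types
  s <- (log(max_freq) - log(1.5)) /
    (stats::qnorm(1 - 0.5 / n_types) - stats::qnorm(h))
  s <- max(s, 1e-3)
  mu <- log(1.5) - s * stats::qnorm(h)

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(substream_seed(seed, 0L, 0L))
  f <- round(exp(rnorm(n_types, mu, s)))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  # exact constraint imposition on the sorted draws
  f <- sort(pmin(pmax(f, 1), max_freq), decreasing = TRUE)
  f[1] <- max_freq
  if (n_hapax > 0) f[(n_types - n_hapax + 1):n_types] <- 1
  head_idx <- seq_len(n_types - n_hapax)
  f[head_idx] <- pmax(f[head_idx], 2)
  f[1] <- max_freq
  new_lexicon(word, f)
}

#' Drop the high-frequency head of a lexicon
#'
#' Returns the "headless" lexicon: entries with frequency at most `cutoff`,
#' in the original order. Removing the most frequent words (the lexical
#' leaders of an articulatorily-driven change) is the manipulation that lets
#' a change run to completion instead of lexicalizing.
#'
#' @param lex A `lexicon`.
#' @param cutoff Keep entries with `freq <= cutoff` (`cutoff >= 1`).
#' @return A `lexicon`.
#' @export
headless_lexicon <- function(lex, cutoff) {
  stopifnot(cutoff >= 1)
  keep <- lex$freq <= cutoff
  if (!any(keep)) {
    abort("headless lexicon empty: every frequency exceeds the cutoff",
          class = "lexdrift_error")
  }
  validate_lexicon(lex[keep, , drop = FALSE])
}

#' The headless initial-/dh/ lexicon
#'
#' The 10-word sublexicon obtained from the Switchboard words beginning with
#' /dh/ after removing every word above 900 tokens: three hapax legomena plus
#' words of frequency 3, 4, 7, 9, 20, 30, and 211. This small, head-truncated
#' frequency profile is the setting in which the outcome of a change is most
#' chaotic (sputtering, completing, or lexicalizing from chain to chain).
#'
#' @return A 10-row `lexicon` (287 tokens in total).
#' @examples
#' sum(headless_eth_lexicon()$freq)
#' @export
headless_eth_lexicon <- function() {
  f <- c(1L, 1L, 1L, 3L, 4L, 7L, 9L, 20L, 30L, 211L)
  new_lexicon(sprintf("eth%02d", seq_along(f)), f)
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon: %d types, %d tokens, %d hapax, max freq %d>\n",
              nrow(x), sum(x$freq), sum(x$freq == 1L), max(x$freq)))
  NextMethod()
}
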
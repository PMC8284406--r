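# Independent oracles used to freeze expected values.

# Exhaustive enumeration of all 2^n +/-1 sequences: tail probabilities
# P(longest run >= l) for l = 1..n. `symbol = "heads"` counts only runs of 1s.
enum_longest_run_tail <- function(n, symbol = c("either", "heads")) {
  symbol <- match.arg(symbol)
  longest <- integer(2^n)
  for (i in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(i))[seq_len(n)]
    r <- rle(bits)
    longest[i + 1] <- if (symbol == "either") max(r$lengths)
                      else max(c(0L, r$lengths[r$values == 1L]))
  }
  vapply(seq_len(n), function(l) mean(longest >= l), numeric(1))
}

# Brute-force grid search for the buffer scaling factor at the configured
# precision: scan upward from `start`, stop at the first violating factor.
grid_search_factor <- function(sample, buffer, opts = scaling_options()) {
  base <- log_span(subtract_buffer(sample, buffer, opts$start), opts$q_floor)
  q <- sample$q
  i_s <- sample$intensity
  i_b <- buffer$intensity
  last <- NA_real_
  for (f in seq(opts$start, opts$max_factor, by = opts$precision)) {
    sub <- tibble::tibble(q = q, intensity = i_s - f * i_b)
    if (any(criterion_violations(sub, base, opts))) break
    last <- f
  }
  last
}

# Small helper profiles.
flat_profile <- function(value = 1, q = seq(0.1, 2.5, by = 0.01)) {
  saxs_profile(q, rep(value, length(q)))
}

noisy_pair <- function(n = 100, seed = NULL, rel_sd = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  q <- seq(0.01, by = 0.002, length.out = n)
  base <- 100 * exp(-300 * q^2) + 1
  list(
    a = saxs_profile(q, base * (1 + rnorm(n, sd = rel_sd))),
    b = saxs_profile(q, base * (1 + rnorm(n, sd = rel_sd)))
  )
}
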
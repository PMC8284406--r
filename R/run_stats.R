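#' Sign sequence of a pairwise intensity comparison
#'
#' When two measurements of the same scattering curve differ only by noise,
#' each point is equally likely to be higher in either curve — a fair coin
#' toss. The sign sequence records `+1` where the first curve is higher and
#' `-1` where the second is; exact ties carry no directional information and
#' are dropped.
#'
#' @param i1,i2 Numeric intensity vectors of equal length.
#' @return Integer vector over `{+1, -1}` (possibly shorter than the input
#'   after tie removal, possibly empty).
#' @examples
#' sign_sequence(c(3, 1, 4, 1), c(2, 2, 2, 2))
#' @export
sign_sequence <- function(i1, i2) {
  if (length(i1) != length(i2)) {
    abort("intensity vectors must have equal length",
          class = "saxsqc_error_shape")
  }
  s <- sign(i1 - i2)
  as.integer(s[s != 0])
}

#' Patch-size decomposition of a sign sequence
#'
#' Decomposes the sequence into maximal runs ("patches") of identical sign
#' and tabulates their lengths.
#'
#' @param signs Integer vector over `{+1, -1}`.
#' @return A list with `patch_hist`, a tibble of `length` and `count`
#'   (ascending lengths), and `longest`, the maximum patch length
#'   (0 for empty input).
#' @examples
#' patch_histogram(c(1, 1, -1, 1))
#' @export
patch_histogram <- function(signs) {
  if (length(signs) == 0L) {
    return(list(patch_hist = tibble(length = integer(0), count = integer(0)),
                longest = 0L))
  }
  if (!all(signs %in% c(-1L, 1L))) {
    abort("signs must be +1 or -1", class = "saxsqc_error_domain")
  }
  runs <- rle(signs)$lengths
  tab <- table(runs)
  list(
    patch_hist = tibble(length = as.integer(names(tab)),
                        count = as.integer(tab)),
    longest = max(runs)
  )
}

#' Exact longest-run p-value under the fair-coin null
#'
#' Probability that `n` independent fair coin tosses contain a run of at
#' least `l` identical outcomes. By default runs of *either* symbol count
#' (heads or tails, matching a patch of `+1` or `-1`); `symbol = "heads"`
#' restricts to runs of a designated outcome. Computed by exact dynamic
#' programming over the current run length, so every value agrees with
#' enumeration of all `2^n` sequences.
#'
#' @param n Number of tosses (`>= 1`).
#' @param l Run length of interest (`1 <= l <= n`).
#' @param symbol `"either"` (default) or `"heads"`.
#' @return `P(longest run >= l)`, a probability in (0, 1].
#' @examples
#' longest_run_pvalue(4, 4)   # only the two constant sequences: 2/16
#' longest_run_pvalue(10, 1)  # always 1
#' @export
longest_run_pvalue <- function(n, l, symbol = c("either", "heads")) {
  symbol <- match.arg(symbol)
  if (length(n) != 1L || length(l) != 1L || n < 1 || l < 1 || l > n ||
      n != round(n) || l != round(l)) {
    abort("need integers 1 <= l <= n", class = "saxsqc_error_domain")
  }
  if (l == 1 && symbol == "either") return(1)
  # state[k]: probability the current run (of the tracked kind) has length k
  # and no run >= l has occurred yet; 'absorbed' accumulates P(run >= l).
  if (symbol == "either") {
    # after the first toss the run length is 1 regardless of symbol;
    # state[k] = P(current run == k, no run >= l yet), k = 1..l-1
    state <- numeric(l - 1)
    state[1] <- 1
    absorbed <- 0
    for (i in seq_len(n - 1)) {
      new <- numeric(l - 1)
      new[1] <- sum(state) * 0.5                       # opposite symbol
      if (l >= 3) new[2:(l - 1)] <- state[1:(l - 2)] * 0.5
      absorbed <- absorbed + state[l - 1] * 0.5        # run reaches l
      state <- new
    }
    return(absorbed)
  }
  # heads-only: run length 0..l-1 of the designated symbol
  state <- numeric(l)            # state[k+1] = P(current heads-run == k)
  state[1] <- 1
  absorbed <- 0
  for (i in seq_len(n)) {
    new <- numeric(l)
    new[1] <- sum(state) * 0.5                   # tails resets
    if (l >= 2) new[2:l] <- state[1:(l - 1)] * 0.5
    absorbed <- absorbed + state[l] * 0.5        # heads extends run to l
    state <- new
  }
  absorbed
}

#' Compare two scattering profiles with the longest-run statistic
#'
#' Restricts both profiles to a common q range, forms the sign sequence of
#' the pointwise comparison, decomposes it into patches, and computes the
#' exact probability of observing the longest patch (or longer) under the
#' fair-coin null. A small p-value indicates a systematic difference
#' between the curves; the test makes no assumption about the noise
#' magnitude, only that it is exchangeable between the two curves.
#'
#' @param p1,p2 Profile tibbles on matching q grids (no interpolation is
#'   performed; grids must agree, within `tol`, after restriction).
#' @param q_range Optional `c(qmin, qmax)` restriction.
#' @param symbol Passed to [longest_run_pvalue()].
#' @param tol Relative tolerance for declaring the q grids equal.
#' @param on_degenerate What to do when every point ties: `"error"`
#'   (default) or `"pvalue1"`, which returns an empty comparison with
#'   `p_value = 1`.
#' @return A `saxs_comparison` object: fields `signs`, `n`, `patch_hist`,
#'   `longest`, `p_value`, `symbol`. Methods: [print()], [tidy()]
#'   (patch histogram), [glance()] (one-row summary), [autoplot()].
#' @examples
#' q <- seq(0.01, 0.1, 0.005)
#' a <- saxs_profile(q, q^-2)
#' b <- saxs_profile(q, q^-2 * (1 + rnorm(length(q), sd = 0.01)))
#' compare_profiles(a, b)
#' @export
compare_profiles <- function(p1, p2, q_range = NULL,
                             symbol = c("either", "heads"),
                             tol = 1e-8, on_degenerate = c("error", "pvalue1")) {
  symbol <- match.arg(symbol)
  on_degenerate <- match.arg(on_degenerate)
  validate_profile(p1); validate_profile(p2)
  a <- restrict_profile(p1, q_range)
  b <- restrict_profile(p2, q_range)
  if (nrow(a) != nrow(b) ||
      (nrow(a) > 0 && any(abs(a$q - b$q) > tol * pmax(abs(a$q), 1)))) {
    abort("profiles are not on a common q grid after restriction",
          class = "saxsqc_error_grid")
  }
  signs <- sign_sequence(a$intensity, b$intensity)
  ph <- patch_histogram(signs)
  n <- length(signs)
  if (n == 0L) {
    if (on_degenerate == "error") {
      abort("all points tie exactly; comparison is degenerate",
            class = "saxsqc_error_degenerate_comparison")
    }
    p <- 1
  } else {
    p <- longest_run_pvalue(n, ph$longest, symbol = symbol)
  }
  structure(
    list(signs = signs, n = n, patch_hist = ph$patch_hist,
         longest = ph$longest, p_value = p, symbol = symbol),
    class = "saxs_comparison"
  )
}

#' @export
print.saxs_comparison <- function(x, ...) {
  cat(sprintf("<saxs_comparison> n = %d, longest patch = %d, p = %.4g (%s-symbol null)\n",
              x$n, x$longest, x$p_value, x$symbol))
  invisible(x)
}

#' @export
tidy.saxs_comparison <- function(x, ...) {
  x$patch_hist
}

#' @export
glance.saxs_comparison <- function(x, ...) {
  tibble(n = x$n, longest = x$longest, p_value = x$p_value,
         n_patches = sum(x$patch_hist$count), symbol = x$symbol)
}

#' @export
autoplot.saxs_comparison <- function(object, ...) {
  bars <- tibble(index = seq_along(object$signs),
                 sign = factor(object$signs, levels = c(-1, 1)))
  p1 <- ggplot2::ggplot(bars, ggplot2::aes(x = .data$index,
                                           y = as.numeric(as.character(.data$sign)),
                                           fill = .data$sign)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "point", y = "sign",
                  title = sprintf("longest patch %d of n = %d, p = %.3g",
                                  object$longest, object$n, object$p_value))
  p2 <- ggplot2::ggplot(object$patch_hist,
                        ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "patch size", y = "count")
  if (requireNamespace("patchwork", quietly = TRUE)) {
    p1 + patchwork::wrap_plots(p2)
  } else {
    p1
  }
}
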
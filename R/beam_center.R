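#' Opposing pie-slice cuts through the beam center
#'
#' Isotropic solution scattering is centro-symmetric about the direct beam,
#' so azimuthal averages taken in two opposing pie slices must agree if the
#' assumed beam center is correct. `"vertical"` uses slices at 90 and 270
#' degrees (above/below the beam), `"horizontal"` 0 and 180 degrees.
#'
#' @param pattern A [saxs_pattern()].
#' @param axis `"vertical"` or `"horizontal"`.
#' @param q_grid Ascending q bin centers for the cuts.
#' @param half_angle Pie-slice half opening angle in degrees (default 10).
#' @return A list of two profile tibbles, `a` and `b` (a = 90 or 0 degrees,
#'   b = the opposing slice).
#' @export
opposing_cuts <- function(pattern, axis = c("vertical", "horizontal"),
                          q_grid, half_angle = 10) {
  axis <- match.arg(axis)
  dirs <- if (axis == "vertical") c(90, 270) else c(0, 180)
  list(
    a = pie_slice_average(pattern, dirs[1], half_angle, q_grid),
    b = pie_slice_average(pattern, dirs[2], half_angle, q_grid)
  )
}

#' Beam-center verification by shifted-cut comparison
#'
#' Compares the two opposing low-q cuts with the longest-run statistic at
#' relative index offsets of -1, 0 and +1 q-grid points. A one-point offset
#' between the cuts realizes a small beam-center displacement along the
#' axis: displacing the center by d pixels shifts the two opposing cuts by
#' +/- d pixels (in radius) in opposite directions, so on a grid with a
#' step of `2 d` pixel-equivalents a one-index offset re-aligns them
#' exactly. If the center is correct the unshifted comparison is the most
#' coin-toss-like (largest p-value); if it is off, one of the shifted
#' comparisons improves on it.
#'
#' Decision rule: recommend `"keep"` when the unshifted comparison has the
#' (weakly) largest p-value; otherwise recommend the shift with the largest
#' p-value; report `"inconclusive"` when every p-value is at least 0.5 or
#' fewer than 10 points survive tie removal. With the conventions above a
#' `shift_plus` verdict on the vertical axis means the true center lies at
#' a larger row coordinate than assumed (and symmetrically for
#' `shift_minus` / horizontal).
#'
#' @param pattern A [saxs_pattern()].
#' @param axis `"vertical"` or `"horizontal"`.
#' @param q_grid Uniform ascending q bin centers; defaults to a grid from
#'   the 3rd pixel-equivalent up to `q_max` in steps of 2 pixel-equivalents.
#' @param q_max Upper end of the comparison range (default 0.05 1/Angstrom,
#'   the very low angle part of the pattern).
#' @param half_angle Pie-slice half angle in degrees.
#' @param symbol Passed to [compare_profiles()].
#' @return A `saxs_center_verdict`: fields `axis`, `results` (named list of
#'   [compare_profiles()] results for shifts `-1`, `0`, `+1`),
#'   `recommendation` (`keep`, `shift_minus`, `shift_plus`, `inconclusive`)
#'   and `p_values`. Methods: [print()], [glance()], [autoplot()].
#' @export
center_scan <- function(pattern, axis = c("vertical", "horizontal"),
                        q_grid = NULL, q_max = 0.05, half_angle = 10,
                        symbol = "either") {
  axis <- match.arg(axis)
  g <- pattern$geometry
  q_per_px <- (4 * pi / g$wavelength) *
    sin(atan(g$pixel_size / g$distance) / 2)
  if (is.null(q_grid)) {
    q_grid <- seq(3 * q_per_px, q_max, by = 2 * q_per_px)
  }
  steps <- diff(q_grid)
  if (length(q_grid) >= 3 &&
      any(abs(steps - steps[1]) > 1e-6 * steps[1])) {
    abort("q_grid must be uniform for a one-point shift to be well defined",
          class = "saxsqc_error_domain")
  }
  cuts <- opposing_cuts(pattern, axis, q_grid, half_angle)
  usable <- !cuts$a$empty & !cuts$b$empty &
    is.finite(cuts$a$intensity) & is.finite(cuts$b$intensity)
  if (sum(usable) < 3L) {
    abort("fewer than 3 usable q points for the center scan",
          class = "saxsqc_error_insufficient_data")
  }
  a <- cuts$a[usable, ]
  b <- cuts$b[usable, ]
  n <- nrow(a)

  compare_at <- function(offset) {
    ia <- seq_len(n - abs(offset))
    ib <- ia + max(offset, 0)
    ia <- ia + max(-offset, 0)
    compare_profiles(
      saxs_profile(a$q[ia], a$intensity[ia]),
      saxs_profile(a$q[ia], b$intensity[ib]),
      symbol = symbol, on_degenerate = "pvalue1"
    )
  }
  results <- list(`-1` = compare_at(-1L), `0` = compare_at(0L),
                  `+1` = compare_at(+1L))
  pv <- vapply(results, function(r) r$p_value, numeric(1))
  n0 <- results[["0"]]$n

  recommendation <-
    if (all(pv >= 0.5) || n0 < 10) "inconclusive"
    else if (pv[["0"]] >= max(pv)) "keep"
    else if (pv[["+1"]] >= pv[["-1"]]) "shift_plus"
    else "shift_minus"

  structure(
    list(axis = axis, results = results, p_values = pv,
         recommendation = recommendation, q_grid = a$q, cuts = cuts),
    class = "saxs_center_verdict"
  )
}

#' @export
print.saxs_center_verdict <- function(x, ...) {
  cat(sprintf("<saxs_center_verdict> axis = %s, recommendation = %s\n",
              x$axis, x$recommendation))
  cat(sprintf("  p(shift -1) = %.3g, p(0) = %.3g, p(+1) = %.3g\n",
              x$p_values[["-1"]], x$p_values[["0"]], x$p_values[["+1"]]))
  invisible(x)
}

#' @export
glance.saxs_center_verdict <- function(x, ...) {
  tibble(axis = x$axis,
         p_minus = x$p_values[["-1"]],
         p_zero = x$p_values[["0"]],
         p_plus = x$p_values[["+1"]],
         n = x$results[["0"]]$n,
         recommendation = x$recommendation)
}

#' @export
tidy.saxs_center_verdict <- function(x, ...) {
  purrr::map_dfr(names(x$results), function(s) {
    dplyr::mutate(glance(x$results[[s]]), shift = s, .before = 1)
  })
}

#' @export
autoplot.saxs_center_verdict <- function(object, ...) {
  cuts <- dplyr::bind_rows(
    dplyr::mutate(object$cuts$a, side = "a"),
    dplyr::mutate(object$cuts$b, side = "b"))
  ggplot2::ggplot(cuts, ggplot2::aes(x = .data$q, y = .data$intensity,
                                     colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = sprintf("axis %s: %s  (p = %.3g / %.3g / %.3g)",
                                  object$axis, object$recommendation,
                                  object$p_values[["-1"]],
                                  object$p_values[["0"]],
                                  object$p_values[["+1"]]),
                  x = "q (1/A)", y = "intensity")
}
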
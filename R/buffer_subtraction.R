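#' Options for the automated scaling-factor search
#'
#' Defaults follow routine beamline practice: the factor starts at 0.9 and
#' is raised in steps of 0.01; each time a criterion fires the step is cut
#' by 10 until the target precision of 0.0001; the factor is capped at 1.0
#' because a water-peak-matched buffer should never be scaled up.
#'
#' @param start Initial scaling factor (default 0.9).
#' @param initial_step Initial step size (default 0.01).
#' @param precision Terminal step size (default 1e-4); the returned factor
#'   is reported on this grid.
#' @param max_factor Upper cap (default 1.0).
#' @param q_floor Criterion 2 considers only q above this value (default
#'   0.3 1/Angstrom), where structural features cannot produce sharp
#'   intensity variation.
#' @param span_threshold Maximum allowed increase of the log10 dynamic
#'   range relative to the baseline, in decades (default 0.05).
#' @param water_window q window of the water peak (default c(1.8, 2.2)).
#' @param dip_window q interval searched for the over-subtraction dip
#'   (default c(1.95, 2.05)). Over-subtraction scoops a minimum into the
#'   centre of the residual peak, whereas an under-subtracted residual peak
#'   always places its trailing-edge minimum beyond one peak-width of the
#'   centre; restricting the search to the core of the peak keeps the test
#'   specific to over-subtraction.
#' @param smooth Apply 3-point smoothing before the water-dip test
#'   (default TRUE).
#' @return A list of class `scaling_options`.
#' @export
scaling_options <- function(start = 0.9, initial_step = 0.01,
                            precision = 1e-4, max_factor = 1.0,
                            q_floor = 0.3, span_threshold = 0.05,
                            water_window = c(1.8, 2.2),
                            dip_window = c(1.95, 2.05), smooth = TRUE) {
  if (!(start > 0 && start < max_factor && max_factor <= 1.5)) {
    abort("need 0 < start < max_factor <= 1.5", class = "saxsqc_error_domain")
  }
  if (!(precision > 0 && precision < initial_step)) {
    abort("need 0 < precision < initial_step", class = "saxsqc_error_domain")
  }
  structure(list(start = start, initial_step = initial_step,
                 precision = precision, max_factor = max_factor,
                 q_floor = q_floor, span_threshold = span_threshold,
                 water_window = water_window, dip_window = dip_window,
                 smooth = smooth),
            class = "scaling_options")
}

#' Match buffer to sample on the water peak
#'
#' Scales the buffer profile so its water-peak magnitude (maximum intensity
#' near q = 2/Angstrom) equals the sample's. Because protein also scatters
#' under the water peak this matching slightly over-weights the buffer; the
#' subsequent scaling-factor estimate compensates by scaling the matched
#' buffer back down.
#'
#' @param sample,buffer Profile tibbles on identical q grids, both covering
#'   the water window.
#' @param window Water-peak q window (default c(1.8, 2.2)).
#' @return A list with `buffer` (the scaled profile, `sigma` scaled too)
#'   and `prefactor`.
#' @export
match_water_peak <- function(sample, buffer, window = c(1.8, 2.2)) {
  check_same_grid(sample, buffer)
  ms <- water_peak_magnitude(sample, window)
  mb <- water_peak_magnitude(buffer, window)
  if (!is.finite(mb) || mb <= 0) {
    abort("buffer water-peak magnitude is not positive",
          class = "saxsqc_error_degenerate_buffer")
  }
  prefactor <- ms / mb
  out <- buffer
  out$intensity <- out$intensity * prefactor
  if ("sigma" %in% names(out)) out$sigma <- out$sigma * prefactor
  list(buffer = out, prefactor = prefactor)
}

#' Scaled buffer subtraction with uncertainty propagation
#'
#' @param sample,buffer Profile tibbles on identical q grids.
#' @param factor Scaling factor f; the result is
#'   `I_sample - f * I_buffer`, with
#'   `sigma = sqrt(sigma_s^2 + f^2 sigma_b^2)` where both are present.
#' @return A profile-shaped tibble (intensity may be negative).
#' @export
subtract_buffer <- function(sample, buffer, factor) {
  check_same_grid(sample, buffer)
  out <- tibble(q = sample$q,
                intensity = sample$intensity - factor * buffer$intensity)
  if ("sigma" %in% names(sample) && "sigma" %in% names(buffer)) {
    out$sigma <- sqrt(sample$sigma^2 + factor^2 * buffer$sigma^2)
  }
  out
}

#' Over-subtraction criteria
#'
#' Criterion 1 fires when the subtracted intensity goes negative anywhere,
#' or when `q * I_sub` develops an interior local minimum under the water
#' peak — both signatures of removing more buffer than is present.
#' Criterion 2 fires when the dynamic range of the subtracted data over
#' `q > q_floor`, measured as the log10 span between the highest and lowest
#' positive intensities, grows beyond `baseline_span + span_threshold`.
#'
#' @param sub Subtracted profile (full q grid).
#' @param baseline_span Reference log10 span in decades; the search uses
#'   the span of the subtraction at the starting factor.
#' @param opts A [scaling_options()].
#' @return A named logical vector `c(c1 = ..., c2 = ...)`, with attribute
#'   `"degenerate"` set when no positive intensities remain above
#'   `q_floor` (reported as a criterion-2 violation).
#' @export
criterion_violations <- function(sub, baseline_span, opts = scaling_options()) {
  c1 <- any(sub$intensity < 0)
  if (!c1) {
    win <- sub$q >= opts$dip_window[1] & sub$q <= opts$dip_window[2]
    if (sum(win) >= 3) {
      qi <- sub$q[win] * sub$intensity[win]
      if (isTRUE(opts$smooth) && length(qi) >= 3) {
        qi <- stats::filter(qi, rep(1 / 3, 3), sides = 2)
        qi <- qi[!is.na(qi)]
      }
      c1 <- has_interior_minimum(qi)
    }
  }
  vals <- sub$intensity[sub$q > opts$q_floor]
  degenerate <- FALSE
  if (any(vals > 0)) {
    span <- log_span(sub, opts$q_floor)
    c2 <- span > baseline_span + opts$span_threshold
  } else if (all(vals == 0)) {
    c2 <- FALSE        # perfect subtraction: nothing left, nothing violated
  } else {
    c2 <- TRUE
    degenerate <- TRUE # nothing positive remains above q_floor
  }
  structure(c(c1 = c1, c2 = c2), degenerate = degenerate)
}

# strict three-point interior local minimum
has_interior_minimum <- function(x) {
  n <- length(x)
  if (n < 3) return(FALSE)
  any(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] < x[3:n])
}

#' @rdname criterion_violations
#' @export
log_span <- function(sub, q_floor = 0.3) {
  v <- sub$intensity[sub$q > q_floor]
  v <- v[v > 0 & is.finite(v)]
  if (length(v) == 0) return(Inf)
  log10(max(v)) - log10(min(v))
}

#' Automated buffer-subtraction scaling factor
#'
#' Coarse-to-fine search for the largest scaling factor at which the
#' subtraction `sample - f * buffer` still satisfies both over-subtraction
#' criteria (see [criterion_violations()]). Starting from `opts$start` the
#' factor is raised by `initial_step` until a criterion fires, then the
#' search backs off to the last feasible factor and the step is divided by
#' 10; this repeats until the step falls below `precision` or the factor
#' reaches `max_factor`. The supplied buffer is assumed to be already
#' water-peak matched (see [match_water_peak()]).
#'
#' @param sample,buffer Profile tibbles on identical q grids (buffer
#'   already matched).
#' @param opts A [scaling_options()].
#' @return A `saxs_scaling` object: `factor` (rounded to the configured
#'   precision), `terminated_by` (`"criterion_1"`, `"criterion_2"` or
#'   `"max_factor_cap"`), `baseline_span`, and `trace`, a tibble of every
#'   tested factor with its violation flags. Methods: [print()], [tidy()]
#'   (the trace), [glance()], [autoplot()].
#' @export
estimate_scaling_factor <- function(sample, buffer, opts = scaling_options()) {
  check_same_grid(sample, buffer)
  if (min(sample$q) > opts$water_window[1] ||
      max(sample$q) < opts$water_window[2]) {
    abort("profiles must cover the water window",
          class = "saxsqc_error_range")
  }
  baseline_span <- log_span(subtract_buffer(sample, buffer, opts$start),
                            opts$q_floor)
  test <- function(f) {
    criterion_violations(subtract_buffer(sample, buffer, f),
                         baseline_span, opts)
  }
  v0 <- test(opts$start)
  trace <- list(trace_row(opts$start, v0))
  if (any(v0)) {
    abort(sprintf("criteria already violated at the starting factor %g; pathological sample/buffer pair",
                  opts$start),
          class = "saxsqc_error_start_infeasible")
  }
  f <- opts$start
  step <- opts$initial_step
  terminated_by <- "max_factor_cap"
  last_violation <- NULL
  while (step >= opts$precision) {
    f_next <- f + step
    if (f_next > opts$max_factor + 1e-12) {
      # cannot raise further at this step; refine
      step <- step / 10
      next
    }
    v <- test(f_next)
    trace[[length(trace) + 1L]] <- trace_row(f_next, v)
    if (any(v)) {
      last_violation <- v
      step <- step / 10
    } else {
      f <- f_next
    }
  }
  if (!is.null(last_violation)) {
    terminated_by <- if (last_violation[["c1"]]) "criterion_1" else "criterion_2"
  } else if (f < opts$max_factor - 1e-12) {
    terminated_by <- "precision_reached"
  }
  structure(
    list(factor = round(f / opts$precision) * opts$precision,
         terminated_by = terminated_by,
         baseline_span = baseline_span,
         trace = dplyr::bind_rows(trace),
         options = opts),
    class = "saxs_scaling"
  )
}

trace_row <- function(f, v) {
  tibble(factor = f, c1 = unname(v[["c1"]]), c2 = unname(v[["c2"]]))
}

#' @export
print.saxs_scaling <- function(x, ...) {
  cat(sprintf("<saxs_scaling> factor = %.4f (terminated by %s, %d evaluations)\n",
              x$factor, x$terminated_by, nrow(x$trace)))
  invisible(x)
}

#' @export
tidy.saxs_scaling <- function(x, ...) {
  x$trace
}

#' @export
glance.saxs_scaling <- function(x, ...) {
  tibble(factor = x$factor, terminated_by = x$terminated_by,
         n_evaluations = nrow(x$trace), baseline_span = x$baseline_span)
}

#' @export
autoplot.saxs_scaling <- function(object, ...) {
  tr <- dplyr::mutate(object$trace,
                      violated = .data$c1 | .data$c2,
                      step = seq_len(nrow(object$trace)))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$factor,
                                   colour = .data$violated)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$factor, linetype = 2) +
    ggplot2::labs(x = "evaluation", y = "scaling factor",
                  title = sprintf("estimated factor %.4f", object$factor))
}

check_same_grid <- function(a, b, tol = 1e-8) {
  validate_profile(a); validate_profile(b)
  if (nrow(a) != nrow(b) || any(abs(a$q - b$q) > tol * pmax(abs(a$q), 1))) {
    abort("profiles must share an identical q grid",
          class = "saxsqc_error_grid")
  }
  invisible(TRUE)
}
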
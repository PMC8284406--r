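#' Build a 1-D scattering profile
#'
#' A profile is a tibble with columns `q` (scattering-vector magnitude,
#' 1/Angstrom, strictly increasing, non-negative), `intensity` (arbitrary
#' units) and optionally `sigma` (per-point uncertainty, same units as
#' `intensity`). All `saxsqc` functions that consume profiles accept any
#' data frame with these columns.
#'
#' @param q Numeric vector of scattering-vector magnitudes (1/Angstrom),
#'   strictly increasing, all `>= 0`.
#' @param intensity Numeric vector of intensities, same length as `q`.
#' @param sigma Optional numeric vector of uncertainties (`>= 0`).
#' @param label Optional free-text label stored in the `"label"` attribute.
#' @return A tibble with columns `q`, `intensity` and (if given) `sigma`.
#' @examples
#' p <- saxs_profile(q = seq(0.01, 0.5, 0.01), intensity = seq(0.01, 0.5, 0.01)^-2)
#' head(p)
#' @export
saxs_profile <- function(q, intensity, sigma = NULL, label = NULL) {
  p <- tibble(q = as.numeric(q), intensity = as.numeric(intensity))
  if (!is.null(sigma)) p$sigma <- as.numeric(sigma)
  validate_profile(p)
  if (!is.null(label)) attr(p, "label") <- label
  p
}

#' Check that a data frame is a valid scattering profile
#'
#' @param p A data frame with columns `q`, `intensity`, optionally `sigma`.
#' @return `p`, invisibly, if valid; otherwise an error of class
#'   `saxsqc_error_profile` is raised.
#' @export
validate_profile <- function(p) {
  if (!is.data.frame(p) || !all(c("q", "intensity") %in% names(p))) {
    abort("profile must be a data frame with columns `q` and `intensity`",
          class = "saxsqc_error_profile")
  }
  if (nrow(p) < 1L) {
    abort("profile has no points", class = "saxsqc_error_profile")
  }
  if (any(!is.finite(p$q)) || any(p$q < 0)) {
    abort("`q` must be finite and non-negative", class = "saxsqc_error_profile")
  }
  if (is.unsorted(p$q, strictly = TRUE)) {
    abort("`q` must be strictly increasing", class = "saxsqc_error_profile")
  }
  if ("sigma" %in% names(p) && any(p$sigma < 0, na.rm = TRUE)) {
    abort("`sigma` must be non-negative", class = "saxsqc_error_profile")
  }
  invisible(p)
}

#' Read a three-column ASCII scattering profile
#'
#' Reads the conventional whitespace-delimited `.dat` format: columns
#' `q`, `I` and optionally `sigma`; lines starting with `#` are comments.
#'
#' @param path Path to the file.
#' @return A profile tibble (see [saxs_profile()]); the file name is stored
#'   in the `"label"` attribute.
#' @export
read_profile <- function(path) {
  m <- read.table(path, comment.char = "#", header = FALSE,
                  colClasses = "numeric")
  if (ncol(m) < 2L) {
    abort("profile file must have at least 2 columns (q, I)",
          class = "saxsqc_error_io")
  }
  saxs_profile(q = m[[1L]], intensity = m[[2L]],
               sigma = if (ncol(m) >= 3L) m[[3L]],
               label = basename(path))
}

#' Write a profile as three-column ASCII
#'
#' @param p Profile tibble.
#' @param path Output path.
#' @param comment Optional character vector written as `#` header lines.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path, comment = NULL) {
  validate_profile(p)
  cols <- c("q", "intensity", if ("sigma" %in% names(p)) "sigma")
  lines <- character(0)
  if (!is.null(comment)) lines <- paste("#", comment)
  body <- do.call(paste, c(lapply(p[cols], formatC, format = "g", digits = 7),
                           list(sep = "  ")))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Magnitude of the water peak
#'
#' Bulk-water scattering produces a broad maximum near q = 2/Angstrom that
#' serves as an internal intensity standard for buffer matching. The
#' magnitude is the maximum intensity inside a q window around the peak.
#'
#' @param p Profile tibble.
#' @param window Two-element numeric, the q window searched
#'   (default `c(1.8, 2.2)` 1/Angstrom).
#' @return The maximum intensity within the window (scalar).
#' @examples
#' q <- seq(0.5, 2.5, 0.01)
#' p <- saxs_profile(q, 1 + 0.5 * exp(-(q - 2)^2 / (2 * 0.08^2)))
#' water_peak_magnitude(p)
#' @export
water_peak_magnitude <- function(p, window = c(1.8, 2.2)) {
  validate_profile(p)
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (min(p$q) > window[1] || max(p$q) < window[2]) {
    abort(sprintf("profile q range [%g, %g] does not cover the water window [%g, %g]",
                  min(p$q), max(p$q), window[1], window[2]),
          class = "saxsqc_error_range")
  }
  inside <- p$q >= window[1] & p$q <= window[2]
  max(p$intensity[inside])
}

# Restrict a profile to a q range (inclusive); empty result allowed.
restrict_profile <- function(p, q_range = NULL) {
  if (is.null(q_range)) return(p)
  stopifnot(length(q_range) == 2L)
  dplyr::filter(p, .data$q >= q_range[1], .data$q <= q_range[2])
}
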
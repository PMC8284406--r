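#' Parameters for the synthetic-data generator
#'
#' The generator emulates the structure of well-averaged solution
#' scattering: a buffer curve with a flat baseline, a weak power-law and a
#' Gaussian water peak at q = 2/Angstrom; a protein term modelled as a
#' sphere form factor plus a small flat wide-angle level; Poisson counting
#' noise at a configurable counts-per-intensity conversion; and, for 2-D
#' patterns, an isotropic mapping of I(q) onto a pixel grid about a planted
#' beam center.
#'
#' @param radius Sphere radius in Angstrom (default 20).
#' @param i0 Protein forward intensity (default 0.03, relative to a buffer
#'   baseline of 1).
#' @param protein_flat Flat wide-angle protein level (default 0.003); real
#'   protein scattering approaches a constant at q > 1/Angstrom, and this
#'   term is what the water-peak matching over-weights.
#' @param baseline Buffer baseline level (default 1).
#' @param powerlaw_amp,powerlaw_exp Weak power-law component
#'   `amp * q^(-exp)` of the buffer (defaults 0.05 and 0.2).
#' @param peak_amp,peak_center,peak_width Gaussian water peak (defaults
#'   1.0, 2.0, 0.1 1/Angstrom).
#' @param buffer_factor Planted buffer-mixing factor c (default 0.995).
#' @param counts_per_intensity Poisson counts per intensity unit (default
#'   1e12, emulating profiles averaged over many pixels and exposures;
#'   0 disables noise).
#' @param geometry A [saxs_geometry()] for 2-D patterns.
#' @param center_offset Planted center offset in pixels `c(dcol, drow)`.
#' @param pattern_counts Peak per-pixel counts for 2-D patterns
#'   (default 2000).
#' @param pattern_radius Sphere radius used for 2-D patterns (default 60
#'   Angstrom, so intensity falls several-fold inside q < 0.05).
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(radius = 20, i0 = 0.03, protein_flat = 0.003,
                         baseline = 1, powerlaw_amp = 0.05,
                         powerlaw_exp = 0.2, peak_amp = 1.0,
                         peak_center = 2.0, peak_width = 0.1,
                         buffer_factor = 0.995,
                         counts_per_intensity = 1e12,
                         geometry = saxs_geometry(1.0, 10000, 1.0,
                                                  center = c(100, 100)),
                         center_offset = c(0, 0),
                         pattern_counts = 2000,
                         pattern_radius = 60) {
  stopifnot(radius > 0, baseline > 0, peak_amp >= 0, peak_width > 0,
            counts_per_intensity >= 0, pattern_counts > 0)
  structure(as.list(environment()), class = "synth_params")
}

#' Sphere form factor
#'
#' `P(x) = [3 (sin x - x cos x) / x^3]^2` with `P(0) = 1`; the first zero
#' sits at `x = qR` equal to the smallest positive root of `tan x = x`
#' (about 4.493).
#'
#' @param x Dimensionless `q * R`.
#' @return Numeric vector in `[0, 1]`.
#' @export
sphere_form_factor <- function(x) {
  out <- x
  out[] <- 1
  nz <- x != 0
  out[nz] <- (3 * (sin(x[nz]) - x[nz] * cos(x[nz])) / x[nz]^3)^2
  out
}

# Poisson-like noise at `cpi` counts per intensity unit; exact Poisson for
# small expectations, Gaussian approximation above (rpois is integer-bound).
add_counting_noise <- function(intensity, cpi) {
  if (cpi <= 0) {
    return(list(intensity = intensity, sigma = rep(0, length(intensity))))
  }
  lambda <- pmax(intensity, 0) * cpi
  counts <- ifelse(lambda < 1e6,
                   rpois(length(lambda), pmin(lambda, 1e6)),
                   rnorm(length(lambda), lambda, sqrt(lambda)))
  list(intensity = counts / cpi, sigma = sqrt(pmax(lambda, 1)) / cpi)
}

buffer_model <- function(params, q) {
  params$baseline + params$powerlaw_amp * q^(-params$powerlaw_exp) +
    params$peak_amp * exp(-(q - params$peak_center)^2 / (2 * params$peak_width^2))
}

protein_model <- function(params, q) {
  params$i0 * sphere_form_factor(q * params$radius) + params$protein_flat
}

#' Synthetic buffer profile
#'
#' @param params A [synth_params()].
#' @param q_grid Positive ascending q values (default 0.01-2.5 in steps of
#'   0.01).
#' @param seed Optional RNG seed for reproducible noise.
#' @return A profile tibble; the noiseless model curve is stored in the
#'   `"truth"` attribute.
#' @export
make_buffer_profile <- function(params = synth_params(),
                                q_grid = seq(0.01, 2.5, by = 0.01),
                                seed = NULL) {
  if (any(q_grid <= 0)) {
    abort("q_grid must be positive", class = "saxsqc_error_domain")
  }
  if (!is.null(seed)) set.seed(seed)
  model <- buffer_model(params, q_grid)
  noisy <- add_counting_noise(model, params$counts_per_intensity)
  p <- saxs_profile(q_grid, noisy$intensity, sigma = noisy$sigma,
                    label = "synthetic buffer")
  attr(p, "truth") <- list(model = model)
  p
}

#' Synthetic protein-in-buffer sample profile
#'
#' `I(q) = i0 * P_sphere(qR) + protein_flat + c * I_buffer(q) + noise`,
#' where `c` is the planted buffer-mixing factor recovered by
#' [estimate_scaling_factor()].
#'
#' @param params A [synth_params()]; `params$buffer_factor` is the planted
#'   c.
#' @param buffer Buffer profile on the target q grid (its noiseless model
#'   is used for mixing so the planted factor is exact; pass a noiseless
#'   buffer to reproduce a measured pair).
#' @param seed Optional RNG seed.
#' @return A profile tibble with the planted truth (factor c and model
#'   curves) in the `"truth"` attribute.
#' @export
make_sample_profile <- function(params = synth_params(), buffer,
                                seed = NULL) {
  validate_profile(buffer)
  if (!is.null(seed)) set.seed(seed)
  q <- buffer$q
  truth_buffer <- attr(buffer, "truth")$model %||% buffer$intensity
  protein <- protein_model(params, q)
  model <- protein + params$buffer_factor * truth_buffer
  noisy <- add_counting_noise(model, params$counts_per_intensity)
  p <- saxs_profile(q, noisy$intensity, sigma = noisy$sigma,
                    label = "synthetic sample")
  attr(p, "truth") <- list(buffer_factor = params$buffer_factor,
                           protein = protein, model = model)
  p
}

#' Synthetic isotropic 2-D pattern with a planted beam center
#'
#' Maps a radial intensity model onto the pixel grid about the planted
#' true center (nominal geometry center plus `params$center_offset`), then
#' applies per-pixel Poisson noise. The nominal geometry is recorded in
#' the pattern, the truth in `pattern$truth`.
#'
#' @param params A [synth_params()].
#' @param radial Function of q giving the noiseless intensity in counts;
#'   defaults to `pattern_counts * P_sphere(q * pattern_radius) + 10`.
#' @param shape Image dimensions (default 200 x 200).
#' @param seed Optional RNG seed.
#' @return A [saxs_pattern()]; `truth$center` is the true center,
#'   `truth$offset` the planted offset in pixels.
#' @export
make_pattern2d <- function(params = synth_params(), radial = NULL,
                           shape = c(200L, 200L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- params$geometry
  true_center <- g$center + params$center_offset
  if (any(true_center < 0) || true_center[1] > shape[2] - 1 ||
      true_center[2] > shape[1] - 1) {
    abort("planted center offset pushes the beam center off the image",
          class = "saxsqc_error_domain")
  }
  if (is.null(radial)) {
    radial <- function(q) {
      params$pattern_counts * sphere_form_factor(q * params$pattern_radius) + 10
    }
  }
  g_true <- saxs_geometry(g$wavelength, g$distance, g$pixel_size, true_center)
  qm <- compute_q_map(g_true, shape)
  mu <- radial(qm)
  img <- matrix(rpois(length(mu), mu), nrow = shape[1])
  saxs_pattern(img, g, truth = list(center = true_center,
                                    offset = params$center_offset))
}

#' Synthetic plate and measurement sheets with planted errors
#'
#' Builds a clean 96-well plate sheet (each plate row: a buffer in well 1
#' serving wells 2-5, a second buffer in well 6 serving wells 7-9) plus the
#' matching measurement sheet, then plants the requested rule violations.
#' Clean sheets validate with zero errors; each planted rule id produces
#' exactly the corresponding validation error.
#'
#' @param n_wells Number of occupied wells (in multiples of 9 the plate
#'   rows are full; default 72, a full 8-row plate).
#' @param planted_errors Character vector of rule ids to plant, from:
#'   `"name_rule"`, `"dup_name"`, `"well_rule"`, `"missing_buffer"`,
#'   `"buffer_every_5"`, `"holder_name_len"`, `"dup_position"`.
#' @param seed RNG seed (default 1), used for the holder UUID sequence.
#' @param proposal_id,saf_id Embedded user information.
#' @return A list with `plate_sheet`, `measurement_sheet` and `truth`
#'   (planted rule ids).
#' @export
make_sheets <- function(n_wells = 72L, planted_errors = character(0),
                        seed = 1L, proposal_id = "301111", saf_id = "312222") {
  known <- c("name_rule", "dup_name", "well_rule", "missing_buffer",
             "buffer_every_5", "holder_name_len", "dup_position")
  bad <- setdiff(planted_errors, known)
  if (length(bad)) {
    abort(paste("unknown planted rule id(s):", paste(bad, collapse = ", ")),
          class = "saxsqc_error_domain")
  }
  stopifnot(n_wells >= 1, n_wells <= 72)
  set.seed(seed)

  wells <- character(0); names_ <- character(0); brefs <- character(0)
  for (k in seq_len(n_wells)) {
    r <- (k - 1) %/% 9 + 1          # plate row 1..8
    col <- (k - 1) %% 9 + 1         # well column 1..9
    wells <- c(wells, paste0(LETTERS[r], col))
    if (col == 1) {
      names_ <- c(names_, sprintf("buf_%d_1", r)); brefs <- c(brefs, NA)
    } else if (col == 6) {
      names_ <- c(names_, sprintf("buf_%d_2", r)); brefs <- c(brefs, NA)
    } else {
      names_ <- c(names_, sprintf("smp_%d_%d", r, col))
      brefs <- c(brefs, sprintf("buf_%d_%d", r, if (col < 6) 1 else 2))
    }
  }
  plate <- tibble(well = wells, sample_name = names_,
                  volume = 30, buffer_ref = brefs,
                  mixing_sources = NA_character_)

  # matching measurement sheet (same mapping generate_transfer_protocol uses)
  rk <- well_row_index(plate$well)
  msheet <- tibble(
    holder_name = paste0("H", (rk - 1L) %/% 2L + 1L),
    position = as.integer(((rk - 1L) %% 2L) * 9L + well_col(plate$well)),
    sample_name = plate$sample_name,
    role = ifelse(is.na(plate$buffer_ref), "buffer", "sample"),
    buffer_ref = plate$buffer_ref
  )

  for (e in planted_errors) {
    switch(e,
      name_rule = {
        plate$sample_name[2] <- "bad name!"
        msheet$sample_name[2] <- "bad name!"
      },
      dup_name = {
        plate$sample_name[3] <- plate$sample_name[4]
        msheet$sample_name[3] <- msheet$sample_name[4]
      },
      well_rule = {
        plate$well[5] <- sub("[0-9]+$", "10", plate$well[5])
      },
      missing_buffer = {
        plate$buffer_ref[2] <- "no_such_buffer"
        msheet$buffer_ref[2] <- "no_such_buffer"
      },
      buffer_every_5 = {
        idx <- which(!is.na(plate$buffer_ref))[1:6]
        plate$buffer_ref[idx] <- plate$buffer_ref[idx[1]]
        msheet$buffer_ref[idx] <- msheet$buffer_ref[idx[1]]
      },
      holder_name_len = {
        msheet$holder_name[msheet$holder_name == "H1"] <- "HOLDER1"
      },
      dup_position = {
        msheet$position[2] <- msheet$position[3]
      })
  }

  list(plate_sheet = plate, measurement_sheet = msheet,
       truth = list(planted = planted_errors, proposal_id = proposal_id,
                    saf_id = saf_id))
}
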
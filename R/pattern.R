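#' Detector geometry
#'
#' Minimal flat-detector geometry for mapping pixels to scattering vector
#' magnitudes: q = (4 pi / lambda) sin(theta / 2) with
#' tan(theta) = r * pixel_size / distance, r the distance (in pixels) from
#' the beam center.
#'
#' @param wavelength X-ray wavelength in Angstrom (> 0).
#' @param distance Sample-detector distance in mm (> 0).
#' @param pixel_size Pixel edge in mm (> 0, square pixels).
#' @param center Beam center as fractional 0-based pixel coordinates
#'   `c(col, row)`.
#' @return An object of class `saxs_geometry`.
#' @examples
#' saxs_geometry(1.0, 3000, 0.172, center = c(480, 520))
#' @export
saxs_geometry <- function(wavelength, distance, pixel_size, center) {
  if (!all(is.finite(c(wavelength, distance, pixel_size))) ||
      wavelength <= 0 || distance <= 0 || pixel_size <= 0) {
    abort("wavelength, distance and pixel_size must be positive",
          class = "saxsqc_error_geometry")
  }
  stopifnot(length(center) == 2L, all(is.finite(center)))
  structure(
    list(wavelength = wavelength, distance = distance,
         pixel_size = pixel_size, center = as.numeric(center)),
    class = "saxs_geometry"
  )
}

#' @export
print.saxs_geometry <- function(x, ...) {
  cat(sprintf(
    "<saxs_geometry> lambda = %g A, distance = %g mm, pixel = %g mm, center = (%g, %g)\n",
    x$wavelength, x$distance, x$pixel_size, x$center[1], x$center[2]))
  invisible(x)
}

#' A 2-D detector pattern
#'
#' Bundles a counts image with its geometry and an optional exclusion mask.
#' Images follow R matrix convention: rows index the detector row (vertical),
#' columns the detector column (horizontal); pixel coordinates are 0-based
#' with q evaluated at pixel centers.
#'
#' @param image Numeric matrix of non-negative counts.
#' @param geometry A [saxs_geometry()].
#' @param mask Optional logical matrix, `TRUE` = exclude; same shape as
#'   `image`.
#' @param truth Optional list of planted ground truth (used by the synthetic
#'   generator).
#' @return An object of class `saxs_pattern`.
#' @export
saxs_pattern <- function(image, geometry, mask = NULL, truth = NULL) {
  stopifnot(is.matrix(image), inherits(geometry, "saxs_geometry"))
  if (any(image < 0, na.rm = TRUE)) {
    abort("image counts must be non-negative", class = "saxsqc_error_pattern")
  }
  if (!is.null(mask) && !identical(dim(mask), dim(image))) {
    abort("mask shape must equal image shape", class = "saxsqc_error_pattern")
  }
  structure(list(image = image, geometry = geometry, mask = mask,
                 truth = truth),
            class = "saxs_pattern")
}

#' @export
print.saxs_pattern <- function(x, ...) {
  cat(sprintf("<saxs_pattern> %d x %d pixels, total %g counts\n",
              nrow(x$image), ncol(x$image), sum(x$image)))
  print(x$geometry)
  invisible(x)
}

#' Per-pixel scattering-vector magnitudes
#'
#' @param geometry A [saxs_geometry()].
#' @param shape Image dimensions `c(nrow, ncol)`.
#' @return A numeric matrix of q values (1/Angstrom), evaluated at pixel
#'   centers.
#' @examples
#' g <- saxs_geometry(1, 1000, 1, center = c(50, 50))
#' qm <- compute_q_map(g, c(101, 101))
#' qm[51, 51] # beam center -> 0
#' @export
compute_q_map <- function(geometry, shape) {
  stopifnot(inherits(geometry, "saxs_geometry"), length(shape) == 2L)
  nr <- shape[1]; nc <- shape[2]
  col <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  row <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  r <- sqrt((col - geometry$center[1])^2 + (row - geometry$center[2])^2)
  theta <- atan(r * geometry$pixel_size / geometry$distance)
  (4 * pi / geometry$wavelength) * sin(theta / 2)
}

# Per-pixel azimuth in degrees in [0, 360): 0 = +column direction,
# 90 = "up" on the detector (decreasing row), measured counter-clockwise.
compute_azimuth_map <- function(geometry, shape) {
  nr <- shape[1]; nc <- shape[2]
  col <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  row <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  phi <- atan2(-(row - geometry$center[2]), col - geometry$center[1]) * 180 / pi
  (phi + 360) %% 360
}

#' Azimuthal average within a pie slice
#'
#' Averages unmasked pixel intensities whose azimuth lies within
#' `half_angle` degrees of `direction`, binned onto `q_grid`. Bin edges are
#' midpoints between consecutive grid values (extended symmetrically at the
#' ends), so the returned profile is evaluated at the supplied bin centers.
#'
#' @param pattern A [saxs_pattern()].
#' @param direction Slice azimuth in degrees (0 = +x, 90 = up,
#'   counter-clockwise).
#' @param half_angle Half opening angle of the slice in degrees, in (0, 90].
#' @param q_grid Ascending numeric vector of q bin centers.
#' @return A profile tibble with columns `q`, `intensity`, `sigma`
#'   (standard error of the bin mean), `n_pix` and `empty` (no pixels fell
#'   in the bin; such rows carry `NA` intensity).
#' @export
pie_slice_average <- function(pattern, direction, half_angle = 10, q_grid) {
  stopifnot(inherits(pattern, "saxs_pattern"))
  if (half_angle <= 0 || half_angle > 90) {
    abort("half_angle must be in (0, 90]", class = "saxsqc_error_domain")
  }
  if (is.unsorted(q_grid, strictly = TRUE)) {
    abort("q_grid must be strictly ascending", class = "saxsqc_error_domain")
  }
  qm <- compute_q_map(pattern$geometry, dim(pattern$image))
  am <- compute_azimuth_map(pattern$geometry, dim(pattern$image))
  dphi <- abs((am - direction + 180) %% 360 - 180)
  keep <- dphi <= half_angle
  if (!is.null(pattern$mask)) keep <- keep & !pattern$mask

  edges <- bin_edges(q_grid)
  idx <- findInterval(qm[keep], edges)
  ok <- idx >= 1L & idx <= length(q_grid)
  vals <- pattern$image[keep][ok]
  idx <- idx[ok]

  n_pix <- tabulate(idx, nbins = length(q_grid))
  if (all(n_pix == 0L)) {
    abort("no unmasked pixels fall in any q bin of the slice",
          class = "saxsqc_error_empty_slice")
  }
  sums <- vapply(split(vals, factor(idx, levels = seq_along(q_grid))),
                 sum, numeric(1))
  means <- ifelse(n_pix > 0, sums / n_pix, NA_real_)
  sds <- vapply(split(vals, factor(idx, levels = seq_along(q_grid))),
                function(v) if (length(v) > 1) sd(v) else 0, numeric(1))
  tibble(
    q = q_grid,
    intensity = as.numeric(means),
    sigma = ifelse(n_pix > 0, sds / sqrt(pmax(n_pix, 1)), NA_real_),
    n_pix = n_pix,
    empty = n_pix == 0L
  )
}

bin_edges <- function(centers) {
  n <- length(centers)
  if (n == 1L) return(c(centers - 0.5, centers + 0.5))
  mid <- (centers[-n] + centers[-1]) / 2
  c(centers[1] - (mid[1] - centers[1]), mid,
    centers[n] + (centers[n] - mid[n - 1]))
}

#' Write / read a detector pattern as TIFF plus YAML geometry sidecar
#'
#' The image is stored as 32-bit float TIFF (counts scaled to `[0, 1]` by
#' the recorded `scale` so the round trip is lossless for counts) and the
#' geometry in `<path>.yaml`.
#'
#' @param pattern A [saxs_pattern()].
#' @param path TIFF file path.
#' @return `path`, invisibly.
#' @export
write_pattern <- function(pattern, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required for TIFF I/O",
          class = "saxsqc_error_io")
  }
  scale <- max(pattern$image, 1)
  tiff::writeTIFF(pattern$image / scale, path, bits.per.sample = 32L)
  g <- pattern$geometry
  yaml::write_yaml(
    list(wavelength = g$wavelength, distance = g$distance,
         pixel_size = g$pixel_size, center = as.list(g$center),
         scale = scale),
    paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_pattern
#' @param geometry_path Optional sidecar path (default `<path>.yaml`).
#' @export
read_pattern <- function(path, geometry_path = paste0(path, ".yaml")) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required for TIFF I/O",
          class = "saxsqc_error_io")
  }
  img <- tiff::readTIFF(path)
  meta <- yaml::read_yaml(geometry_path)
  scale <- meta$scale %||% 1
  saxs_pattern(img * scale,
               saxs_geometry(meta$wavelength, meta$distance, meta$pixel_size,
                             unlist(meta$center)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
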
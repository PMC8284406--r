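#' @name sheets
#' @title Spreadsheet schemas for mail-in sample tracking
#' @description
#' Two tabular schemas drive the logistics layer.
#'
#' **Measurement sheet** (samples already in 18-position holders): columns
#' `holder_name` (at most 4 characters), `position` (1-18, unique within a
#' holder), `sample_name` (detector-safe: `[A-Za-z0-9_-]+`), `role`
#' (`"sample"` or `"buffer"`) and `buffer_ref` (for samples, the
#' `sample_name` of the paired buffer in the same holder). Validation
#' enriches the sheet with `proposal_id`, `saf_id` and a per-holder
#' `holder_uuid`.
#'
#' **Plate sheet** (samples in a 96-well plate): columns `well` (`A1`-`H12`),
#' `sample_name`, `volume` (microlitres), `buffer_ref` and optional
#' `mixing_sources` (a string like `"A10=5|A11=3"`: source well `=` transfer
#' volume, `|`-separated). Only wells in columns 1-9 are measured (they map
#' onto the two 9-position rows of a holder); columns 10-12 hold buffer or
#' chemical stocks used as mixing sources.
#'
#' Both sheets are read/written as CSV with [read_sheet()] / [write_sheet()].
NULL

DETECTOR_SAFE <- "^[A-Za-z0-9_-]+$"
WELL_RE <- "^[A-H](1[0-2]|[1-9])$"
HOLDER_POSITIONS <- 18L
WELLS_PER_ROW <- 9L
BUFFER_EVERY <- 5L
STORAGE_HOLDERS <- 20L

#' Read or write a logistics sheet (CSV)
#'
#' @param path CSV file path.
#' @return A tibble ([read_sheet()]) or `path` invisibly ([write_sheet()]).
#' @export
read_sheet <- function(path) {
  as_tibble(read.table(path, sep = ",", header = TRUE,
                       colClasses = "character", na.strings = c("", "NA")))
}

#' @rdname read_sheet
#' @param sheet A sheet tibble.
#' @export
write_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = ",", row.names = FALSE, na = "",
              quote = FALSE)
  invisible(path)
}

new_validation_report <- function(errors, warnings, sheet, extra = list()) {
  structure(c(list(valid = nrow(errors) == 0L, errors = errors,
                   warnings = warnings, sheet = sheet), extra),
            class = "saxs_validation")
}

#' @export
print.saxs_validation <- function(x, ...) {
  cat(sprintf("<saxs_validation> %s: %d error(s), %d warning(s)\n",
              if (x$valid) "PASS" else "FAIL",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors)) print(x$errors)
  invisible(x)
}

#' @export
tidy.saxs_validation <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$errors, severity = "error"),
    dplyr::mutate(x$warnings, severity = "warning"))
}

#' @export
glance.saxs_validation <- function(x, ...) {
  tibble(valid = x$valid, n_errors = nrow(x$errors),
         n_warnings = nrow(x$warnings), n_rows = nrow(x$sheet))
}

issue <- function(rule, location, message) {
  tibble(rule = rule, location = location, message = message)
}

no_issues <- function() {
  tibble(rule = character(0), location = character(0), message = character(0))
}

#' Validate a measurement sheet
#'
#' Checks the rules that would otherwise stop automated data collection:
#' detector-safe sample names, no duplicate names or positions within a
#' holder, every sample paired with a buffer in the same holder, at most
#' five samples per buffer measurement (drift of empty-cell scattering),
#' and holder names no longer than four characters. On success the sheet is
#' enriched with the user information (proposal and SAF numbers) and a
#' fresh UUID per holder; on failure the input sheet is returned unchanged.
#'
#' @param sheet Measurement-sheet tibble (see [sheets]).
#' @param proposal_id,saf_id User information embedded on success.
#' @param buffer_every Maximum samples per buffer measurement (default 5).
#' @param enforce_buffer_every Demote the buffer-frequency rule to a
#'   warning by setting this to `FALSE`.
#' @return A `saxs_validation` report: `valid`, `errors`, `warnings`
#'   (tibbles of `rule`, `location`, `message`) and `sheet` (enriched on
#'   success). Rules fired: `name_rule`, `dup_name`, `missing_buffer`,
#'   `buffer_every_5`, `holder_name_len`, `position_range`, `dup_position`,
#'   `role_rule`.
#' @export
validate_measurement_sheet <- function(sheet, proposal_id = NULL,
                                       saf_id = NULL,
                                       buffer_every = BUFFER_EVERY,
                                       enforce_buffer_every = TRUE) {
  required <- c("holder_name", "position", "sample_name", "role", "buffer_ref")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols)) {
    abort(paste("measurement sheet is missing columns:",
                paste(missing_cols, collapse = ", ")),
          class = "saxsqc_error_schema")
  }
  sheet <- as_tibble(sheet)
  sheet$position <- as.integer(sheet$position)
  errors <- no_issues()
  warnings <- no_issues()
  loc <- function(i) sprintf("row %d (%s/%s)", i, sheet$holder_name[i],
                             sheet$sample_name[i])

  for (i in seq_len(nrow(sheet))) {
    if (is.na(sheet$sample_name[i]) || !grepl(DETECTOR_SAFE, sheet$sample_name[i])) {
      errors <- dplyr::bind_rows(errors, issue("name_rule", loc(i),
        "sample name is not detector-safe ([A-Za-z0-9_-]+)"))
    }
    if (is.na(sheet$holder_name[i]) || nchar(sheet$holder_name[i]) > 4L ||
        nchar(sheet$holder_name[i]) == 0L) {
      errors <- dplyr::bind_rows(errors, issue("holder_name_len", loc(i),
        "holder name must be 1-4 characters"))
    }
    if (is.na(sheet$position[i]) || sheet$position[i] < 1L ||
        sheet$position[i] > HOLDER_POSITIONS) {
      errors <- dplyr::bind_rows(errors, issue("position_range", loc(i),
        sprintf("position must be 1-%d", HOLDER_POSITIONS)))
    }
    if (!sheet$role[i] %in% c("sample", "buffer")) {
      errors <- dplyr::bind_rows(errors, issue("role_rule", loc(i),
        "role must be 'sample' or 'buffer'"))
    }
  }

  for (h in unique(sheet$holder_name)) {
    rows <- sheet[sheet$holder_name %in% h, ]
    dup_n <- unique(rows$sample_name[duplicated(rows$sample_name)])
    for (d in dup_n) {
      errors <- dplyr::bind_rows(errors, issue("dup_name", sprintf("holder %s", h),
        sprintf("duplicate sample name '%s' within holder", d)))
    }
    dup_p <- unique(rows$position[duplicated(rows$position)])
    for (d in dup_p) {
      errors <- dplyr::bind_rows(errors, issue("dup_position", sprintf("holder %s", h),
        sprintf("position %d used more than once", d)))
    }
    buffers <- rows$sample_name[rows$role == "buffer"]
    samples <- rows[rows$role == "sample", ]
    for (i in seq_len(nrow(samples))) {
      if (is.na(samples$buffer_ref[i]) || !samples$buffer_ref[i] %in% buffers) {
        errors <- dplyr::bind_rows(errors,
          issue("missing_buffer", sprintf("holder %s/%s", h, samples$sample_name[i]),
                "sample has no resolvable buffer in its holder"))
      }
    }
    counts <- table(samples$buffer_ref[samples$buffer_ref %in% buffers])
    for (b in names(counts)[counts > buffer_every]) {
      it <- issue("buffer_every_5", sprintf("holder %s/buffer %s", h, b),
                  sprintf("%d samples reference one buffer (max %d): a new buffer measurement is required every %d samples",
                          counts[[b]], buffer_every, buffer_every))
      if (enforce_buffer_every) errors <- dplyr::bind_rows(errors, it)
      else warnings <- dplyr::bind_rows(warnings, it)
    }
  }

  if (nrow(errors) == 0L) {
    holders <- unique(sheet$holder_name)
    uuids <- setNames(random_uuid(length(holders)), holders)
    sheet$holder_uuid <- unname(uuids[sheet$holder_name])
    if (!is.null(proposal_id)) sheet$proposal_id <- as.character(proposal_id)
    if (!is.null(saf_id)) sheet$saf_id <- as.character(saf_id)
  }
  new_validation_report(errors, warnings, sheet)
}

#' Validate a 96-well plate sheet
#'
#' Enforces the plate conventions: measured wells (samples and their
#' buffers) only in columns 1-9, detector-safe unique names, resolvable
#' buffer references among measured wells, and resolvable mixing sources
#' anywhere on the plate. Also reports the holders and tip racks a
#' transfer run would need.
#'
#' @param sheet Plate-sheet tibble (see [sheets]).
#' @param tip_policy `"per_source_well"` (one tip per distinct source well,
#'   default) or `"per_step"` (a fresh tip for every aspirate).
#' @param rack_size Tips per rack (default 96).
#' @return A `saxs_validation` report with extra fields `holders_needed`,
#'   `tips_needed` and `tip_racks_needed`. Rules fired: `well_rule`,
#'   `name_rule`, `dup_name`, `missing_buffer`, `mixing_ref`,
#'   `volume_rule`, `no_samples`.
#' @export
validate_plate_sheet <- function(sheet, tip_policy = c("per_source_well", "per_step"),
                                 rack_size = 96L) {
  tip_policy <- match.arg(tip_policy)
  required <- c("well", "sample_name", "volume", "buffer_ref")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols)) {
    abort(paste("plate sheet is missing columns:",
                paste(missing_cols, collapse = ", ")),
          class = "saxsqc_error_schema")
  }
  sheet <- as_tibble(sheet)
  if (!"mixing_sources" %in% names(sheet)) sheet$mixing_sources <- NA_character_
  sheet$volume <- as.numeric(sheet$volume)
  errors <- no_issues()
  warnings <- no_issues()

  wc <- well_col(sheet$well)
  measured <- !is.na(sheet$well) & grepl(WELL_RE, sheet$well) &
    !is.na(wc) & wc <= WELLS_PER_ROW
  if (!any(measured)) {
    errors <- dplyr::bind_rows(errors,
      issue("no_samples", "plate", "no measured wells (columns 1-9) on the plate"))
  }

  for (i in seq_len(nrow(sheet))) {
    w <- sheet$well[i]
    if (is.na(w) || !grepl(WELL_RE, w)) {
      errors <- dplyr::bind_rows(errors, issue("well_rule", sprintf("row %d", i),
        sprintf("invalid well '%s'", w)))
      next
    }
    if (!is.na(sheet$sample_name[i]) && !grepl(DETECTOR_SAFE, sheet$sample_name[i])) {
      errors <- dplyr::bind_rows(errors, issue("name_rule", w,
        "sample name is not detector-safe ([A-Za-z0-9_-]+)"))
    }
    is_sample_like <- !is.na(sheet$buffer_ref[i])
    if (is_sample_like && well_col(w) > WELLS_PER_ROW) {
      errors <- dplyr::bind_rows(errors, issue("well_rule", w,
        sprintf("samples are restricted to columns 1-%d; columns %d-12 hold buffer/chemical stocks",
                WELLS_PER_ROW, WELLS_PER_ROW + 1L)))
    }
    if (measured[i] && (is.na(sheet$volume[i]) || sheet$volume[i] <= 0)) {
      errors <- dplyr::bind_rows(errors, issue("volume_rule", w,
        "measured wells need a positive volume"))
    }
    for (src in mixing_source_wells(sheet$mixing_sources[i])) {
      if (!src %in% sheet$well) {
        errors <- dplyr::bind_rows(errors, issue("mixing_ref", w,
          sprintf("mixing source well '%s' is not on the plate", src)))
      }
    }
  }

  dup <- unique(sheet$sample_name[measured][duplicated(sheet$sample_name[measured])])
  dup <- dup[!is.na(dup)]
  for (d in dup) {
    errors <- dplyr::bind_rows(errors, issue("dup_name", "plate",
      sprintf("duplicate sample name '%s' on plate", d)))
  }

  # buffers must live in the same row pair as their samples, because each
  # pair of plate rows fills one holder and background subtraction pairs
  # sample and buffer within a holder
  pair_of <- function(w) (well_row_index(w) - 1L) %/% 2L
  measured_names <- sheet$sample_name[measured]
  referenced <- sheet$buffer_ref[measured]
  for (i in which(measured)) {
    br <- sheet$buffer_ref[i]
    if (is.na(br)) {
      if (!sheet$sample_name[i] %in% referenced) {
        errors <- dplyr::bind_rows(errors, issue("missing_buffer", sheet$well[i],
          "measured well is neither a buffer (referenced by a sample) nor assigned a buffer_ref"))
      }
      next
    }
    j <- which(measured & sheet$sample_name == br)
    if (length(j) == 0L) {
      errors <- dplyr::bind_rows(errors, issue("missing_buffer", sheet$well[i],
        sprintf("buffer_ref '%s' does not name a measured well (columns 1-%d)",
                br, WELLS_PER_ROW)))
    } else if (all(pair_of(sheet$well[j]) != pair_of(sheet$well[i]))) {
      errors <- dplyr::bind_rows(errors, issue("missing_buffer", sheet$well[i],
        sprintf("buffer '%s' sits in a different plate-row pair (holder) than its sample", br)))
    }
  }
  buf_counts <- table(referenced[!is.na(referenced)])
  for (b in names(buf_counts)[buf_counts > BUFFER_EVERY]) {
    errors <- dplyr::bind_rows(errors, issue("buffer_every_5", sprintf("buffer %s", b),
      sprintf("%d samples reference one buffer (max %d)", buf_counts[[b]], BUFFER_EVERY)))
  }

  occupied_rows <- unique(substr(sheet$well[measured], 1, 1))
  holders_needed <- ceiling(length(occupied_rows) / 2)
  tips <- count_tips(sheet[measured, ], tip_policy)
  new_validation_report(errors, warnings, sheet,
                        extra = list(holders_needed = as.integer(holders_needed),
                                     tips_needed = tips,
                                     tip_racks_needed = as.integer(ceiling(tips / rack_size))))
}

well_col <- function(w) {
  suppressWarnings(as.integer(substr(w, 2, nchar(w))))
}

well_row_index <- function(w) {
  match(substr(w, 1, 1), LETTERS[1:8])
}

mixing_source_wells <- function(spec) {
  if (is.na(spec) || !nzchar(spec)) return(character(0))
  parts <- strsplit(spec, "|", fixed = TRUE)[[1]]
  vapply(strsplit(parts, "=", fixed = TRUE), `[[`, character(1), 1L)
}

mixing_source_volumes <- function(spec) {
  if (is.na(spec) || !nzchar(spec)) return(numeric(0))
  parts <- strsplit(spec, "|", fixed = TRUE)[[1]]
  vapply(strsplit(parts, "=", fixed = TRUE),
         function(x) as.numeric(x[2]), numeric(1))
}

count_tips <- function(measured_sheet, tip_policy) {
  n_steps <- 0L
  sources <- character(0)
  for (i in seq_len(nrow(measured_sheet))) {
    srcs <- mixing_source_wells(measured_sheet$mixing_sources[i])
    n_steps <- n_steps + length(srcs) + 1L
    sources <- c(sources, srcs, measured_sheet$well[i])
  }
  if (tip_policy == "per_step") n_steps else length(unique(sources))
}
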
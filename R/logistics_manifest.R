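STORAGE_SAMPLES <- 360L   # 20 holders x 18 positions

#' Compile the holder manifest for a collection run
#'
#' Before automated collection starts, every holder loaded in the storage
#' unit must resolve to exactly one owner (proposal/SAF) and measurement
#' sheet. The manifest groups holders by owner and enforces the storage
#' capacity of 20 holders / 360 samples.
#'
#' @param holder_uuids UUIDs of the holders loaded for the run.
#' @param registry A list of validated, enriched measurement sheets (each
#'   carrying `holder_uuid`, `proposal_id`, `saf_id` columns), e.g. the
#'   `sheet` field of [validate_measurement_sheet()] reports or the
#'   `measurement_sheet` of [generate_transfer_protocol()].
#' @param max_holders,max_samples Storage capacity (defaults 20 and 360).
#' @return A `saxs_manifest`: `holders` (tibble of holder_uuid, owner,
#'   holder_name, n_positions), `by_owner` (named list of holder tibbles)
#'   and `rows` (per-sample rows for the run).
#' @export
compile_manifest <- function(holder_uuids, registry,
                             max_holders = STORAGE_HOLDERS,
                             max_samples = STORAGE_SAMPLES) {
  if (anyDuplicated(holder_uuids)) {
    abort("duplicate holder UUID in the run list",
          class = "saxsqc_error_duplicate")
  }
  if (length(holder_uuids) > max_holders) {
    abort(sprintf("%d holders exceed the storage capacity of %d holders (%d samples)",
                  length(holder_uuids), max_holders, max_samples),
          class = "saxsqc_error_capacity")
  }
  all_rows <- dplyr::bind_rows(lapply(registry, function(s) {
    need <- c("holder_uuid", "proposal_id", "saf_id", "holder_name",
              "position", "sample_name", "role", "buffer_ref")
    miss <- setdiff(need, names(s))
    if (length(miss)) {
      abort(paste("registry sheet lacks columns:", paste(miss, collapse = ", ")),
            class = "saxsqc_error_schema")
    }
    s[need]
  }))
  if (nrow(all_rows) == 0L) {
    all_rows <- tibble(holder_uuid = character(0), proposal_id = character(0),
                       saf_id = character(0), holder_name = character(0),
                       position = integer(0), sample_name = character(0),
                       role = character(0), buffer_ref = character(0))
  }
  unknown <- setdiff(holder_uuids, all_rows$holder_uuid)
  if (length(unknown)) {
    abort(sprintf("sample information missing for holder(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "saxsqc_error_missing_information")
  }
  rows <- all_rows[all_rows$holder_uuid %in% holder_uuids, ]
  if (nrow(rows) > max_samples) {
    abort(sprintf("%d samples exceed the storage capacity of %d",
                  nrow(rows), max_samples),
          class = "saxsqc_error_capacity")
  }
  holders <- rows |>
    dplyr::group_by(.data$holder_uuid) |>
    dplyr::summarise(
      owner = paste0(dplyr::first(.data$proposal_id), "/",
                     dplyr::first(.data$saf_id)),
      holder_name = dplyr::first(.data$holder_name),
      n_positions = dplyr::n(), .groups = "drop")
  multi_owner <- rows |>
    dplyr::group_by(.data$holder_uuid) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$proposal_id, .data$saf_id),
                     .groups = "drop") |>
    dplyr::filter(.data$k > 1)
  if (nrow(multi_owner)) {
    abort(sprintf("holder(s) resolve to more than one owner: %s",
                  paste(multi_owner$holder_uuid, collapse = ", ")),
          class = "saxsqc_error_missing_information")
  }
  structure(
    list(holders = holders,
         by_owner = split(holders, holders$owner),
         rows = rows,
         capacity = list(max_holders = max_holders,
                         max_samples = max_samples)),
    class = "saxs_manifest"
  )
}

#' @export
print.saxs_manifest <- function(x, ...) {
  cat(sprintf("<saxs_manifest> %d holder(s), %d sample position(s), %d owner(s)\n",
              nrow(x$holders), nrow(x$rows), length(x$by_owner)))
  invisible(x)
}

#' @export
tidy.saxs_manifest <- function(x, ...) x$holders

#' @export
glance.saxs_manifest <- function(x, ...) {
  tibble(n_holders = nrow(x$holders), n_rows = nrow(x$rows),
         n_owners = length(x$by_owner),
         max_holders = x$capacity$max_holders,
         max_samples = x$capacity$max_samples)
}
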
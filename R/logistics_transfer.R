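DECK_SLOTS <- 12L
HOLDERS_PER_ADAPTOR <- 3L

#' Generate a plate-to-holder transfer protocol
#'
#' Maps the measured wells of a validated plate sheet onto 18-position
#' holders: plate rows are paired top-down, each pair filling one holder
#' (row `2k-1` columns 1-9 to positions 1-9, row `2k` to positions 10-18,
#' matching the holder's two 9-position rows). Mixing steps for a well
#' precede its final transfer, which carries the mix flag. The emitted
#' measurement sheet records the plate of origin per sample, embeds the
#' user information, and itself passes [validate_measurement_sheet()].
#'
#' @param sheet A plate-sheet tibble (will be validated first).
#' @param holder_uuids Character vector of holder UUIDs, at least as many
#'   as holders needed.
#' @param proposal_id,saf_id User information to embed.
#' @param plate_id Two-digit plate identifier (default `"01"`), used in the
#'   generated holder names `P<plate><A/B/...>`.
#' @param tip_policy Passed to [validate_plate_sheet()].
#' @return A `saxs_transfer_protocol`: `steps` (tibble of `step`,
#'   `source_well`, `holder_uuid`, `holder_index`, `position`, `volume`,
#'   `mix`), `holders` (holder_index / uuid / name map), `labware`
#'   (plates, adaptors, tip racks) and `measurement_sheet`.
#' @export
generate_transfer_protocol <- function(sheet, holder_uuids,
                                       proposal_id = NULL, saf_id = NULL,
                                       plate_id = "01",
                                       tip_policy = "per_source_well") {
  report <- validate_plate_sheet(sheet, tip_policy = tip_policy)
  if (!report$valid) {
    abort("plate sheet failed validation; fix the reported errors first",
          class = "saxsqc_error_invalid_sheet")
  }
  sheet <- report$sheet
  if (length(holder_uuids) < report$holders_needed) {
    abort(sprintf("need %d holder(s), only %d UUID(s) supplied",
                  report$holders_needed, length(holder_uuids)),
          class = "saxsqc_error_capacity")
  }
  if (anyDuplicated(holder_uuids)) {
    abort("holder UUIDs must be unique", class = "saxsqc_error_duplicate")
  }

  wc <- well_col(sheet$well)
  measured <- !is.na(wc) & wc <= WELLS_PER_ROW
  wells <- sheet[measured, ]
  ord <- order(well_row_index(wells$well), well_col(wells$well))
  wells <- wells[ord, ]

  rk <- well_row_index(wells$well)          # 1..8
  holder_index <- (rk - 1L) %/% 2L + 1L
  position <- ((rk - 1L) %% 2L) * WELLS_PER_ROW + well_col(wells$well)

  steps <- list()
  for (i in seq_len(nrow(wells))) {
    srcs <- mixing_source_wells(wells$mixing_sources[i])
    vols <- mixing_source_volumes(wells$mixing_sources[i])
    for (j in seq_along(srcs)) {
      steps[[length(steps) + 1L]] <- tibble(
        source_well = srcs[j], holder_index = holder_index[i],
        position = position[i], volume = vols[j], mix = FALSE)
    }
    steps[[length(steps) + 1L]] <- tibble(
      source_well = wells$well[i], holder_index = holder_index[i],
      position = position[i], volume = wells$volume[i],
      mix = length(srcs) > 0L)
  }
  steps <- dplyr::bind_rows(steps)
  steps$holder_uuid <- holder_uuids[steps$holder_index]
  steps <- dplyr::mutate(steps, step = dplyr::row_number(), .before = 1)

  n_holders <- max(holder_index)
  holders <- tibble(
    holder_index = seq_len(n_holders),
    holder_uuid = holder_uuids[seq_len(n_holders)],
    holder_name = paste0("P", plate_id, LETTERS[seq_len(n_holders)])
  )

  roles <- ifelse(wells$sample_name %in% wells$buffer_ref, "buffer", "sample")
  msheet <- tibble(
    holder_name = holders$holder_name[holder_index],
    position = as.integer(position),
    sample_name = wells$sample_name,
    role = roles,
    buffer_ref = wells$buffer_ref,
    plate_of_origin = paste0(plate_id, ":", wells$well)
  )
  check <- validate_measurement_sheet(msheet, proposal_id, saf_id)
  if (check$valid) {
    msheet <- check$sheet
    msheet$holder_uuid <- holders$holder_uuid[match(msheet$holder_name,
                                                    holders$holder_name)]
  }

  structure(
    list(steps = steps, holders = holders,
         labware = tibble(
           type = c("plate", "holder_adaptor", "tip_rack"),
           count = c(1L,
                     as.integer(ceiling(n_holders / HOLDERS_PER_ADAPTOR)),
                     report$tip_racks_needed)),
         measurement_sheet = msheet,
         measurement_sheet_valid = check$valid),
    class = "saxs_transfer_protocol"
  )
}

#' @export
print.saxs_transfer_protocol <- function(x, ...) {
  cat(sprintf("<saxs_transfer_protocol> %d steps onto %d holder(s)\n",
              nrow(x$steps), nrow(x$holders)))
  invisible(x)
}

#' @export
tidy.saxs_transfer_protocol <- function(x, ...) x$steps

#' @export
glance.saxs_transfer_protocol <- function(x, ...) {
  tibble(n_steps = nrow(x$steps), n_holders = nrow(x$holders),
         n_mix = sum(x$steps$mix),
         sheet_valid = x$measurement_sheet_valid)
}

#' Serialize / read a transfer protocol as JSON
#'
#' @param protocol A `saxs_transfer_protocol`.
#' @param path Output path.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(
    list(steps = protocol$steps, holders = protocol$holders,
         labware = protocol$labware,
         measurement_sheet = protocol$measurement_sheet),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plan the liquid-handler deck
#'
#' The deck takes 12 standard-plate-size labwares, shared between sample
#' plates, three-holder adaptors and tip racks. Returns the slot
#' allocation, or raises a capacity error with a feasible split into runs.
#'
#' @param n_plates,n_holders Non-negative counts for the run.
#' @param tip_racks_needed Tip racks required (e.g. from
#'   [validate_plate_sheet()]); defaults to the worst-case planning policy
#'   of [max_holders_per_run()] (3 tips per occupied well).
#' @param total_slots Deck capacity (default 12).
#' @return A `saxs_deck_layout`: tibble `slots` (slot, labware), counts,
#'   and `max_feasible_holders` for the given plates and tips.
#' @export
plan_deck <- function(n_plates, n_holders,
                      tip_racks_needed = 3L * n_plates,
                      total_slots = DECK_SLOTS) {
  stopifnot(n_plates >= 0, n_holders >= 0, tip_racks_needed >= 0)
  adaptors <- as.integer(ceiling(n_holders / HOLDERS_PER_ADAPTOR))
  used <- n_plates + adaptors + tip_racks_needed
  free_for_adaptors <- total_slots - n_plates - tip_racks_needed
  max_holders <- max(0L, as.integer(free_for_adaptors) * HOLDERS_PER_ADAPTOR)
  if (used > total_slots) {
    n_runs <- ceiling(n_holders / max(max_holders, HOLDERS_PER_ADAPTOR))
    abort(sprintf(
      "deck needs %d slots but only %d available; split into %d runs of at most %d holders",
      used, total_slots, n_runs, max_holders),
      class = "saxsqc_error_capacity")
  }
  slots <- tibble(
    slot = seq_len(used),
    labware = c(rep("plate", n_plates), rep("holder_adaptor", adaptors),
                rep("tip_rack", tip_racks_needed))
  )
  structure(list(slots = slots, n_plates = n_plates, n_holders = n_holders,
                 adaptors = adaptors, tip_racks = tip_racks_needed,
                 free_slots = total_slots - used,
                 max_feasible_holders = max_holders),
            class = "saxs_deck_layout")
}

#' @export
print.saxs_deck_layout <- function(x, ...) {
  cat(sprintf("<saxs_deck_layout> %d plate(s), %d holder(s) in %d adaptor(s), %d tip rack(s), %d free slot(s)\n",
              x$n_plates, x$n_holders, x$adaptors, x$tip_racks, x$free_slots))
  invisible(x)
}

#' Maximum holders per transfer run
#'
#' Worst-case deck arithmetic: every occupied well may need its own
#' transfer plus up to two mixing aspirates with fresh tips (3 tips per
#' well), so a full plate consumes 3 racks of 96. With `n_plates` plates
#' and their tip racks on the deck, the remaining slots take three-holder
#' adaptors.
#'
#' @param n_plates Plates on the deck (default 2, the most a run handles).
#' @param tips_per_well Planning tip budget per occupied well (default 3).
#' @param wells_per_plate Default 96.
#' @param rack_size Tips per rack (default 96).
#' @param total_slots Deck capacity (default 12).
#' @return Integer: the largest holder count that fits.
#' @export
max_holders_per_run <- function(n_plates = 2L, tips_per_well = 3L,
                                wells_per_plate = 96L, rack_size = 96L,
                                total_slots = DECK_SLOTS) {
  racks <- ceiling(n_plates * wells_per_plate * tips_per_well / rack_size)
  max(0L, as.integer((total_slots - n_plates - racks) * HOLDERS_PER_ADAPTOR))
}
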
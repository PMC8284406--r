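test_that("a minimal measurement sheet validates and gains a UUID", {
  sheet <- tibble::tibble(
    holder_name = "h1", position = 1:2,
    sample_name = c("bufA", "lys1"),
    role = c("buffer", "sample"), buffer_ref = c(NA, "bufA"))
  set.seed(7)
  r <- validate_measurement_sheet(sheet, proposal_id = "301111",
                                  saf_id = "312222")
  expect_true(r$valid)
  expect_match(r$sheet$holder_uuid[1],
               "^[0-9a-f]{8}-[0-9a-f]{4}-4[0-9a-f]{3}-[89ab][0-9a-f]{3}-[0-9a-f]{12}$")
  expect_equal(r$sheet$proposal_id[1], "301111")
  # re-validation is idempotent apart from the fresh UUID
  r2 <- validate_measurement_sheet(r$sheet[names(sheet)], "301111", "312222")
  expect_true(r2$valid)
  expect_equal(r2$sheet[names(sheet)], r$sheet[names(sheet)])
})

test_that("measurement-sheet rules catch the planted violations", {
  base <- tibble::tibble(
    holder_name = "h1",
    position = 1:7,
    sample_name = c("buf", paste0("s", 1:6)),
    role = c("buffer", rep("sample", 6)),
    buffer_ref = c(NA, rep("buf", 6)))
  # six samples on one buffer: a new buffer is required every five samples
  r <- validate_measurement_sheet(base)
  expect_false(r$valid)
  expect_equal(r$errors$rule, "buffer_every_5")
  # ... demotable to a warning
  r_w <- validate_measurement_sheet(base, enforce_buffer_every = FALSE)
  expect_true(r_w$valid)
  expect_equal(r_w$warnings$rule, "buffer_every_5")

  # holder name longer than four letters
  long <- dplyr::mutate(base[1:3, ], holder_name = "ABCDE")
  r2 <- validate_measurement_sheet(long)
  expect_true("holder_name_len" %in% r2$errors$rule)

  # duplicate names / positions within a holder; bad characters; bad role
  bad <- tibble::tibble(
    holder_name = "h1", position = c(1, 2, 2, 4),
    sample_name = c("buf", "a b", "x", "x"),
    role = c("buffer", "sample", "sample", "mystery"),
    buffer_ref = c(NA, "buf", "buf", "buf"))
  r3 <- validate_measurement_sheet(bad)
  expect_setequal(unique(r3$errors$rule),
                  c("name_rule", "dup_name", "dup_position", "role_rule"))

  # unresolvable buffer reference
  orphan <- dplyr::mutate(base[1:2, ], buffer_ref = c(NA, "nope"))
  r4 <- validate_measurement_sheet(orphan)
  expect_true("missing_buffer" %in% r4$errors$rule)
})

test_that("plate-sheet rules enforce the 9-of-12 well convention", {
  sheets <- make_sheets(n_wells = 36, seed = 2)
  r <- validate_plate_sheet(sheets$plate_sheet)
  expect_true(r$valid)
  expect_equal(r$holders_needed, 2L)   # 4 occupied rows, two rows per holder

  # a sample placed in column 10 breaks the well rule
  bad <- sheets$plate_sheet
  bad$well[2] <- "A10"
  r2 <- validate_plate_sheet(bad)
  expect_true("well_rule" %in% r2$errors$rule)

  # dangling mixing source
  bad2 <- sheets$plate_sheet
  bad2$mixing_sources[2] <- "H12=5"
  r3 <- validate_plate_sheet(bad2)
  expect_equal(r3$errors$rule, "mixing_ref")

  # an empty sheet is reported, not thrown
  expect_no_error(r4 <- validate_plate_sheet(sheets$plate_sheet[0, ]))
  expect_true("no_samples" %in% r4$errors$rule)
})

test_that("transfer protocol maps a full plate onto 4 holders", {
  sheets <- make_sheets(n_wells = 72, seed = 3)
  set.seed(11)
  uuids <- random_uuid(4)
  tp <- generate_transfer_protocol(sheets$plate_sheet, uuids,
                                   proposal_id = "301111", saf_id = "312222")
  expect_equal(nrow(tp$steps), 72L)
  expect_equal(nrow(tp$holders), 4L)
  # injective mapping: no holder position receives two wells
  expect_false(any(duplicated(tp$steps[c("holder_uuid", "position")])))
  expect_true(all(tp$steps$position >= 1 & tp$steps$position <= 18))
  # emitted measurement sheet passes validation
  expect_true(tp$measurement_sheet_valid)
  expect_true(all(c("holder_uuid", "proposal_id", "plate_of_origin") %in%
                    names(tp$measurement_sheet)))

  # row pairing: row A goes to positions 1-9, row B to 10-18 of holder 1
  rowA <- tp$steps[grepl("^A", tp$steps$source_well), ]
  rowB <- tp$steps[grepl("^B", tp$steps$source_well), ]
  expect_true(all(rowA$position <= 9) && all(rowA$holder_index == 1))
  expect_true(all(rowB$position >= 10) && all(rowB$holder_index == 1))
})

test_that("single-well and mixing transfers produce the expected steps", {
  plate <- tibble::tibble(
    well = c("A1", "A2", "A10", "A11"),
    sample_name = c("buf", "mix1", "stockA", "stockB"),
    volume = c(30, 20, 200, 200),
    buffer_ref = c(NA, "buf", NA, NA),
    mixing_sources = c(NA, "A10=5|A11=5", NA, NA))
  set.seed(1)
  tp <- generate_transfer_protocol(plate, random_uuid(1))
  expect_equal(nrow(tp$steps), 4L)   # buf + (2 mixing + 1 final) for mix1
  mix_steps <- tp$steps[tp$steps$position == 2, ]
  expect_equal(nrow(mix_steps), 3L)
  expect_equal(mix_steps$mix, c(FALSE, FALSE, TRUE))
  expect_equal(mix_steps$source_well, c("A10", "A11", "A2"))

  # insufficient holders is a capacity error
  sheets <- make_sheets(n_wells = 72, seed = 4)
  expect_error(generate_transfer_protocol(sheets$plate_sheet, random_uuid(3)),
               class = "saxsqc_error_capacity")
})

test_that("deck planning respects the 12-slot capacity", {
  # two full plates with worst-case tips: exactly 12 holders fit
  expect_equal(max_holders_per_run(n_plates = 2), 12L)
  d <- plan_deck(n_plates = 2, n_holders = 12, tip_racks_needed = 6)
  expect_equal(nrow(d$slots), 12L)
  expect_equal(d$free_slots, 0L)
  expect_error(plan_deck(n_plates = 2, n_holders = 13, tip_racks_needed = 6),
               class = "saxsqc_error_capacity")
  empty <- plan_deck(0, 0, 0)
  expect_equal(nrow(empty$slots), 0L)
})

test_that("holder manifests group by owner and enforce storage capacity", {
  mk <- function(h, prop, saf) tibble::tibble(
    holder_uuid = h, proposal_id = prop, saf_id = saf,
    holder_name = substr(h, 1, 4), position = 1L,
    sample_name = paste0("s", substr(h, 1, 4)), role = "sample",
    buffer_ref = "b")
  set.seed(2)
  u <- random_uuid(3)
  reg <- list(mk(u[1], "1", "10"), mk(u[2], "1", "10"), mk(u[3], "2", "20"))
  m <- compile_manifest(u, reg)
  expect_equal(length(m$by_owner), 2L)
  expect_equal(nrow(m$holders), 3L)
  expect_equal(glance(m)$max_samples, 360L)

  expect_error(compile_manifest(c(u, u[1]), reg),
               class = "saxsqc_error_duplicate")
  expect_error(compile_manifest(random_uuid(21), reg),
               class = "saxsqc_error_capacity")
  expect_error(compile_manifest(random_uuid(1), reg),
               class = "saxsqc_error_missing_information")
})

test_that("plate labels are deterministic and parse-invertible", {
  lab <- make_label_payload(301111, 312222, "01")
  p <- parse_label_payload(lab$payload)
  expect_equal(p$proposal_id, "301111")
  expect_equal(p$saf_id, "312222")
  expect_equal(p$plate_id, "01")
  expect_error(make_label_payload(301111, 312222, "1"),
               class = "saxsqc_error_format")
  expect_error(parse_label_payload("garbage"), class = "saxsqc_error_format")
  # seeded UUID generation reproduces the same sequence
  set.seed(99); a <- random_uuid(3)
  set.seed(99); b <- random_uuid(3)
  expect_identical(a, b)
})
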
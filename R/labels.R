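#' Seedable version-4 UUIDs
#'
#' UUIDs identify sample holders via their QR codes. These are standard v4
#' UUIDs whose random bits are drawn from R's RNG, so a fixed
#' [set.seed()] reproduces the sequence — which is what makes holder
#' tracking testable.
#'
#' @param n How many UUIDs.
#' @return Character vector of lower-case v4 UUIDs.
#' @examples
#' set.seed(1); random_uuid(2)
#' @export
random_uuid <- function(n = 1L) {
  vapply(seq_len(n), function(i) {
    h <- sample(c(0:9, letters[1:6]), 32, replace = TRUE)
    h[13] <- "4"                                  # version nibble
    h[17] <- sample(c("8", "9", "a", "b"), 1)     # variant nibble
    paste0(paste(h[1:8], collapse = ""), "-",
           paste(h[9:12], collapse = ""), "-",
           paste(h[13:16], collapse = ""), "-",
           paste(h[17:20], collapse = ""), "-",
           paste(h[21:32], collapse = ""))
  }, character(1))
}

#' Plate label text and QR payload
#'
#' Builds the label attached to a shipped 96-well plate: human-readable
#' text plus a machine-parsable payload (also the QR content) carrying the
#' proposal number, the SAF number and a two-digit plate identifier.
#'
#' @param proposal_id,saf_id Numeric identifiers (digits only).
#' @param plate_id Two-digit plate identifier, e.g. `"01"`.
#' @return A list with `text` (printable label) and `payload`
#'   (`parse_label_payload()`-invertible string).
#' @examples
#' make_label_payload(301111, 312222, "01")$payload
#' @export
make_label_payload <- function(proposal_id, saf_id, plate_id) {
  if (!grepl("^[0-9]+$", as.character(proposal_id)) ||
      !grepl("^[0-9]+$", as.character(saf_id))) {
    abort("proposal and SAF ids must be numeric", class = "saxsqc_error_format")
  }
  if (!grepl("^[0-9]{2}$", as.character(plate_id))) {
    abort("plate_id must be exactly two digits", class = "saxsqc_error_format")
  }
  payload <- sprintf("LIXPLATE;proposal=%s;saf=%s;plate=%s",
                     proposal_id, saf_id, plate_id)
  text <- sprintf("Proposal %s / SAF %s / Plate %s",
                  proposal_id, saf_id, plate_id)
  list(text = text, payload = payload)
}

#' @rdname make_label_payload
#' @param payload A payload string produced by [make_label_payload()].
#' @return For `parse_label_payload()`: a list with `proposal_id`, `saf_id`,
#'   `plate_id`.
#' @export
parse_label_payload <- function(payload) {
  m <- regmatches(payload,
    regexec("^LIXPLATE;proposal=([0-9]+);saf=([0-9]+);plate=([0-9]{2})$", payload))[[1]]
  if (length(m) != 4L) {
    abort("not a plate-label payload", class = "saxsqc_error_format")
  }
  list(proposal_id = m[2], saf_id = m[3], plate_id = m[4])
}
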
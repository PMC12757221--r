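#' @importFrom rlang %||% .data abort warn
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Round half away from zero at `digits` decimals (display convention for
# proportion tables; base round() is round-half-even).
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# Case-fold a raw drug name for matching: trim, drop trailing periods
# (FAERS verbatim names often end "DRUGNAME."), lower-case.
fold_drugname <- function(x) {
  tolower(stringr::str_remove(stringr::str_trim(x), "\\.+$"))
}

# An 8-digit string that parses as a real calendar date.
is_complete_date <- function(x) {
  ok <- !is.na(x) & stringr::str_detect(x, "^[0-9]{8}$")
  ok[ok] <- !is.na(as.Date(x[ok], format = "%Y%m%d"))
  ok
}

# 4- or 6-digit year / year-month fragments (FAERS partial dates).
is_partial_date <- function(x) {
  !is.na(x) & stringr::str_detect(x, "^[0-9]{4}([0-9]{2})?$")
}

as_date8 <- function(x) as.Date(x, format = "%Y%m%d")

date8 <- function(x) format(x, "%Y%m%d")

# Zero-pad numeric-looking ids to a common width so lexicographic max
# equals numeric max; non-numeric ids compared as-is.
pad_id <- function(x) {
  w <- max(nchar(x), 0L)
  stringr::str_pad(x, width = w, pad = "0")
}

# Long view of Primary Suspect exposures: one row per (report row,
# drug), on the normalized name with a case-folded raw-name fallback.
ps_exposure <- function(reports) {
  long <- reports |>
    mutate(.row = row_number()) |>
    select(".row", "drugs") |>
    tidyr::unnest("drugs")
  long <- long[long$role == "PS", ]
  distinct(tibble(
    row = long$.row,
    drug = coalesce(long$drugname_norm, fold_drugname(long$drugname_raw))
  ))
}

assert_flagged <- function(reports) {
  if (!"is_case" %in% names(reports)) {
    abort("`reports` must carry an `is_case` column; run `flag_cases()` first.")
  }
}
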
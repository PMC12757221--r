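#' Column schemas for FAERS quarterly ASCII tables
#'
#' FAERS quarters are distributed as "$"-delimited ASCII files, one per
#' table. Column dialects changed over the years; rather than sniffing,
#' the reader takes an explicit schema per table and ships the modern
#' (post-2014) column set as the default. A schema is the character
#' vector of columns the reader requires in the header; extra columns in
#' a file are kept and passed through.
#'
#' @param table_id One of `"DEMO"`, `"DRUG"`, `"REAC"`, `"THER"`,
#'   `"OUTC"`, `"INDI"`.
#' @return Character vector of required column names.
#' @examples
#' faers_schema("DEMO")
#' @export
faers_schema <- function(table_id) {
  schemas <- list(
    DEMO = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
             "age", "age_cod", "sex", "wt", "wt_cod", "reporter_country"),
    DRUG = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
    REAC = c("primaryid", "caseid", "pt"),
    THER = c("primaryid", "caseid", "dsg_drug_seq", "start_dt"),
    OUTC = c("primaryid", "caseid", "outc_cod"),
    INDI = c("primaryid", "caseid", "indi_drug_seq", "indi_pt")
  )
  table_id <- toupper(table_id)
  if (!table_id %in% names(schemas)) {
    abort(paste0("Unknown FAERS table id: ", table_id))
  }
  schemas[[table_id]]
}

#' Read one FAERS-style "$"-delimited ASCII table
#'
#' Splits each line on `"$"` (the FAERS delimiter; fields are never
#' quoted), maps empty fields to `NA`, and validates the header against
#' the table schema. Malformed lines (wrong field count) are skipped and
#' counted, never silently dropped: the per-file parse log is attached
#' as the `"faers_log"` attribute and retrievable with [parse_log()].
#'
#' @param path Path to the ASCII file.
#' @param table_id Table identifier (see [faers_schema()]).
#' @param schema Required columns; defaults to `faers_schema(table_id)`.
#' @param encoding File encoding; FAERS ships latin-1.
#' @return A tibble with one row per well-formed data line, all columns
#'   character, plus a `"faers_log"` attribute listing rows read,
#'   rows kept and rows skipped.
#' @examples
#' f <- tempfile()
#' writeLines(c("primaryid$caseid$pt", "1001$500$Hepatotoxicity"), f)
#' read_faers(f, "REAC")
#' @export
read_faers <- function(path, table_id, schema = NULL,
                       encoding = "latin1") {
  if (!file.exists(path)) {
    abort(paste0("Cannot read FAERS file: ", path))
  }
  schema <- schema %||% faers_schema(table_id)
  lines <- readr::read_lines(path, locale = readr::locale(encoding = encoding))
  if (length(lines) == 0) {
    abort(paste0("Empty FAERS file (no header line): ", path))
  }
  header <- stringr::str_split_1(lines[1], stringr::fixed("$"))
  missing_cols <- setdiff(schema, header)
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Header of ", path, " does not match the ", toupper(table_id),
      " schema; missing columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- stringr::str_split(body, stringr::fixed("$"))
  ok <- lengths(fields) == length(header)
  rows <- fields[ok]
  out <- if (length(rows) == 0) {
    as_tibble(stats::setNames(rep(list(character()), length(header)), header))
  } else {
    m <- matrix(unlist(rows), ncol = length(header), byrow = TRUE)
    colnames(m) <- header
    as_tibble(m)
  }
  out <- mutate(out, across(everything(), ~ ifelse(.x == "", NA_character_, .x)))
  log <- list(
    path = path, table_id = toupper(table_id),
    rows_read = length(body), rows_kept = sum(ok),
    rows_skipped = sum(!ok)
  )
  attr(out, "faers_log") <- log
  out
}

#' Retrieve the parse / processing log attached to a table
#'
#' Reader, de-duplication and normalization steps attach bookkeeping
#' (row counts, removed duplicates, unmapped drug names) as a
#' `"faers_log"` attribute so that no report is ever silently lost.
#'
#' @param x An object returned by [read_faers()], [deduplicate_reports()]
#'   or [normalize_drugs()].
#' @return The log (a list), or `NULL` if none is attached.
#' @export
parse_log <- function(x) attr(x, "faers_log")

#' Assemble analysis-ready case reports from raw FAERS tables
#'
#' Joins the DEMO backbone with per-report drugs (DRUG, with therapy
#' start dates from THER matched on drug sequence number), reaction
#' Preferred Terms (REAC) and outcome codes (OUTC), keyed throughout on
#' `primaryid`. Demographics are harmonized: ages with unit codes other
#' than years are converted (DEC x10, MON /12, WK /52, DY /365.25),
#' implausible ages (> 120 years) are set missing, weights are converted
#' to kilograms (LBS x0.453592, GMS /1000), and the reporter country is
#' upper-cased. Missing values stay `NA`; no sentinel codes are used.
#'
#' @param tables Named list with elements `demo`, `drug`, `reac` and
#'   optionally `ther`, `outc` — tibbles as returned by [read_faers()].
#' @return A tibble with one row per report version: `primaryid`,
#'   `caseid`, `fda_dt`, `event_dt`, `age_years`, `sex`, `weight_kg`,
#'   `country`, and list-columns `outcomes` (character vectors),
#'   `drugs` (tibbles of `drugname_raw`, `drugname_norm`, `atc_code`,
#'   `role`, `start_dt`) and `reaction_pts` (character vectors).
#' @export
assemble_reports <- function(tables) {
  need <- c("demo", "drug", "reac")
  if (!all(need %in% names(tables))) {
    abort(paste0("`tables` must contain at least: ", paste(need, collapse = ", ")))
  }
  tables <- purrr::map(tables, function(t) {
    attr(t, "faers_log") <- NULL
    t
  })
  demo <- tables$demo
  ther <- tables$ther %||%
    tibble(primaryid = character(), dsg_drug_seq = character(),
           start_dt = character())
  outc <- tables$outc %||% tibble(primaryid = character(), outc_cod = character())

  drugs <- tables$drug |>
    left_join(
      select(ther, "primaryid", drug_seq = "dsg_drug_seq", "start_dt"),
      by = c("primaryid", "drug_seq")
    ) |>
    transmute(
      .data$primaryid,
      drugname_raw = .data$drugname,
      drugname_norm = NA_character_,
      atc_code = NA_character_,
      role = .data$role_cod,
      start_dt = .data$start_dt
    ) |>
    tidyr::nest(drugs = -"primaryid")

  reacs <- tables$reac |>
    summarise(reaction_pts = list(.data$pt), .by = "primaryid")
  outcomes <- outc |>
    summarise(outcomes = list(.data$outc_cod), .by = "primaryid")

  demo |>
    transmute(
      .data$primaryid,
      .data$caseid,
      fda_dt = .data$fda_dt,
      event_dt = .data$event_dt,
      age_years = harmonize_age(.data$age, .data$age_cod),
      sex = ifelse(.data$sex %in% c("F", "M"), .data$sex, NA_character_),
      weight_kg = harmonize_weight(.data$wt, .data$wt_cod),
      country = toupper(.data$reporter_country)
    ) |>
    left_join(outcomes, by = "primaryid") |>
    left_join(drugs, by = "primaryid") |>
    left_join(reacs, by = "primaryid") |>
    mutate(
      outcomes = purrr::map(.data$outcomes, ~ .x %||% character()),
      reaction_pts = purrr::map(.data$reaction_pts, ~ .x %||% character()),
      drugs = purrr::map(.data$drugs, ~ .x %||% empty_drugs())
    ) |>
    arrange(.data$primaryid)
}

empty_drugs <- function() {
  tibble(drugname_raw = character(), drugname_norm = character(),
         atc_code = character(), role = character(), start_dt = character())
}

harmonize_age <- function(age, age_cod) {
  x <- suppressWarnings(as.numeric(age))
  cod <- toupper(ifelse(is.na(age_cod), "YR", age_cod))
  factor_tbl <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52,
                  DY = 1 / 365.25, HR = 1 / 8766)
  f <- unname(factor_tbl[cod])
  out <- x * ifelse(is.na(f), NA_real_, f)
  out[!is.na(out) & (out < 0 | out > 120)] <- NA_real_
  out
}

harmonize_weight <- function(wt, wt_cod) {
  x <- suppressWarnings(as.numeric(wt))
  cod <- toupper(ifelse(is.na(wt_cod), "KG", wt_cod))
  factor_tbl <- c(KG = 1, KGS = 1, LBS = 0.453592, GMS = 1e-3)
  f <- unname(factor_tbl[cod])
  out <- x * ifelse(is.na(f), NA_real_, f)
  out[!is.na(out) & out <= 0] <- NA_real_
  out
}

#' Remove duplicate versions of the same safety case
#'
#' FAERS carries multiple versions of the same case (identical `caseid`,
#' distinct `primaryid`). Following FDA de-duplication practice, the
#' latest version is retained: maximal FDA receipt date (`fda_dt`), ties
#' broken by maximal `primaryid` (zero-padded numeric comparison). The
#' number of removed versions is recorded in the attached log.
#'
#' @param reports Report tibble from [assemble_reports()].
#' @return The de-duplicated tibble (one row per `caseid`) with a
#'   `"faers_log"` attribute recording input, kept and removed counts.
#' @export
deduplicate_reports <- function(reports) {
  if (nrow(reports) == 0) {
    attr(reports, "faers_log") <- list(rows_in = 0L, rows_kept = 0L,
                                       duplicates_removed = 0L)
    return(reports)
  }
  out <- reports |>
    mutate(
      .date_key = ifelse(is.na(.data$fda_dt), "", .data$fda_dt),
      .id_key = pad_id(.data$primaryid)
    ) |>
    arrange(.data$caseid, .data$.date_key, .data$.id_key) |>
    slice_tail(n = 1, by = "caseid") |>
    select(-".date_key", -".id_key") |>
    arrange(.data$primaryid)
  attr(out, "faers_log") <- list(
    rows_in = nrow(reports), rows_kept = nrow(out),
    duplicates_removed = nrow(reports) - nrow(out)
  )
  out
}

#' Flag hepatotoxicity (or any target PT) cases
#'
#' A report is a case iff the target MedDRA Preferred Term appears among
#' its reaction PTs (case-insensitive exact match on the trimmed term —
#' a single PT, no MedDRA hierarchy expansion) AND the report carries at
#' least one Primary Suspect (PS) drug. Exposure attribution downstream
#' uses PS drugs only; reports whose only suspect roles are secondary or
#' concomitant are never cases.
#'
#' @param reports Report tibble.
#' @param target_pt Preferred Term string, e.g. `"hepatotoxicity"`.
#' @return `reports` with a logical `is_case` column appended.
#' @export
flag_cases <- function(reports, target_pt) {
  if (is.null(target_pt) || is.na(target_pt) || !nzchar(trimws(target_pt))) {
    abort("`target_pt` must be a non-empty Preferred Term string.")
  }
  pt <- tolower(trimws(target_pt))
  lens <- lengths(reports$reaction_pts)
  idx <- rep.int(seq_along(lens), lens)
  hit <- tolower(trimws(unlist(reports$reaction_pts))) == pt
  pt_hit <- logical(nrow(reports))
  pt_hit[unique(idx[hit])] <- TRUE
  has_ps <- logical(nrow(reports))
  has_ps[unique(ps_exposure(reports)$row)] <- TRUE
  mutate(reports, is_case = pt_hit & has_ps)
}

#' Normalize verbatim drug names to standard names and ATC codes
#'
#' FAERS drug names are free text; analysis requires mapping them to a
#' standardized name and Anatomical Therapeutic Chemical (ATC) code via
#' a user-supplied lookup table. Matching is case-insensitive on the
#' trimmed raw name with trailing periods stripped (so `"MERCAPTOPURINE."`
#' matches a `"mercaptopurine"` entry). Unmapped names are left `NA` and
#' tallied in the attached log — they are never guessed.
#'
#' @param reports Report tibble.
#' @param atc_table Data frame (or path to a CSV) with columns
#'   `drugname_raw`, `drugname_norm`, `atc_code`; raw names must be
#'   unique after case-folding.
#' @return `reports` with `drugname_norm` / `atc_code` filled inside the
#'   `drugs` list-column, plus a log of mapped and unmapped name counts.
#' @export
normalize_drugs <- function(reports, atc_table) {
  if (is.character(atc_table) && length(atc_table) == 1) {
    atc_table <- readr::read_csv(atc_table, show_col_types = FALSE)
  }
  need <- c("drugname_raw", "drugname_norm", "atc_code")
  if (!all(need %in% names(atc_table))) {
    abort(paste0("`atc_table` needs columns: ", paste(need, collapse = ", ")))
  }
  lut <- atc_table |>
    as_tibble() |>
    mutate(.key = fold_drugname(.data$drugname_raw)) |>
    distinct(.data$.key, .data$drugname_norm, .data$atc_code)
  if (anyDuplicated(lut$.key)) {
    dup <- lut$.key[duplicated(lut$.key)]
    abort(paste0("Conflicting ATC mappings for: ",
                 paste(unique(dup), collapse = ", ")))
  }
  long <- reports |>
    mutate(.row = row_number()) |>
    select(".row", "drugs") |>
    tidyr::unnest("drugs")
  key <- fold_drugname(long$drugname_raw)
  i <- match(key, lut$.key)
  long$drugname_norm <- lut$drugname_norm[i]
  long$atc_code <- lut$atc_code[i]
  nested <- tidyr::nest(long, drugs = -".row")
  out <- reports
  out$drugs[nested$.row] <- nested$drugs
  miss <- unique(key[is.na(i)])
  attr(out, "faers_log") <- list(
    n_unmapped_names = length(miss),
    unmapped_names = miss
  )
  out
}
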
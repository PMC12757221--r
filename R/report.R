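#' Demographic and outcome strata of case reports
#'
#' Tabulates de-duplicated case reports by gender, age group, weight
#' group, reporting region, outcome and receipt year, each stratum with
#' its count and proportion of the grand total. Conventions follow the
#' standard FAERS descriptive layout: age bins <18 / 18-64.9 / 65-85 /
#' >85 / Missing; weight bins <50 / 50-100 / >100 kg / Missing; outcome
#' codes mapped DE=Death, LT=Life-Threatening, DS=Disability,
#' HO=Hospitalization, remainder Other and Unknown, with ONE outcome
#' per report chosen by severity precedence DE > LT > DS > HO > other
#' (so the outcome strata are mutually exclusive and sum to 100%).
#' Display percentages are rounded half-up to 2 decimals.
#'
#' @param reports De-duplicated case report tibble.
#' @return Tibble `dimension`, `level`, `count`, `proportion`
#'   (fraction of grand total), `pct` (display percentage).
#' @export
demographics_table <- function(reports) {
  if (nrow(reports) == 0) {
    return(tibble(dimension = character(), level = character(),
                  count = integer(), proportion = numeric(),
                  pct = numeric()))
  }
  total <- nrow(reports)
  strat <- function(dimension, level) {
    tibble(level = level) |>
      count(.data$level, name = "count") |>
      mutate(dimension = dimension, .before = 1)
  }
  gender <- strat("gender", case_when(
    reports$sex == "F" ~ "Female",
    reports$sex == "M" ~ "Male",
    TRUE ~ "Missing"
  ))
  age <- strat("age", case_when(
    is.na(reports$age_years) ~ "Missing",
    reports$age_years < 18 ~ "<18",
    reports$age_years < 65 ~ "18-64.9",
    reports$age_years <= 85 ~ "65-85",
    TRUE ~ ">85"
  ))
  weight <- strat("weight", case_when(
    is.na(reports$weight_kg) ~ "Missing",
    reports$weight_kg < 50 ~ "<50 kg",
    reports$weight_kg <= 100 ~ "50-100 kg",
    TRUE ~ ">100 kg"
  ))
  region <- strat("region", ifelse(is.na(reports$country), "Missing",
                                   reports$country))
  outcome <- strat("outcome", purrr::map_chr(reports$outcomes, outcome_label))
  year <- strat("year", ifelse(is_complete_date(reports$fda_dt) |
                                 is_partial_date(reports$fda_dt),
                               substr(reports$fda_dt, 1, 4), "Missing"))
  bind_rows(gender, age, weight, region, outcome, year) |>
    mutate(
      proportion = .data$count / total,
      pct = round_half_up(100 * .data$proportion, 2)
    )
}

# One outcome per report by severity precedence DE > LT > DS > HO.
outcome_label <- function(codes) {
  if (any(codes == "DE")) return("Death")
  if (any(codes == "LT")) return("Life-Threatening")
  if (any(codes == "DS")) return("Disability")
  if (any(codes == "HO")) return("Hospitalization")
  "Other and Unknown"
}

#' Annual report counts
#'
#' Counts reports per calendar year of the FDA receipt date (the
#' de-duplication recency date); `use_event_date = TRUE` switches to
#' the adverse-event date. Reports without a usable year are tallied
#' under `NA`.
#'
#' @param reports Report tibble.
#' @param use_event_date Count by event year instead of receipt year.
#' @return Tibble `year` (integer, `NA` for missing), `n`.
#' @export
annual_counts <- function(reports, use_event_date = FALSE) {
  if (nrow(reports) == 0) return(tibble(year = integer(), n = integer()))
  dt <- if (use_event_date) reports$event_dt else reports$fda_dt
  usable <- is_complete_date(dt) | is_partial_date(dt)
  tibble(year = ifelse(usable, suppressWarnings(as.integer(substr(dt, 1, 4))),
                       NA_integer_)) |>
    count(.data$year) |>
    arrange(.data$year)
}

#' Run the full signal-detection pipeline
#'
#' Orchestrates every stage in order — read (or generate) the corpus,
#' de-duplicate, normalize drug names, flag cases, disproportionality
#' scoring and ranking, univariate screen, LASSO selection,
#' multivariate logistic model, time-to-onset summaries, and the
#' descriptive tables — with flow accounting at every stage (raw rows =
#' retained + excluded; any stage error aborts naming the stage). With
#' `out_dir` set, writes `signals.csv`, `forest.csv`, `tto.csv`,
#' `demographics.csv`, `annual.csv` and `run_log.json`; a rerun with
#' the same seed and config reproduces the bundle byte for byte.
#'
#' @param config List with either `synth` (a [synth_config()]) or
#'   `input_dir` (a directory of FAERS-style files); `target_pt`
#'   (default `"Hepatotoxicity"`); `atc_table` (data frame or CSV path;
#'   defaults to [synth_atc_table()] for synthetic corpora);
#'   `screen_min_cases` (default 100), `alpha` (default 0.01),
#'   `min_cases` (ROR ranking, default 3), `tto_min_n` (default 10),
#'   `seed` (LASSO folds, default the synth seed or 1).
#' @param out_dir Optional output directory for the CSV/JSON bundle.
#' @return List: `reports`, `signals`, `ranked`, `screen`, `selected`,
#'   `forest`, `tto`, `tto_by_drug`, `demographics`, `annual`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline failed at stage '", name, "': ",
                   conditionMessage(e)))
    })
  }
  log <- list(seed = config$seed %||% NA_integer_,
              package_version = as.character(utils::packageVersion("faersignal")))

  if (!is.null(config$synth)) {
    gen <- stage("generate", synth_generate(config$synth))
    raw <- gen$reports
    atc_table <- config$atc_table %||% synth_atc_table(config$synth)
    log$seed <- config$synth$seed
  } else if (!is.null(config$input_dir)) {
    raw <- stage("read", read_corpus(config$input_dir))
    atc_table <- config$atc_table %||%
      abort("`config$atc_table` is required for a file corpus.")
  } else {
    abort("`config` must name either `synth` or `input_dir`.")
  }
  log$raw_reports <- nrow(raw)

  dedup <- stage("deduplicate", deduplicate_reports(raw))
  log$deduplicated <- nrow(dedup)
  log$duplicates_removed <- parse_log(dedup)$duplicates_removed

  norm <- stage("normalize", normalize_drugs(dedup, atc_table))
  log$unmapped_drug_names <- parse_log(norm)$n_unmapped_names

  target_pt <- config$target_pt %||% "Hepatotoxicity"
  flagged <- stage("extract", flag_cases(norm, target_pt))
  log$cases <- sum(flagged$is_case)
  log$non_cases <- sum(!flagged$is_case)

  counts <- stage("contingency", contingency_counts(flagged))
  scores <- stage("signals", signal_scores(counts))
  ranked <- rank_signals(scores, min_cases = config$min_cases %||% 3)
  log$drugs_tabulated <- nrow(scores)
  log$drugs_ror_signal <- nrow(ranked)

  seed <- config$seed %||% log$seed %||% 1
  drugs_all <- scores$drug
  design <- stage("design", build_design(flagged, drugs_all))
  screen <- stage("screen", univariate_screen(
    design, drugs_all,
    min_cases = config$screen_min_cases %||% 100,
    alpha = config$alpha %||% 0.01
  ))
  screened <- screen$drug[screen$passes_screen]
  log$drugs_screened <- length(screened)

  if (length(screened) >= 2) {
    selected <- stage("lasso", lasso_select(design, screened, seed = seed))
  } else {
    selected <- screened
  }
  log$drugs_selected <- length(selected)
  forest <- if (length(selected) > 0) {
    stage("logistic", multivariate_logistic(
      design, selected, alpha = config$alpha %||% 0.01
    ))
  } else {
    tibble()
  }

  cases <- filter(flagged, .data$is_case)
  tto <- stage("tto", compute_tto(cases))
  log$tto_usable <- nrow(tto)
  log$tto_excluded <- sum(tto_exclusions(tto)$n)
  tto_by_drug <- tto_summary(tto, min_n = config$tto_min_n %||% 10)

  demo_tab <- stage("demographics", demographics_table(cases))
  annual <- stage("annual", annual_counts(cases))

  out <- list(
    reports = flagged, signals = scores, ranked = ranked, screen = screen,
    selected = selected, forest = forest, tto = tto,
    tto_by_drug = tto_by_drug, demographics = demo_tab, annual = annual,
    log = log
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(signal_table(ranked), file.path(out_dir, "signals.csv"))
    readr::write_csv(forest, file.path(out_dir, "forest.csv"))
    readr::write_csv(tto_by_drug, file.path(out_dir, "tto.csv"))
    readr::write_csv(demo_tab, file.path(out_dir, "demographics.csv"))
    readr::write_csv(annual, file.path(out_dir, "annual.csv"))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
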
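#' Define a synthetic drug profile
#'
#' A profile fixes the ground truth for one drug in a generated corpus:
#' how often it is the report's Primary Suspect drug, the reporting odds
#' ratio it should exhibit for the target event against all other
#' drugs, and the Weibull time-to-onset law for the event under that
#' drug.
#'
#' @param name Drug name (stored upper-case in raw fields).
#' @param atc_code ATC code string.
#' @param use_probability Probability a report has this drug as its PS
#'   drug; profiles' probabilities must sum to < 1, the remainder going
#'   to a background pool of null drugs.
#' @param true_ror Target reporting odds ratio for the event (1 = null).
#' @param tto_scale_alpha Weibull scale, days.
#' @param tto_shape_beta Weibull shape (dimensionless).
#' @return One-row tibble.
#' @export
synth_profile <- function(name, atc_code = NA_character_,
                          use_probability = 0.02, true_ror = 1,
                          tto_scale_alpha = 60, tto_shape_beta = 1) {
  stopifnot(use_probability > 0, use_probability < 1,
            true_ror > 0, tto_scale_alpha > 0, tto_shape_beta > 0)
  tibble(name = toupper(name), atc_code = atc_code,
         use_probability = use_probability, true_ror = true_ror,
         tto_scale_alpha = tto_scale_alpha, tto_shape_beta = tto_shape_beta)
}

#' Configure a synthetic FAERS corpus
#'
#' The generator emulates the statistical structure of spontaneous
#' reporting data: per-drug event odds calibrated to a target reporting
#' odds ratio, Weibull onset times, demographic strata with realistic
#' missingness, duplicate case versions, and partially or invalidly
#' entered dates. Defaults mirror the strata observed in published
#' FAERS hepatotoxicity tabulations (about 40% missing age, 80% missing
#' weight, a quarter missing sex, age mass concentrated in 18-64.9).
#'
#' @param n_reports Number of unique cases to generate (duplicate
#'   versions are added on top).
#' @param drug_profiles Tibble of [synth_profile()] rows.
#' @param baseline_event_rate Probability of the target event under a
#'   null drug.
#' @param n_background_drugs Size of the null background drug pool that
#'   absorbs reports not assigned a profile drug.
#' @param background_tto `c(alpha, beta)` Weibull onset law for
#'   background drugs.
#' @param event_pt Preferred Term string injected for events.
#' @param sex_probs,age_bins,weight_lnorm Demographic generators: sex
#'   probabilities (`F`, `M`); age bin mixture (list of `probs` and
#'   `ranges`); lognormal `c(meanlog, sdlog)` for weight in kg.
#' @param missingness Named rates for `age`, `sex`, `weight`, `country`.
#' @param duplicate_fraction Fraction of cases that also carry an older
#'   report version (same `caseid`, earlier receipt date).
#' @param invalid_date_fraction Fraction of reports whose dates are
#'   corrupted (missing, partial, invalid, or reversed interval).
#' @param outcome_probs Probabilities of outcome codes given case:
#'   `DE`, `LT`, `HO`, `DS` (remainder "O"); scaled down for non-cases.
#' @param fatal_short_onset_or Odds multiplier on death for cases with
#'   onset within 30 days (1 = outcomes independent of onset timing).
#' @param year_range Receipt-year span, or use `yearly_volumes`.
#' @param yearly_volumes Optional named integer vector of exact report
#'   counts per receipt year; overrides `n_reports` and `year_range`.
#' @param seed Mandatory integer seed: a fixed seed yields a
#'   byte-identical corpus.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(n_reports = 10000,
                         drug_profiles = synth_profile("EXAMPLODRUG", "L01XX99",
                                                       0.05, 5, 50, 0.9),
                         baseline_event_rate = 0.01,
                         n_background_drugs = 20,
                         background_tto = c(60, 1),
                         event_pt = "Hepatotoxicity",
                         sex_probs = c(F = 0.55, M = 0.45),
                         age_bins = list(
                           probs = c(0.06, 0.66, 0.25, 0.03),
                           ranges = list(c(1, 17.9), c(18, 64.9),
                                         c(65, 85), c(85.1, 99))
                         ),
                         weight_lnorm = c(log(72), 0.25),
                         missingness = c(age = 0.40, sex = 0.26,
                                         weight = 0.82, country = 0.10),
                         duplicate_fraction = 0.10,
                         invalid_date_fraction = 0.03,
                         outcome_probs = c(DE = 0.105, LT = 0.045,
                                           HO = 0.17, DS = 0.005),
                         fatal_short_onset_or = 1,
                         year_range = c(2015, 2023),
                         yearly_volumes = NULL,
                         seed = 1) {
  cfg <- list(
    n_reports = as.integer(n_reports), drug_profiles = drug_profiles,
    baseline_event_rate = baseline_event_rate,
    n_background_drugs = as.integer(n_background_drugs),
    background_tto = background_tto, event_pt = event_pt,
    sex_probs = sex_probs, age_bins = age_bins,
    weight_lnorm = weight_lnorm, missingness = missingness,
    duplicate_fraction = duplicate_fraction,
    invalid_date_fraction = invalid_date_fraction,
    outcome_probs = outcome_probs,
    fatal_short_onset_or = fatal_short_onset_or,
    year_range = year_range, yearly_volumes = yearly_volumes,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  p <- cfg$drug_profiles
  probs <- c(cfg$baseline_event_rate, cfg$duplicate_fraction,
             cfg$invalid_date_fraction, cfg$missingness, cfg$outcome_probs)
  if (any(probs < 0 | probs > 1)) abort("All rates must lie in [0, 1].")
  if (sum(p$use_probability) >= 1) {
    abort("Profile use probabilities must sum to < 1.")
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) abort("A seed is mandatory.")
  # Odds calibration must give a valid probability for every profile.
  p0 <- cfg$baseline_event_rate
  odds <- p$true_ror * p0 / (1 - p0)
  pe <- odds / (1 + odds)
  if (any(!is.finite(pe) | pe <= 0 | pe >= 1)) {
    abort("Infeasible true_ror / baseline_event_rate combination.")
  }
  invisible(cfg)
}

#' Generate a synthetic FAERS-structured corpus with known ground truth
#'
#' Each report draws one Primary Suspect drug (a profile drug by its
#' `use_probability`, otherwise a background null drug). The target
#' event is assigned with per-drug probability `p_d` solving
#' `p_d / (1 - p_d) = true_ror * p_0 / (1 - p_0)` against the baseline
#' rate `p_0`, so the population reporting odds ratio of each profile
#' drug against all other drugs equals its `true_ror`. Event reports
#' get a therapy start date and an event date whose difference is a
#' Weibull draw from the drug's onset law, rounded up to whole days
#' with a floor of one day. Configured fractions of duplicate case
#' versions, missing demographics and corrupted dates are then
#' injected. Every injected quantity is recorded in the truth ledger.
#'
#' @param config A [synth_config()].
#' @return List with `reports` (same shape as [assemble_reports()]
#'   output, duplicate versions included) and `truth` (a list: per-drug
#'   ledger tibble, per-report assignments, totals).
#' @export
synth_generate <- function(config) {
  validate_synth_config(config)
  withr::with_seed(config$seed, synth_generate_impl(config))
}

synth_generate_impl <- function(cfg) {
  profiles <- cfg$drug_profiles
  bg_names <- sprintf("BACKGROUNDDRUG%02d", seq_len(cfg$n_background_drugs))

  if (!is.null(cfg$yearly_volumes)) {
    years <- rep(as.integer(names(cfg$yearly_volumes)),
                 times = as.integer(cfg$yearly_volumes))
    n <- length(years)
  } else {
    n <- cfg$n_reports
    years <- sample(seq(cfg$year_range[1], cfg$year_range[2]), n, replace = TRUE)
  }

  # --- drug assignment and event calibration -------------------------
  pool <- c(profiles$name, bg_names)
  bg_prob <- (1 - sum(profiles$use_probability)) / length(bg_names)
  drug_prob <- c(profiles$use_probability, rep(bg_prob, length(bg_names)))
  drug_ix <- sample.int(length(pool), n, replace = TRUE, prob = drug_prob)
  drug <- pool[drug_ix]

  p0 <- cfg$baseline_event_rate
  odds <- profiles$true_ror * p0 / (1 - p0)
  p_event_by_drug <- c(odds / (1 + odds), rep(p0, length(bg_names)))
  is_event <- stats::runif(n) < p_event_by_drug[drug_ix]

  # --- onset times ---------------------------------------------------
  alpha <- c(profiles$tto_scale_alpha, rep(cfg$background_tto[1], length(bg_names)))
  beta <- c(profiles$tto_shape_beta, rep(cfg$background_tto[2], length(bg_names)))
  onset <- pmax(1, ceiling(stats::rweibull(n, shape = beta[drug_ix],
                                           scale = alpha[drug_ix])))

  # --- dates ---------------------------------------------------------
  year_start <- as.Date(sprintf("%d-01-01", years))
  fda_date <- year_start + sample.int(365, n, replace = TRUE) - 1L
  lag <- sample(10:120, n, replace = TRUE)
  event_date <- fda_date - lag
  start_date <- event_date - onset

  # --- demographics --------------------------------------------------
  sexes <- sample(names(cfg$sex_probs), n, replace = TRUE,
                  prob = cfg$sex_probs)
  bin <- sample.int(length(cfg$age_bins$probs), n, replace = TRUE,
                    prob = cfg$age_bins$probs)
  lo <- purrr::map_dbl(cfg$age_bins$ranges, 1)[bin]
  hi <- purrr::map_dbl(cfg$age_bins$ranges, 2)[bin]
  ages <- round(stats::runif(n, lo, hi), 1)
  weights <- round(stats::rlnorm(n, cfg$weight_lnorm[1], cfg$weight_lnorm[2]), 1)
  countries <- sample(
    c("US", "CA", "IT", "ES", "DE", "FR", "GB", "JP", "CN", "BR"),
    n, replace = TRUE,
    prob = c(0.19, 0.15, 0.09, 0.08, 0.06, 0.06, 0.05, 0.05, 0.04, 0.23)
  )
  miss <- cfg$missingness
  ages[stats::runif(n) < miss[["age"]]] <- NA_real_
  sexes[stats::runif(n) < miss[["sex"]]] <- NA_character_
  weights[stats::runif(n) < miss[["weight"]]] <- NA_real_
  countries[stats::runif(n) < miss[["country"]]] <- NA_character_

  # --- outcomes (one primary code + occasional extra HO) -------------
  op <- cfg$outcome_probs
  p_de <- ifelse(is_event & onset <= 30,
                 plogis(qlogis(op[["DE"]]) + log(cfg$fatal_short_onset_or)),
                 op[["DE"]])
  severity_scale <- ifelse(is_event, 1, 0.4)
  u <- stats::runif(n)
  cum1 <- p_de * severity_scale
  cum2 <- cum1 + op[["LT"]] * severity_scale
  cum3 <- cum2 + op[["HO"]] * severity_scale
  cum4 <- cum3 + op[["DS"]] * severity_scale
  primary_outc <- dplyr::case_when(
    u < cum1 ~ "DE", u < cum2 ~ "LT", u < cum3 ~ "HO",
    u < cum4 ~ "DS", TRUE ~ "OT"
  )
  extra_ho <- stats::runif(n) < 0.05 & primary_outc != "HO"
  outcomes <- purrr::map2(primary_outc, extra_ho,
                          ~ if (.y) c(.x, "HO") else .x)

  # --- reaction PTs --------------------------------------------------
  other_pts <- c("Nausea", "Rash", "Fatigue", "Pyrexia", "Anaemia",
                 "Diarrhoea", "Headache", "Vomiting")
  base_pt <- sample(other_pts, n, replace = TRUE)
  second_pt <- stats::runif(n) < 0.3
  reaction_pts <- purrr::pmap(
    list(is_event, base_pt, second_pt),
    function(ev, bp, sp) {
      if (ev) c(cfg$event_pt, if (sp) bp) else c(bp, if (sp) "Pruritus")
    }
  )

  # --- date corruption ------------------------------------------------
  start_dt <- date8(start_date)
  event_dt <- date8(event_date)
  n_bad <- floor(cfg$invalid_date_fraction * n)
  bad_ix <- if (n_bad > 0) sample.int(n, n_bad) else integer()
  bad_kind <- sample(c("missing", "partial", "invalid", "negative"),
                     n_bad, replace = TRUE)
  for (k in seq_along(bad_ix)) {
    i <- bad_ix[k]
    switch(bad_kind[k],
      missing = { start_dt[i] <- NA_character_ },
      partial = { event_dt[i] <- substr(event_dt[i], 1, 6) },
      invalid = { event_dt[i] <- paste0(substr(event_dt[i], 1, 4), "1345") },
      negative = {
        tmp <- start_dt[i]; start_dt[i] <- event_dt[i]; event_dt[i] <- tmp
      }
    )
  }

  # --- assemble current versions -------------------------------------
  caseid <- sprintf("%07d", seq_len(n))
  noisy <- stats::runif(n) < 0.10
  raw_name <- ifelse(noisy, paste0(drug, "."), drug)
  atc_pool <- c(stats::setNames(profiles$atc_code, profiles$name),
                stats::setNames(rep(NA_character_, length(bg_names)), bg_names))

  reports <- tibble(
    primaryid = paste0(caseid, "2"),
    caseid = caseid,
    fda_dt = date8(fda_date),
    event_dt = event_dt,
    age_years = ages,
    sex = sexes,
    weight_kg = weights,
    country = countries,
    outcomes = outcomes,
    drugs = purrr::map2(raw_name, start_dt, function(nm, sd) {
      vctrs::new_data_frame(
        list(drugname_raw = nm, drugname_norm = NA_character_,
             atc_code = NA_character_, role = "PS", start_dt = sd),
        n = 1L, class = c("tbl_df", "tbl")
      )
    }),
    reaction_pts = reaction_pts
  )

  # --- duplicate (older) versions ------------------------------------
  n_dup <- floor(cfg$duplicate_fraction * n)
  dup_ix <- if (n_dup > 0) sample.int(n, n_dup) else integer()
  dups <- reports[dup_ix, ] |>
    mutate(
      primaryid = paste0(.data$caseid, "1"),
      fda_dt = date8(as_date8(.data$fda_dt) - 90),
      weight_kg = NA_real_
    )
  all_reports <- bind_rows(reports, dups) |> arrange(.data$primaryid)

  # --- truth ledger ---------------------------------------------------
  per_drug <- tibble(drug = drug, is_event = is_event) |>
    summarise(n_reports = n(), n_events = sum(.data$is_event), .by = "drug")
  ledger <- tibble(
    drug = pool,
    atc_code = unname(atc_pool[pool]),
    kind = c(rep("profile", nrow(profiles)), rep("background", length(bg_names))),
    true_ror = c(profiles$true_ror, rep(1, length(bg_names))),
    p_event = p_event_by_drug,
    tto_alpha = alpha, tto_beta = beta
  ) |>
    left_join(per_drug, by = "drug") |>
    mutate(across(c("n_reports", "n_events"), ~ tidyr::replace_na(.x, 0L)))

  truth <- list(
    drugs = ledger,
    assignments = tibble(caseid = caseid, drug = drug, is_event = is_event,
                         onset_days = onset, outcome = primary_outc,
                         date_corrupted = seq_len(n) %in% bad_ix),
    n_unique_cases = n,
    n_raw_reports = nrow(all_reports),
    n_duplicates = n_dup,
    n_corrupted_dates = n_bad,
    n_cases = sum(is_event),
    event_pt = cfg$event_pt,
    seed = cfg$seed
  )
  list(reports = all_reports, truth = truth)
}

#' Build the drug-name to ATC lookup implied by a synth config
#'
#' Covers every profile and background drug name the generator can
#' emit, so a generated corpus normalizes with zero unmapped names.
#'
#' @param config A [synth_config()].
#' @return Tibble with `drugname_raw`, `drugname_norm`, `atc_code`.
#' @export
synth_atc_table <- function(config) {
  p <- config$drug_profiles
  bg <- sprintf("BACKGROUNDDRUG%02d", seq_len(config$n_background_drugs))
  tibble(
    drugname_raw = c(p$name, bg),
    drugname_norm = tolower(c(p$name, bg)),
    atc_code = c(p$atc_code, rep(NA_character_, length(bg)))
  )
}

#' Write a report tibble out as FAERS-style "$"-delimited ASCII files
#'
#' Emits `demo.txt`, `drug.txt`, `reac.txt`, `ther.txt` and `outc.txt`
#' in the dialect [read_faers()] consumes, so that a generated corpus
#' round-trips exactly through the reader and [assemble_reports()].
#'
#' @param reports Report tibble (e.g. from [synth_generate()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_corpus <- function(reports, out_dir) {
  if (nrow(reports) == 0) abort("`reports` is empty; nothing to write.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(paste0("Cannot create directory: ", out_dir))

  fmt_num <- function(x) ifelse(is.na(x), NA_character_,
                                format(x, trim = TRUE, scientific = FALSE))
  demo <- reports |>
    transmute(
      .data$primaryid, .data$caseid,
      caseversion = stringr::str_sub(.data$primaryid, -1),
      .data$fda_dt, .data$event_dt,
      age = fmt_num(.data$age_years),
      age_cod = ifelse(is.na(.data$age_years), NA_character_, "YR"),
      .data$sex,
      wt = fmt_num(.data$weight_kg),
      wt_cod = ifelse(is.na(.data$weight_kg), NA_character_, "KG"),
      reporter_country = .data$country
    )
  drug <- reports |>
    select("primaryid", "caseid", "drugs") |>
    mutate(drugs = purrr::map(.data$drugs, ~ mutate(.x, drug_seq = as.character(row_number())))) |>
    tidyr::unnest("drugs") |>
    transmute(.data$primaryid, .data$caseid,
              .data$drug_seq, role_cod = .data$role,
              drugname = .data$drugname_raw)
  ther <- reports |>
    select("primaryid", "caseid", "drugs") |>
    mutate(drugs = purrr::map(.data$drugs, ~ mutate(.x, dsg_drug_seq = as.character(row_number())))) |>
    tidyr::unnest("drugs") |>
    filter(!is.na(.data$start_dt)) |>
    transmute(.data$primaryid, .data$caseid,
              .data$dsg_drug_seq, .data$start_dt)
  reac <- reports |>
    select("primaryid", "caseid", "reaction_pts") |>
    tidyr::unnest("reaction_pts") |>
    transmute(.data$primaryid, .data$caseid, pt = .data$reaction_pts)
  outc <- reports |>
    select("primaryid", "caseid", "outcomes") |>
    tidyr::unnest("outcomes") |>
    transmute(.data$primaryid, .data$caseid, outc_cod = .data$outcomes)

  paths <- c(
    demo = file.path(out_dir, "demo.txt"),
    drug = file.path(out_dir, "drug.txt"),
    reac = file.path(out_dir, "reac.txt"),
    ther = file.path(out_dir, "ther.txt"),
    outc = file.path(out_dir, "outc.txt")
  )
  readr::write_delim(demo, paths[["demo"]], delim = "$", na = "")
  readr::write_delim(drug, paths[["drug"]], delim = "$", na = "")
  readr::write_delim(reac, paths[["reac"]], delim = "$", na = "")
  readr::write_delim(ther, paths[["ther"]], delim = "$", na = "")
  readr::write_delim(outc, paths[["outc"]], delim = "$", na = "")
  invisible(paths)
}

#' Read a written corpus back into a report tibble
#'
#' Convenience wrapper: [read_faers()] on the five files written by
#' [write_corpus()], then [assemble_reports()].
#'
#' @param dir Directory holding `demo.txt` etc.
#' @return Report tibble.
#' @export
read_corpus <- function(dir) {
  assemble_reports(list(
    demo = read_faers(file.path(dir, "demo.txt"), "DEMO"),
    drug = read_faers(file.path(dir, "drug.txt"), "DRUG"),
    reac = read_faers(file.path(dir, "reac.txt"), "REAC"),
    ther = read_faers(file.path(dir, "ther.txt"), "THER"),
    outc = read_faers(file.path(dir, "outc.txt"), "OUTC")
  ))
}
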
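# Hand-built report rows and small shared corpora for the tests.

make_drug <- function(name, role = "PS", start_dt = NA_character_,
                      norm = NA_character_, atc = NA_character_) {
  tibble::tibble(drugname_raw = name, drugname_norm = norm,
                 atc_code = atc, role = role, start_dt = start_dt)
}

make_report <- function(primaryid, caseid = primaryid, fda_dt = "20200101",
                        event_dt = NA_character_, age_years = NA_real_,
                        sex = NA_character_, weight_kg = NA_real_,
                        country = NA_character_, outcomes = character(),
                        drugs = make_drug("DRUGX"), pts = "Nausea") {
  tibble::tibble(
    primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
    event_dt = event_dt, age_years = age_years, sex = sex,
    weight_kg = weight_kg, country = country,
    outcomes = list(outcomes), drugs = list(drugs),
    reaction_pts = list(pts)
  )
}

extdata <- function(file) {
  system.file("extdata", file, package = "faersignal", mustWork = TRUE)
}

# Expand the published strata counts into a case-report tibble: each
# dimension is assigned independently (marginals are all the published
# table constrains), with representative values inside each bin.
strata_corpus <- function() {
  counts <- readr::read_csv(extdata("hepatotox_demographics.csv"),
                            show_col_types = FALSE)
  pick <- function(dim) dplyr::filter(counts, dimension == dim)
  expand <- function(values, n) rep(values, times = n)
  g <- pick("gender"); a <- pick("age"); w <- pick("weight")
  r <- pick("region"); o <- pick("outcome")
  total <- sum(g$count)
  sex <- expand(c(Female = "F", Male = "M", Missing = NA)[g$level], g$count)
  age_val <- c("<18" = 10, ">85" = 90, "18-64.9" = 40, "65-85" = 70,
               "Missing" = NA)
  age <- expand(age_val[a$level], a$count)
  wt_val <- c("<50 kg" = 45, ">100 kg" = 110, "50-100 kg" = 75,
              "Missing" = NA)
  wt <- expand(wt_val[w$level], w$count)
  country <- c(expand(r$level, r$count), rep(NA, total - sum(r$count)))
  outc_val <- list("Death" = "DE", "Disability" = "DS",
                   "Hospitalization" = "HO", "Life-Threatening" = "LT",
                   "Other and Unknown" = character())
  outc <- rep(outc_val[o$level], times = o$count)
  tibble::tibble(
    primaryid = sprintf("%07d1", seq_len(total)),
    caseid = sprintf("%07d", seq_len(total)),
    fda_dt = "20210601", event_dt = NA_character_,
    age_years = unname(age), sex = unname(sex), weight_kg = unname(wt),
    country = country, outcomes = outc,
    drugs = rep(list(make_drug("DRUGX")), total),
    reaction_pts = rep(list("Hepatotoxicity"), total)
  )
}

# One mid-size synthetic corpus shared across riskmodel/tto tests.
shared_env <- new.env()
shared_corpus <- function() {
  if (is.null(shared_env$corpus)) {
    profs <- dplyr::bind_rows(
      synth_profile("RISKDRUGA", "L01AA01", 0.04, 8, 40, 0.7),
      synth_profile("RISKDRUGB", "L01AA02", 0.04, 5, 80, 1.5),
      synth_profile("NULLDRUGX", "L01AA03", 0.04, 1, 60, 1)
    )
    cfg <- synth_config(n_reports = 30000, drug_profiles = profs,
                        baseline_event_rate = 0.02, seed = 11)
    gen <- synth_generate(cfg)
    flagged <- gen$reports |>
      deduplicate_reports() |>
      normalize_drugs(synth_atc_table(cfg)) |>
      flag_cases("hepatotoxicity")
    shared_env$corpus <- list(cfg = cfg, truth = gen$truth,
                              raw = gen$reports, flagged = flagged)
  }
  shared_env$corpus
}
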
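test_that("Bonferroni correction caps at 1, preserves order, never decreases", {
  expect_equal(bonferroni(0.001), 0.001)
  expect_equal(bonferroni(rep(0.001, 50))[1], 0.05)
  expect_equal(bonferroni(c(0.5, 0.2, 0.01)), c(1, 0.6, 0.03))
  p <- c(0.04, 0.2, 0.9)
  expect_true(all(bonferroni(p) >= p))
  expect_error(bonferroni(c(0.5, 1.2)), "0, 1")
  expect_error(bonferroni(c(0.5, NA)))
})

test_that("design table encodes exposures and Missing covariate levels", {
  r <- dplyr::bind_rows(
    make_report("1", age_years = 40, sex = "F", weight_kg = 70,
                drugs = make_drug("A", norm = "a"), pts = "Hepatotoxicity"),
    make_report("2", age_years = NA, sex = NA, weight_kg = NA,
                drugs = make_drug("B", norm = "b")),
    make_report("3", age_years = 90, sex = "M", weight_kg = 120,
                drugs = make_drug("A", norm = "a"))
  ) |> flag_cases("hepatotoxicity")
  d <- build_design(r, c("a", "b"))
  expect_equal(d$is_case, c(1L, 0L, 0L))
  expect_equal(d$a, c(1L, 0L, 1L))
  expect_equal(d$b, c(0L, 1L, 0L))
  expect_true("Missing" %in% levels(d$age_group))
  expect_equal(as.character(d$age_group), c("18-64.9", "Missing", ">85"))
  expect_equal(as.character(d$weight_group), c("50-100", "Missing", ">100"))
})

test_that("univariate screen passes injected drugs and rejects inverse ones", {
  corp <- shared_corpus()
  scores <- signal_scores(contingency_counts(corp$flagged))
  design <- build_design(corp$flagged, scores$drug)
  screen <- univariate_screen(design, scores$drug)
  scr <- dplyr::filter(screen, passes_screen)
  expect_true("riskdruga" %in% scr$drug)
  expect_false("nulldrugx" %in% scr$drug)
  expect_true(all(scr$ror_lo > 1 & scr$case_count > 100 & scr$p_adjusted < 0.01))
  # a drug appearing only in non-cases can never pass
  design$ghost <- as.integer(design$is_case == 0 &
                               seq_len(nrow(design)) %% 37 == 0)
  g <- univariate_screen(design, c(scores$drug, "ghost"))
  expect_false(g$passes_screen[g$drug == "ghost"])
})

test_that("a null drug with ample cases rarely passes the screen", {
  n <- 20000; n_exp <- 1500; p <- 0.1
  passed <- purrr::map_lgl(1:100, function(i) {
    set.seed(1000 + i)
    x <- as.integer(seq_len(n) <= n_exp)
    y <- stats::rbinom(n, 1, p)
    design <- tibble::tibble(is_case = y, nulldrug = x)
    univariate_screen(design, "nulldrug", min_cases = 100)$passes_screen
  })
  expect_gte(mean(!passed), 0.95)
})

test_that("LASSO keeps a single dominant predictor and is deterministic", {
  set.seed(3)
  n <- 5000
  x1 <- stats::rbinom(n, 1, 0.2)
  x2 <- stats::rbinom(n, 1, 0.2)
  y <- stats::rbinom(n, 1, stats::plogis(-3 + 2.5 * x1))
  design <- tibble::tibble(is_case = y, strong = x1, noise = x2,
                           flat = 0L)
  sel <- lasso_select(design, c("strong", "noise", "flat"), seed = 4)
  expect_true("strong" %in% sel)
  expect_false("flat" %in% sel)  # zero variance: dropped, never selected
  expect_identical(sel, lasso_select(design, c("strong", "noise", "flat"),
                                     seed = 4))
})

test_that("a drugs-only single-term model reproduces the univariate fit", {
  corp <- shared_corpus()
  design <- build_design(corp$flagged, "riskdruga")
  uni <- univariate_screen(design, "riskdruga")
  multi <- multivariate_logistic(design, "riskdruga",
                                 covariates = character())
  expect_equal(multi$odds_ratio, uni$ror, tolerance = 1e-8)
  expect_equal(multi$p_raw, uni$p_raw, tolerance = 1e-8)
})

test_that("adjustment removes a confounded null drug", {
  set.seed(12)
  n <- 20000
  old <- stats::rbinom(n, 1, 0.3)
  # drug preferentially given to the high-risk age group, no direct effect
  drug <- stats::rbinom(n, 1, ifelse(old == 1, 0.3, 0.02))
  y <- stats::rbinom(n, 1, stats::plogis(-3.5 + 1.8 * old))
  design <- tibble::tibble(
    is_case = y, confdrug = drug,
    age_group = factor(ifelse(old == 1, "65-85", "18-64.9"))
  )
  uni <- univariate_screen(design, "confdrug", min_cases = 10)
  expect_gt(uni$ror, 1)
  expect_lt(uni$p_raw, 0.01)
  multi <- multivariate_logistic(design, "confdrug", covariates = "age_group")
  expect_false(multi$significant[multi$term == "confdrug"])
  expect_true(multi$significant[grepl("age_group", multi$term)])
})

test_that("log-odds of injected drugs are recovered with small bias", {
  biases <- purrr::map_dbl(1:5, function(s) {
    profs <- dplyr::bind_rows(
      synth_profile("RECDRUG", "L01XX01", 0.05, 8, 50, 1),
      synth_profile("OTHERNULL", "L01XX02", 0.05, 1, 50, 1)
    )
    cfg <- synth_config(n_reports = 30000, drug_profiles = profs,
                        baseline_event_rate = 0.02, seed = 400 + s)
    gen <- synth_generate(cfg)
    flagged <- gen$reports |>
      deduplicate_reports() |>
      normalize_drugs(synth_atc_table(cfg)) |>
      flag_cases("hepatotoxicity")
    design <- build_design(flagged, c("recdrug", "othernull"))
    fit <- multivariate_logistic(design, c("recdrug", "othernull"))
    log(fit$odds_ratio[fit$term == "recdrug"]) - log(8)
  })
  expect_lt(abs(mean(biases)) / log(8), 0.10)
})
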
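test_that("onset computation handles good, partial, invalid and reversed dates", {
  r <- dplyr::bind_rows(
    make_report("1", event_dt = "20200131",
                drugs = make_drug("A", start_dt = "20200101", norm = "a")),
    make_report("2", event_dt = "20200105",
                drugs = make_drug("A", start_dt = "20200105", norm = "a")),
    make_report("3", event_dt = "20200301",
                drugs = make_drug("A", start_dt = "202001", norm = "a")),
    make_report("4", event_dt = "20201345",
                drugs = make_drug("A", start_dt = "20200101", norm = "a")),
    make_report("5", event_dt = "20200101",
                drugs = make_drug("A", start_dt = "20200301", norm = "a")),
    make_report("6", event_dt = NA,
                drugs = make_drug("A", start_dt = "20200101", norm = "a")),
    make_report("7", event_dt = "20200301",
                drugs = make_drug("A", start_dt = "20200101", role = "C",
                                  norm = "a"))
  )
  tto <- compute_tto(r)
  expect_equal(tto$primaryid, c("1", "2"))
  expect_equal(tto$onset_days, c(30, 1))  # same-day onset floors at 1 day
  excl <- tto_exclusions(tto)
  expect_equal(
    tibble::deframe(excl[order(excl$reason), ]),
    c("invalid date" = 1L, "missing date" = 1L, "negative interval" = 1L,
      "partial date" = 1L)
  )
})

test_that("quartiles use linear interpolation between order statistics", {
  expect_equal(median_iqr(c(1, 2, 3, 4, 5)),
               tibble::tibble(n = 5, median = 3, q1 = 2, q3 = 4))
  expect_equal(median_iqr(1), tibble::tibble(n = 1, median = 1, q1 = 1, q3 = 1))
  x <- withr::with_seed(8, stats::rweibull(200, 0.9, 40))
  got <- median_iqr(x)
  # independent order-statistic interpolation: h = (n-1)p + 1
  oracle_q <- function(x, p) {
    xs <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }
  expect_equal(got$q1, oracle_q(x, 0.25), tolerance = 1e-12)
  expect_equal(got$median, oracle_q(x, 0.5), tolerance = 1e-12)
  expect_equal(got$q3, oracle_q(x, 0.75), tolerance = 1e-12)
})

test_that("Weibull MLE recovers generating parameters", {
  x <- withr::with_seed(101, stats::rweibull(500, shape = 0.8, scale = 50))
  f <- fit_weibull(x)
  expect_true(f$converged)
  expect_gt(f$alpha, 42); expect_lt(f$alpha, 58)
  expect_gt(f$beta, 0.72); expect_lt(f$beta, 0.88)
  # exponential data: the shape CI straddles 1
  e <- fit_weibull(withr::with_seed(7, stats::rexp(1000, rate = 1 / 50)))
  expect_lt(e$beta_ci[1], 1)
  expect_gt(e$beta_ci[2], 1)
  expect_equal(e$failure_type, "random")
})

test_that("the fitted likelihood is at least the likelihood at truth", {
  ll <- function(x, a, b) sum(stats::dweibull(x, b, a, log = TRUE))
  for (s in 1:5) {
    x <- withr::with_seed(200 + s, stats::rweibull(80, 1.3, 30))
    f <- fit_weibull(x)
    expect_gte(f$loglik, ll(x, 30, 1.3) - 1e-8)
  }
})

test_that("the fit agrees with an independent Weibull MLE implementation", {
  skip_if_not_installed("fitdistrplus")
  x <- withr::with_seed(55, stats::rweibull(300, 0.7, 120))
  f <- fit_weibull(x)
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(f$beta, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(f$alpha, unname(ref$estimate["scale"]), tolerance = 1e-3)
  expect_equal(f$se_beta, unname(ref$sd["shape"]), tolerance = 5e-3)
})

test_that("scaling onsets scales alpha and leaves beta invariant", {
  x <- withr::with_seed(33, stats::rweibull(200, 1.1, 20))
  f1 <- fit_weibull(x)
  f2 <- fit_weibull(x * 3)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
  expect_equal(f2$alpha, 3 * f1$alpha, tolerance = 1e-6)
})

test_that("degenerate and undersized samples are refused", {
  expect_error(fit_weibull(c(3, 4)), "at least")
  flat <- fit_weibull(rep(5, 20))
  expect_false(flat$converged)
  expect_true(flat$boundary)
  expect_error(fit_weibull(c(0, 1, 2)), "positive")
})

test_that("tidy and glance expose the fit in broom form", {
  f <- fit_weibull(withr::with_seed(2, stats::rweibull(100, 2, 10)))
  td <- tidy(f)
  expect_equal(td$term, c("alpha", "beta"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  g <- glance(f)
  expect_equal(g$n, 100)
  expect_true(g$converged)
})

test_that("failure classification matches published shape-CI rows", {
  expect_equal(classify_failure(0.43, 0.31, 0.55), "early")
  expect_equal(classify_failure(0.93, 0.78, 1.07), "random")
  expect_equal(classify_failure(3.10, 1.94, 4.26), "wear_out")
  # exhaustive and mutually exclusive over arbitrary CIs
  set.seed(9)
  lo <- stats::runif(500, 0, 3)
  hi <- lo + stats::runif(500, 0, 2)
  lab <- classify_failure((lo + hi) / 2, lo, hi)
  expect_true(all(lab %in% c("early", "random", "wear_out")))
  expect_equal(lab == "early", hi < 1)
  expect_equal(lab == "wear_out", lo > 1)
  expect_error(classify_failure(1, 2, 1), "exceed")
})

test_that("onset bins are right-closed with proportions summing to one", {
  b <- bin_onsets(c(5, 30, 31))
  expect_equal(b$n, c(2, 1))
  expect_equal(sum(b$proportion), 1)
  expect_equal(nrow(bin_onsets(numeric())), 0)
  # early-failure drugs front-load the first month
  x <- withr::with_seed(4, pmax(1, ceiling(stats::rweibull(2000, 0.5, 60))))
  bb <- bin_onsets(x)
  expect_gt(bb$proportion[1], bb$proportion[2])
})

test_that("rank-sum comparison is exact for small groups", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  sep <- compare_groups(c(1, 2, 3), c(100, 101, 102))
  expect_equal(sep$p_value, 0.1)  # 2 of the 20 rank assignments as extreme
  expect_equal(sep$method, "exact enumeration")
})

test_that("the rank-sum test detects a halved median with high power", {
  hits <- purrr::map_lgl(1:100, function(s) {
    withr::with_seed(3000 + s, {
      fatal <- pmax(1, ceiling(stats::rweibull(300, 1, 30)))
      nonfatal <- pmax(1, ceiling(stats::rweibull(300, 1, 60)))
    })
    compare_groups(fatal, nonfatal)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("per-drug summaries fit only drugs with enough onsets", {
  corp <- shared_corpus()
  cases <- dplyr::filter(corp$flagged, is_case)
  tto <- compute_tto(cases)
  smry <- tto_summary(tto, min_n = 30)
  expect_true(all(is.na(smry$beta[smry$n < 30])))
  fitted <- dplyr::filter(smry, !is.na(beta))
  expect_true(all(fitted$failure_type %in% c("early", "random", "wear_out")))
  a <- dplyr::filter(smry, drug == "riskdruga")
  expect_equal(a$failure_type, "early")   # generated with beta = 0.7
  b <- dplyr::filter(smry, drug == "riskdrugb")
  expect_equal(b$failure_type, "wear_out")  # generated with beta = 1.5
})
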
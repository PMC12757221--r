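# Independent brute-force evaluation of the four algorithms, written
# directly from their defining ratios (chi-square via the sum over
# observed/expected cells) — deliberately not sharing code with
# signal_scores().
brute_force_scores <- function(a, b, c, d) {
  N <- a + b + c + d
  O <- c(a, b, c, d)
  E <- c((a + b) * (a + c), (a + b) * (b + d),
         (c + d) * (a + c), (c + d) * (b + d)) / N
  v <- 1 / a + 1 / b + 1 / c + 1 / d
  ror <- (a / c) / (b / d)
  ebgm <- a / E[1]
  list(
    ror = ror,
    ror_lo = exp(log(ror) - 1.96 * sqrt(v)),
    ror_hi = exp(log(ror) + 1.96 * sqrt(v)),
    prr = (a / (a + b)) / (c / (c + d)),
    chi2 = sum((O - E)^2 / E),
    ebgm = ebgm,
    ebgm05 = exp(log(ebgm) - 1.645 * sqrt(v)),
    ic = log(ebgm) / log(2),
    ic025 = log(ebgm) / log(2) - 1.96 * sqrt(v) / log(2)
  )
}

test_that("a perfectly symmetric table gives null statistics", {
  s <- signal_scores(tibble::tibble(a = 25, b = 25, c = 25, d = 25))
  expect_equal(s$ror, 1)
  expect_equal(s$prr, 1)
  expect_equal(s$ebgm, 1)
  expect_equal(s$ic, 0)
  expect_equal(s$chi2, 0)
  expect_false(s$ror_signal)
})

test_that("the worked 2x2 example matches independent hand arithmetic", {
  s <- signal_scores(tibble::tibble(a = 10, b = 90, c = 100, d = 9900))
  expect_equal(s$ror, 11, tolerance = 1e-12)
  expect_equal(s$prr, 10, tolerance = 1e-12)
  expect_equal(s$ebgm, 101000 / 11000, tolerance = 1e-12)
  expect_equal(s$ic, log2(101000 / 11000), tolerance = 1e-12)
  expect_equal(s$chi2, 74.447, tolerance = 1e-4)
  expect_equal(s$ror_lo, 5.560, tolerance = 1e-3)
  expect_equal(s$ror_hi, 21.765, tolerance = 1e-3)
  expect_true(s$ror_signal && s$prr_signal && s$mgps_signal && s$bcpnn_signal)
})

test_that("scores match brute-force evaluation on all small tables", {
  grid <- expand.grid(a = 1:6, b = 1:6, c = 1:6, d = 1:6)
  s <- signal_scores(grid)
  bf <- purrr::pmap(grid, brute_force_scores)
  for (col in c("ror", "ror_lo", "ror_hi", "prr", "chi2", "ebgm",
                "ebgm05", "ic", "ic025")) {
    got <- s[[col]]
    want <- purrr::map_dbl(bf, col)
    rel <- abs(got - want) / pmax(abs(want), 1e-300)
    expect_lt(max(rel), 1e-12)
  }
  # chi-square also agrees with the Pearson test statistic
  i <- which(grid$a == 3 & grid$b == 5 & grid$c == 2 & grid$d == 6)
  m <- matrix(c(3, 5, 2, 6), 2, byrow = TRUE)
  ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  expect_equal(s$chi2[i], unname(ref$statistic), tolerance = 1e-12)
})

test_that("IC equals log2(EBGM) identically, including at printed precision", {
  grid <- expand.grid(a = 1:5, b = c(2, 9), c = c(3, 8), d = c(50, 500))
  s <- signal_scores(grid)
  expect_equal(s$ic, log2(s$ebgm), tolerance = 1e-15)
  published <- readr::read_csv(extdata("hepatotox_top30_signals.csv"),
                               show_col_types = FALSE)
  expect_true(all(abs(round(log2(published$ebgm), 2) - published$ic) <= 0.011))
})

test_that("ROR is at least PRR and both rise monotonically in a", {
  set.seed(42)
  tabs <- tibble::tibble(
    a = sample(1:50, 200, TRUE), b = sample(1:500, 200, TRUE),
    c = sample(1:50, 200, TRUE), d = sample(100:5000, 200, TRUE)
  )
  s <- signal_scores(tabs)
  pos <- s$ror >= 1   # the inequality flips below the null
  expect_gt(sum(pos), 10)
  expect_true(all(s$ror[pos] >= s$prr[pos] - 1e-12))
  inc <- signal_scores(tibble::tibble(a = 1:30, b = 40, c = 25, d = 900))
  for (col in c("ror", "prr", "ebgm", "ic")) {
    expect_true(all(diff(inc[[col]]) > 0), info = col)
  }
})

test_that("zero cells and zero marginals yield absent scores, never infinities", {
  s <- signal_scores(tibble::tibble(a = c(0, 5, 0), b = c(10, 0, 0),
                                    c = c(3, 3, 4), d = c(100, 100, 100)))
  expect_true(all(is.na(s$ror)))
  expect_true(all(!s$ror_signal & !s$prr_signal & !s$mgps_signal &
                    !s$bcpnn_signal))
  expect_equal(s$reason, c("zero cell", "zero cell", "zero marginal"))
  expect_false(any(purrr::map_lgl(s, ~ any(is.infinite(unlist(.x))))))
  # the optional continuity correction rescues zero cells
  h <- signal_scores(tibble::tibble(a = 0, b = 10, c = 3, d = 100),
                     haldane = TRUE)
  expect_true(is.finite(h$ror))
})

test_that("ranking keeps ROR-positive drugs in descending ROR order", {
  counts <- tibble::tibble(
    drug = c("strong", "weak", "null", "rare"),
    a = c(30, 12, 2, 2), b = c(70, 88, 98, 4),
    c = c(70, 88, 98, 98), d = c(9830, 9812, 9802, 9896)
  )
  ranked <- rank_signals(signal_scores(counts))
  expect_equal(ranked$drug[1:2], c("strong", "weak"))
  expect_false("null" %in% ranked$drug)   # CI lower bound below 1
  expect_false("rare" %in% ranked$drug)   # fewer than 3 cases
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  tab <- signal_table(ranked)
  expect_match(tab$ror_ci[1], "^[0-9.]+ \\([0-9.]+-[0-9.]+\\)$")
})

test_that("the injected signal outranks null drugs in a synthetic corpus", {
  corp <- shared_corpus()
  ranked <- corp$flagged |>
    contingency_counts() |>
    signal_scores() |>
    rank_signals()
  expect_equal(ranked$drug[1], "riskdruga")
  expect_true("riskdrugb" %in% ranked$drug)
})

test_that("the ROR flag holds its nominal false-positive rate under the null", {
  set.seed(7)
  n_rep <- 1000
  n_exp <- 500; n_unexp <- 19500; p <- 0.01
  a <- stats::rbinom(n_rep, n_exp, p)
  c <- stats::rbinom(n_rep, n_unexp, p)
  s <- signal_scores(tibble::tibble(a = a, b = n_exp - a, c = c,
                                    d = n_unexp - c))
  expect_lte(mean(s$ror_signal), 0.075)
})
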
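#' Build 2x2 contingency tables for drug-event pairs
#'
#' For each drug, reports are cross-classified against the target event:
#' `a` = reports with the drug as Primary Suspect AND the target PT,
#' `b` = PS drug without the PT, `c` = other reports with the PT,
#' `d` = the rest; `a + b + c + d` equals the total report count for
#' every drug. Exposure uses PS drugs only, on the normalized name
#' where available (falling back to the case-folded raw name).
#'
#' @param reports De-duplicated, case-flagged report tibble (run
#'   [deduplicate_reports()], [normalize_drugs()], [flag_cases()]).
#' @param drugs Character vector of drug names to tabulate; default all
#'   PS drug names present. A drug absent from the corpus gets
#'   `a = b = 0` (valid, low-count).
#' @return Tibble with columns `drug`, `a`, `b`, `c`, `d`.
#' @export
contingency_counts <- function(reports, drugs = NULL) {
  assert_flagged(reports)
  n_total <- nrow(reports)
  n_cases <- sum(reports$is_case)
  exposure <- ps_exposure(reports) |>
    mutate(is_case = reports$is_case[.data$row])
  drugs <- drugs %||% sort(unique(exposure$drug))
  counts <- exposure |>
    summarise(n_exposed = n(), a = sum(.data$is_case), .by = "drug")
  tibble(drug = drugs) |>
    left_join(counts, by = "drug") |>
    mutate(
      n_exposed = tidyr::replace_na(.data$n_exposed, 0L),
      a = as.integer(tidyr::replace_na(.data$a, 0L)),
      b = as.integer(.data$n_exposed - .data$a),
      c = as.integer(n_cases - .data$a),
      d = as.integer(n_total - .data$n_exposed - .data$c)
    ) |>
    select("drug", "a", "b", "c", "d")
}

#' Disproportionality statistics and signal criteria for 2x2 tables
#'
#' Computes, per table, the four classical pharmacovigilance measures
#' with their interval bounds and signal flags:
#'
#' * ROR = (a/c)/(b/d), 95% CI `exp(ln ROR +- 1.96 sqrt(v))` with the
#'   shared variance term `v = 1/a + 1/b + 1/c + 1/d`; signal when the
#'   CI lower bound exceeds 1 and `a >= 3`.
#' * PRR = (a/(a+b))/(c/(c+d)) with Pearson's chi-square (no continuity
#'   correction); signal when `PRR >= 2`, `chi2 >= 4` and `a >= 3`.
#' * EBGM = aN/((a+b)(a+c)) — the observed-to-expected relative
#'   reporting ratio (the unshrunk form; no gamma-Poisson shrinkage) —
#'   with one-sided 95% lower bound `EBGM05 = exp(ln EBGM - 1.645
#'   sqrt(v))`; signal when `EBGM05 > 2`.
#' * IC = log2(EBGM) with `IC025 = IC - 1.96 sqrt(v)/ln 2`; signal when
#'   `IC025 > 0` and `a > 0`.
#'
#' Tables with a zero cell cannot support these estimates on the odds
#' scale: their scores and bounds are returned `NA` with a structured
#' `reason` ("zero marginal" or "zero cell") and all flags `FALSE`;
#' infinities are never propagated. An optional Haldane-style
#' continuity correction (`+0.5` to every cell) is available but off by
#' default.
#'
#' @param counts Tibble with integer columns `a`, `b`, `c`, `d` (other
#'   columns, e.g. `drug`, are carried through).
#' @param haldane Add 0.5 to every cell before scoring (default FALSE).
#' @return `counts` with appended columns `n_cases`, `ror`, `ror_lo`,
#'   `ror_hi`, `prr`, `chi2`, `ebgm`, `ebgm05`, `ic`, `ic025`, the four
#'   flags `ror_signal`, `prr_signal`, `mgps_signal`, `bcpnn_signal`,
#'   and `reason` (`NA` when scored).
#' @examples
#' signal_scores(tibble::tibble(a = 10, b = 90, c = 100, d = 9900))
#' @export
signal_scores <- function(counts, haldane = FALSE) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(counts)))
  x <- as_tibble(counts)
  if (any(x$a < 0 | x$b < 0 | x$c < 0 | x$d < 0)) {
    abort("Contingency cells must be non-negative.")
  }
  a0 <- x$a; b0 <- x$b; c0 <- x$c; d0 <- x$d
  N0 <- a0 + b0 + c0 + d0
  if (any(N0 == 0)) abort("Contingency tables must have N > 0.")
  zero_marg <- (a0 + b0) == 0 | (c0 + d0) == 0 | (a0 + c0) == 0 | (b0 + d0) == 0

  off <- if (haldane) 0.5 else 0
  a <- a0 + off; b <- b0 + off; c <- c0 + off; d <- d0 + off
  zero_cell <- a == 0 | b == 0 | c == 0 | d == 0
  bad <- zero_marg | zero_cell

  N <- a + b + c + d
  v <- 1 / a + 1 / b + 1 / c + 1 / d
  ror <- (a / c) / (b / d)
  prr <- (a / (a + b)) / (c / (c + d))
  chi2 <- N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  ebgm <- a * N / ((a + b) * (a + c))
  ic <- log2(ebgm)
  ror_lo <- exp(log(ror) - 1.96 * sqrt(v))
  ror_hi <- exp(log(ror) + 1.96 * sqrt(v))
  ebgm05 <- exp(log(ebgm) - 1.645 * sqrt(v))
  ic025 <- ic - 1.96 * sqrt(v) / log(2)

  blank <- function(z) ifelse(bad, NA_real_, z)
  x |>
    mutate(
      n_cases = a0,
      ror = blank(ror), ror_lo = blank(ror_lo), ror_hi = blank(ror_hi),
      prr = blank(prr), chi2 = blank(chi2),
      ebgm = blank(ebgm), ebgm05 = blank(ebgm05),
      ic = blank(ic), ic025 = blank(ic025),
      ror_signal = !bad & ror_lo > 1 & a0 >= 3,
      prr_signal = !bad & prr >= 2 & chi2 >= 4 & a0 >= 3,
      mgps_signal = !bad & ebgm05 > 2,
      bcpnn_signal = !bad & ic025 > 0 & a0 > 0,
      reason = case_when(
        zero_marg ~ "zero marginal",
        zero_cell ~ "zero cell",
        TRUE ~ NA_character_
      )
    )
}

#' Rank drugs by reporting odds ratio among ROR-positive signals
#'
#' Keeps drugs meeting the primary signal criterion (ROR 95% CI lower
#' bound > 1 with at least `min_cases` target-event reports) and orders
#' them by descending ROR. The three other algorithms' flags are
#' carried alongside, not intersected.
#'
#' @param scores Output of [signal_scores()].
#' @param min_cases Minimum target-event count (default 3).
#' @return The filtered, ordered tibble with a `rank` column prepended.
#' @export
rank_signals <- function(scores, min_cases = 3) {
  scores |>
    filter(.data$ror_signal, .data$n_cases >= min_cases) |>
    arrange(desc(.data$ror)) |>
    mutate(rank = row_number(), .before = 1)
}

#' Format a ranked signal table for display or CSV export
#'
#' Produces the conventional pharmacovigilance layout: rank, ATC code,
#' drug, case count, then "estimate (interval)" strings for ROR,
#' PRR (chi-square), EBGM (EBGM05) and IC (IC025), all at 2 decimals.
#'
#' @param ranked Output of [rank_signals()]; an `atc_code` column is
#'   used if present.
#' @return Character-column tibble, one row per ranked drug.
#' @export
signal_table <- function(ranked) {
  f2 <- function(x) formatC(round_half_up(x, 2), format = "f", digits = 2)
  ranked |>
    transmute(
      rank = .data$rank,
      atc_code = if ("atc_code" %in% names(ranked)) .data$atc_code else NA_character_,
      drug = .data$drug,
      cases = .data$n_cases,
      ror_ci = paste0(f2(.data$ror), " (", f2(.data$ror_lo), "-", f2(.data$ror_hi), ")"),
      prr_chi2 = paste0(f2(.data$prr), " (", f2(.data$chi2), ")"),
      ebgm_ebgm05 = paste0(f2(.data$ebgm), " (", f2(.data$ebgm05), ")"),
      ic_ic025 = paste0(f2(.data$ic), " (", f2(.data$ic025), ")")
    )
}
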
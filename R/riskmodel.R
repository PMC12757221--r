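#' Bonferroni multiple-testing correction
#'
#' `p_adj_i = min(1, m * p_i)` with `m` the number of tests; order is
#' preserved and a p-value is never decreased.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bonferroni(c(0.001, 0.5))
#' @export
bonferroni <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] and be non-missing.")
  }
  stats::p.adjust(p, method = "bonferroni")
}

#' Build a report-level design table for risk-factor regression
#'
#' One row per de-duplicated report; the outcome is the case flag and
#' each drug contributes a 0/1 Primary-Suspect exposure indicator.
#' Demographic covariates are categorical with explicit `"Missing"`
#' levels (reports with missing demographics are retained, not
#' listwise-deleted): age group (<18, 18-64.9, 65-85, >85), sex, and
#' weight group (<50, 50-100, >100 kg). Reference level of each factor
#' is its largest stratum.
#'
#' @param reports De-duplicated, case-flagged, normalized report tibble.
#' @param drugs Drug names (normalized) to encode as indicators.
#' @return Tibble with `is_case` (0/1), one integer column per drug,
#'   and factors `age_group`, `sex_group`, `weight_group`.
#' @export
build_design <- function(reports, drugs) {
  assert_flagged(reports)
  exposure <- ps_exposure(reports)
  design <- tibble(is_case = as.integer(reports$is_case))
  for (dg in drugs) {
    col <- integer(nrow(reports))
    col[exposure$row[exposure$drug == dg]] <- 1L
    design[[dg]] <- col
  }
  biggest_first <- function(f) {
    f <- factor(f)
    stats::relevel(f, ref = names(which.max(table(f))))
  }
  design$age_group <- biggest_first(case_when(
    is.na(reports$age_years) ~ "Missing",
    reports$age_years < 18 ~ "<18",
    reports$age_years < 65 ~ "18-64.9",
    reports$age_years <= 85 ~ "65-85",
    TRUE ~ ">85"
  ))
  design$sex_group <- biggest_first(case_when(
    is.na(reports$sex) ~ "Missing",
    TRUE ~ reports$sex
  ))
  design$weight_group <- biggest_first(case_when(
    is.na(reports$weight_kg) ~ "Missing",
    reports$weight_kg < 50 ~ "<50",
    reports$weight_kg <= 100 ~ "50-100",
    TRUE ~ ">100"
  ))
  design
}

glm_term <- function(fit, term) {
  s <- summary(fit)$coefficients
  if (!term %in% rownames(s)) return(NULL)
  est <- s[term, "Estimate"]; se <- s[term, "Std. Error"]
  list(coef = est, se = se, p = s[term, "Pr(>|z|)"],
       or = exp(est), lo = exp(est - 1.96 * se), hi = exp(est + 1.96 * se))
}

#' Univariate logistic screen of candidate drugs
#'
#' Per drug, a single-predictor logistic regression of the case flag on
#' the exposure indicator (its odds ratio equals the 2x2 reporting odds
#' ratio); Wald p-values are Bonferroni-corrected over the number of
#' drugs tested. A drug passes the screen iff the OR 95% CI lower bound
#' exceeds 1, its target-event count exceeds `min_cases`, and the
#' adjusted p-value is below `alpha`. Drugs with separated or otherwise
#' non-estimable fits are flagged and never pass.
#'
#' @param design Output of [build_design()].
#' @param drugs Drug columns to screen.
#' @param min_cases Event-count threshold (default 100, strict `>`).
#' @param alpha Adjusted-p threshold (default 0.01).
#' @return Tibble: `drug`, `case_count`, `ror`, `ror_lo`, `ror_hi`,
#'   `p_raw`, `p_adjusted`, `estimable`, `passes_screen`.
#' @export
univariate_screen <- function(design, drugs, min_cases = 100, alpha = 0.01) {
  rows <- purrr::map(drugs, function(dg) {
    x <- design[[dg]]
    cc <- sum(x == 1 & design$is_case == 1)
    if (stats::var(x) == 0) {
      return(tibble(drug = dg, case_count = cc, ror = NA_real_,
                    ror_lo = NA_real_, ror_hi = NA_real_, p_raw = NA_real_,
                    estimable = FALSE))
    }
    fit <- stats::glm(design$is_case ~ x, family = stats::binomial())
    tm <- glm_term(fit, "x")
    separated <- is.null(tm) || abs(tm$coef) > 15 || tm$se > 15
    if (separated) {
      return(tibble(drug = dg, case_count = cc, ror = NA_real_,
                    ror_lo = NA_real_, ror_hi = NA_real_, p_raw = NA_real_,
                    estimable = FALSE))
    }
    tibble(drug = dg, case_count = cc, ror = tm$or, ror_lo = tm$lo,
           ror_hi = tm$hi, p_raw = tm$p, estimable = TRUE)
  })
  out <- bind_rows(rows)
  p_adj <- rep(NA_real_, nrow(out))
  est <- out$estimable
  # Bonferroni multiplicity m = number of drugs tested (all attempted)
  p_adj[est] <- pmin(1, length(drugs) * out$p_raw[est])
  out |>
    mutate(
      p_adjusted = p_adj,
      passes_screen = .data$estimable & .data$ror_lo > 1 &
        .data$case_count > min_cases & .data$p_adjusted < alpha
    )
}

#' LASSO selection of screened drugs
#'
#' L1-penalized logistic regression over the screened drug indicators;
#' the penalty is chosen by 10-fold cross-validated binomial deviance
#' (`lambda.min` by default, the 1-SE rule as an option), with the fold
#' assignment fixed by `seed` so the selected set is fully
#' deterministic. Zero-variance columns are dropped before fitting and
#' can never be selected.
#'
#' @param design Output of [build_design()].
#' @param drugs Screened drug columns (at least 2).
#' @param seed Integer seed for the cross-validation folds.
#' @param rule `"min"` (CV-minimum deviance) or `"1se"`.
#' @param nfolds Number of CV folds (default 10).
#' @return Character vector of selected drugs (nonzero coefficients);
#'   empty, with a warning, if nothing survives.
#' @export
lasso_select <- function(design, drugs, seed = 1, rule = c("min", "1se"),
                         nfolds = 10) {
  rule <- match.arg(rule)
  keep <- drugs[purrr::map_dbl(drugs, ~ stats::var(design[[.x]])) > 0]
  if (length(keep) < 2) {
    abort("LASSO selection needs at least 2 non-degenerate screened drugs.")
  }
  x <- as.matrix(design[keep])
  y <- design$is_case
  cvfit <- withr::with_seed(
    seed,
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                      nfolds = nfolds, type.measure = "deviance")
  )
  lam <- if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  beta <- as.matrix(stats::coef(cvfit, s = lam))[-1, 1]
  selected <- names(beta)[beta != 0]
  if (length(selected) == 0) {
    warn("LASSO selected no drugs at the cross-validated penalty.")
  }
  selected
}

#' Multivariate logistic risk-factor model
#'
#' Joint maximum-likelihood logistic regression of the case flag on the
#' LASSO-selected drug indicators plus demographic covariates. Each
#' term is reported as an odds ratio with Wald 95% CI; p-values are
#' Bonferroni-corrected over all reported (non-intercept) terms, and a
#' term is significant when its adjusted p-value is below `alpha`.
#' Terms showing separation are flagged; non-convergence is an error
#' naming the model terms.
#'
#' @param design Output of [build_design()].
#' @param drugs Selected drug columns.
#' @param covariates Covariate columns (default age, sex, weight
#'   groups); use `character()` for a drugs-only model.
#' @param alpha Significance threshold on adjusted p (default 0.01).
#' @return Tibble of terms: `term`, `odds_ratio`, `ci_lo`, `ci_hi`,
#'   `p_raw`, `p_adjusted`, `separated`, `significant` — the table
#'   behind a forest plot.
#' @export
multivariate_logistic <- function(design, drugs,
                                  covariates = c("age_group", "sex_group",
                                                 "weight_group"),
                                  alpha = 0.01) {
  if (length(drugs) == 0) abort("No drugs supplied to the multivariate model.")
  vars <- c(drugs, covariates)
  fml <- stats::reformulate(sprintf("`%s`", vars), response = "is_case")
  fit <- stats::glm(fml, data = design, family = stats::binomial())
  if (!fit$converged) {
    abort(paste0("Logistic model did not converge; terms: ",
                 paste(vars, collapse = ", ")))
  }
  s <- summary(fit)$coefficients
  s <- s[rownames(s) != "(Intercept)", , drop = FALSE]
  term <- stringr::str_remove_all(rownames(s), "`")
  out <- tibble(
    term = term,
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    p_raw = s[, "Pr(>|z|)"]
  ) |>
    mutate(
      odds_ratio = exp(.data$estimate),
      ci_lo = exp(.data$estimate - 1.96 * .data$std_error),
      ci_hi = exp(.data$estimate + 1.96 * .data$std_error),
      separated = abs(.data$estimate) > 15 | .data$std_error > 15,
      p_adjusted = bonferroni(.data$p_raw),
      significant = !.data$separated & .data$p_adjusted < alpha
    ) |>
    select("term", "odds_ratio", "ci_lo", "ci_hi", "p_raw", "p_adjusted",
           "separated", "significant")
  attr(out, "fit") <- fit
  out
}
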
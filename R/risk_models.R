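# Logistic models of event reporting on categorical demographic and
# treatment covariates: univariable screening followed by a multivariable
# fit on the covariates passing the screen. Fits are maximum-likelihood via
# iteratively reweighted least squares (stats::glm); odds ratios carry Wald
# 95% intervals.

glm_ctrl <- function() stats::glm.control(epsilon = 1e-8, maxit = 100)

tidy_logistic <- function(fit, data, covariates, outcome) {
  sm <- summary(fit)$coefficients
  rows <- list()
  for (cov in covariates) {
    lv <- levels(data[[cov]])
    counts <- table(data[[cov]], data[[outcome]])
    for (j in seq_along(lv)) {
      term <- paste0(cov, lv[j])
      is_ref <- j == 1L
      if (is_ref) {
        est <- 0; se <- NA_real_; p <- NA_real_
      } else if (term %in% rownames(sm)) {
        est <- sm[term, "Estimate"]
        se <- sm[term, "Std. Error"]
        p <- sm[term, "Pr(>|z|)"]
      } else {
        est <- NA_real_; se <- NA_real_; p <- NA_real_
      }
      # a zero cell against the reference makes the level non-estimable
      # (separation); flag rather than report a diverged estimate
      estimable <- all(counts[c(1L, j), ] > 0)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        covariate = cov, level = lv[j], reference = is_ref,
        n_control = unname(counts[j, 1L]), n_case = unname(counts[j, 2L]),
        or = if (is_ref) 1 else exp(est),
        or_low = if (is_ref) NA_real_ else exp(est - 1.96 * se),
        or_high = if (is_ref) NA_real_ else exp(est + 1.96 * se),
        p_value = p,
        estimable = estimable
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_used") <- nrow(data)
  attr(out, "converged") <- fit$converged
  attr(out, "log_lik") <- as.numeric(logLik(fit))
  class(out) <- c("logistic_fit", class(out))
  out
}

prepare_model_frame <- function(data, covariates, outcome, weights = NULL) {
  data <- as.data.frame(data)
  if (!outcome %in% names(data)) {
    abort(paste0("outcome column not found: ", outcome),
          class = "faerspv_config_error")
  }
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) {
    abort("outcome must be binary (0/1 or logical).",
          class = "faerspv_config_error")
  }
  data[[outcome]] <- y
  for (cov in covariates) {
    if (!cov %in% names(data)) {
      abort(paste0("covariate column not found: ", cov),
            class = "faerspv_config_error")
    }
    if (!is.factor(data[[cov]])) data[[cov]] <- factor(data[[cov]])
    data[[cov]] <- droplevels(data[[cov]])
  }
  if (!is.null(weights)) data$..w <- weights
  keep <- stats::complete.cases(data[, covariates, drop = FALSE])
  data[keep, , drop = FALSE]
}

#' Univariable logistic regression on one categorical covariate
#'
#' Available-case maximum-likelihood fit of the outcome on a single
#' categorical covariate. For a one-way layout the fitted odds ratio of each
#' level against the reference equals the closed-form cross-product ratio of
#' the corresponding 2x2 -- this identity is used as an internal consistency
#' check in the test suite. Wald 95% CIs.
#'
#' @param data data frame; rows with missing covariate are dropped.
#' @param covariate name of the covariate column (factor; first level is the
#'   reference).
#' @param outcome name of the binary outcome column (default `"y"`).
#' @param weights optional non-negative case weights (e.g. aggregated
#'   counts).
#' @return a `logistic_fit` tibble: one row per level with counts, OR, CI,
#'   p-value, and an `estimable` flag (FALSE under separation).
#' @export
fit_univariable <- function(data, covariate, outcome = "y", weights = NULL) {
  mf <- prepare_model_frame(data, covariate, outcome, weights)
  if (nlevels(mf[[covariate]]) < 2L) {
    abort(paste0("covariate has fewer than 2 observed levels: ", covariate),
          class = "faerspv_data_error")
  }
  fml <- stats::as.formula(paste(outcome, "~", covariate))
  fit <- if (is.null(weights)) {
    glm(fml, family = binomial(), data = mf, control = glm_ctrl())
  } else {
    glm(fml, family = binomial(), data = mf, weights = mf$..w,
        control = glm_ctrl())
  }
  out <- tidy_logistic_weighted(fit, mf, covariate, outcome)
  attr(out, "model") <- "univariable"
  out
}

# count table respecting optional weights
tidy_logistic_weighted <- function(fit, mf, covariates, outcome) {
  if (is.null(mf$..w)) return(tidy_logistic(fit, mf, covariates, outcome))
  sm <- summary(fit)$coefficients
  rows <- list()
  for (cov in covariates) {
    lv <- levels(mf[[cov]])
    agg <- stats::xtabs(..w ~ mf[[cov]] + mf[[outcome]], data = mf)
    for (j in seq_along(lv)) {
      term <- paste0(cov, lv[j])
      is_ref <- j == 1L
      est <- if (is_ref) 0 else sm[term, "Estimate"]
      se <- if (is_ref) NA_real_ else sm[term, "Std. Error"]
      p <- if (is_ref) NA_real_ else sm[term, "Pr(>|z|)"]
      estimable <- all(agg[c(1L, j), ] > 0)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        covariate = cov, level = lv[j], reference = is_ref,
        n_control = unname(agg[j, 1L]), n_case = unname(agg[j, 2L]),
        or = if (is_ref) 1 else exp(est),
        or_low = if (is_ref) NA_real_ else exp(est - 1.96 * se),
        or_high = if (is_ref) NA_real_ else exp(est + 1.96 * se),
        p_value = p, estimable = estimable
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_used") <- sum(mf$..w)
  attr(out, "converged") <- fit$converged
  attr(out, "log_lik") <- as.numeric(logLik(fit))
  class(out) <- c("logistic_fit", class(out))
  out
}

#' Screen covariates for the multivariable model
#'
#' A covariate passes when any of its non-reference level-wise Wald p-values
#' is below `alpha`.
#'
#' @param fits a named list of `logistic_fit` objects (names = covariates),
#'   e.g. from [fit_univariable()] per covariate.
#' @param alpha significance threshold, default 0.05.
#' @return character vector of covariate names passing the screen.
#' @export
screen_covariates <- function(fits, alpha = 0.05) {
  if (alpha <= 0 || alpha > 1) {
    abort("`alpha` must lie in (0, 1].", class = "faerspv_config_error")
  }
  passed <- vapply(fits, function(f) {
    p <- f$p_value[!f$reference]
    any(!is.na(p) & p < alpha)
  }, logical(1))
  names(fits)[passed]
}

#' Multivariable logistic regression on selected covariates
#'
#' Complete-case joint maximum-likelihood fit (IRLS; convergence when the
#' relative deviance change falls below 1e-8, at most 100 iterations).
#' Warns when the number of complete cases is below ten per estimated
#' coefficient; errors if IRLS does not converge.
#'
#' @param data data frame with the outcome and covariate columns.
#' @param covariates character vector of categorical covariate names.
#' @param outcome name of the binary outcome column.
#' @param weights optional non-negative case weights.
#' @return a `logistic_fit` tibble with one row per (covariate, level),
#'   adjusted ORs, Wald CIs, p-values; metadata in attributes
#'   (`n_used`, `converged`, `log_lik`).
#' @export
fit_multivariable <- function(data, covariates, outcome = "y",
                              weights = NULL) {
  mf <- prepare_model_frame(data, covariates, outcome, weights)
  n_coef <- 1L + sum(vapply(covariates,
                            function(cov) nlevels(mf[[cov]]) - 1L, integer(1)))
  if (nrow(mf) < 10L * n_coef) {
    warn(sprintf("only %d complete cases for %d coefficients (< 10 per coefficient)",
                 nrow(mf), n_coef))
  }
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(covariates, collapse = " + ")))
  fit <- if (is.null(weights)) {
    glm(fml, family = binomial(), data = mf, control = glm_ctrl())
  } else {
    glm(fml, family = binomial(), data = mf, weights = mf$..w,
        control = glm_ctrl())
  }
  if (!fit$converged) {
    abort("multivariable logistic fit did not converge within 100 IRLS iterations.",
          class = "faerspv_fit_error")
  }
  out <- tidy_logistic_weighted(fit, mf, covariates, outcome)
  attr(out, "model") <- "multivariable"
  out
}

#' Expand an aggregated count table into model input
#'
#' Turns a table with one row per covariate level and the per-outcome counts
#' into a weighted model-input frame (four rows per level pair), suitable for
#' [fit_univariable()]/[fit_multivariable()] with `weights`.
#'
#' @param counts data frame with columns `level`, `n_control`, `n_case`;
#'   levels in display order, first row the reference.
#' @param covariate name to give the covariate column.
#' @return list with `data` (columns `y`, covariate) and `weights`.
#' @export
expand_count_table <- function(counts, covariate = "x") {
  counts <- tibble::as_tibble(counts)
  lv <- counts$level
  data <- tibble::tibble(
    y = rep(c(0L, 1L), each = nrow(counts)),
    x = factor(rep(lv, 2L), levels = lv)
  )
  names(data)[2] <- covariate
  list(data = data, weights = c(counts$n_control, counts$n_case))
}

#' Assemble the risk-model input from a cleaned dataset
#'
#' One row per case with a matched target drug; outcome `y = 1` when the
#' case reports at least one mapped event PT. Covariates: `age_group`,
#' `wt_group`, `sex`, `duration_group` (therapy start to event onset, binned),
#' and `drug` (reference level = first drug in `drug_levels`).
#'
#' @param clean a `faers_clean` object.
#' @param drug_levels level order for the drug factor (first = reference);
#'   default: alphabetical order of the observed target drugs.
#' @return tibble ready for [fit_univariable()] / [fit_multivariable()].
#' @export
make_model_input <- function(clean, drug_levels = NULL) {
  cases <- clean$cases[!is.na(clean$cases$target_drug), , drop = FALSE]
  if (is.null(drug_levels)) drug_levels <- sort(unique(cases$target_drug))
  tto <- compute_tto(cases$start_dt, cases$event_dt)
  dur <- bin_covariates(duration_days = tto$tto_days)$duration_group
  tibble::tibble(
    caseid = cases$caseid,
    y = as.integer(cases$any_event),
    age_group = cases$age_group,
    wt_group = cases$wt_group,
    sex = factor(cases$sex, levels = c("F", "M")),
    duration_group = dur,
    drug = factor(cases$target_drug, levels = drug_levels)
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit: %s> n = %s, converged = %s, logLik = %.2f\n",
              attr(x, "model") %||% "?", format(attr(x, "n_used")),
              attr(x, "converged"), attr(x, "log_lik")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
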
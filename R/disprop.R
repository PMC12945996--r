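# Disproportionality statistics for 2x2 report contingency tables.
#
# Cell layout (one deduplicated case counts at most once per pair):
#   a  target drug & target event     b  target drug, other events
#   c  other drugs, target event      d  other drugs, other events
#
# BCPNN priors follow the standard one-layer Bayesian confidence propagation
# parameterisation: alpha1 = beta1 = 1, alpha = beta = 2, gamma11 = 1, with
# gamma calibrated so that the prior expectation of the information
# component is zero under independence.

bcpnn_priors <- list(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2, gamma11 = 1)

#' Build a 2x2 contingency table for one (drug, event) pair
#'
#' The exposed margin holds deduplicated cases whose matched suspect drug is
#' the target; the comparator margin holds every other case in the dataset
#' (other suspect drugs, role-excluded cases, and cases with no dictionary
#' drug), the "all other drugs in the loaded data" background policy.
#'
#' @param clean a `faers_clean` object from [build_clean_cases()].
#' @param target_drug canonical drug name.
#' @param target_event a PT (default) or an SMQ category label.
#' @param event_type `"pt"` or `"category"`.
#' @return list with integer cells `a`, `b`, `c`, `d`, the total `n`, and a
#'   logical `flagged` set when the target drug is absent from the data.
#' @export
build_contingency <- function(clean, target_drug, target_event,
                              event_type = c("pt", "category")) {
  event_type <- match.arg(event_type)
  cases <- clean$cases
  if (!nrow(cases)) {
    abort("empty dataset: no cases to tabulate.", class = "faerspv_data_error")
  }
  ev_cases <- unique(clean$events$caseid[clean$events[[event_type]] == target_event])
  exposed <- !is.na(cases$target_drug) & cases$target_drug == target_drug
  with_ev <- cases$caseid %in% ev_cases
  a <- sum(exposed & with_ev)
  b <- sum(exposed & !with_ev)
  c <- sum(!exposed & with_ev)
  d <- sum(!exposed & !with_ev)
  list(a = a, b = b, c = c, d = d, n = a + b + c + d,
       flagged = (a + b) == 0L)
}

#' Reporting odds ratio with Wald 95% confidence interval
#'
#' `ROR = (a d)/(b c)`; `CI = exp(log ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`.
#' Any zero cell leaves the statistic undefined (`NA`, no continuity
#' correction is applied by default).
#'
#' @param a,b,c,d cell counts (vectorised).
#' @return tibble with columns `ror`, `ror_low`, `ror_high`.
#' @export
compute_ror <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ifelse(ok, (a * d) / (b * c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  tibble::tibble(
    ror = ror,
    ror_low = exp(log(ror) - 1.96 * se),
    ror_high = exp(log(ror) + 1.96 * se)
  )
}

#' Proportional reporting ratio with Wald 95% CI and Pearson chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`;
#' `CI = exp(log PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#' The chi-squared statistic is the Pearson statistic of the 2x2 table on
#' 1 df, without continuity correction unless `correct = TRUE`.
#'
#' @param a,b,c,d cell counts (vectorised).
#' @param correct apply the Yates continuity correction to chi-squared.
#' @return tibble with columns `prr`, `prr_low`, `prr_high`, `chi2`.
#' @export
compute_prr <- function(a, b, c, d, correct = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  ok <- a > 0 & c > 0 & (a + b) > 0 & (c + d) > 0
  prr <- ifelse(ok, (a / (a + b)) / (c / (c + d)), NA_real_)
  se <- ifelse(ok, sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)), NA_real_)
  dev <- abs(a * d - b * c)
  if (correct) dev <- pmax(dev - n / 2, 0)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom > 0, n * dev^2 / denom, NA_real_)
  tibble::tibble(
    prr = prr,
    prr_low = exp(log(prr) - 1.96 * se),
    prr_high = exp(log(prr) + 1.96 * se),
    chi2 = chi2
  )
}

#' BCPNN information component: posterior expectation and variance
#'
#' Closed-form expectation and variance of the information component under
#' the standard Beta priors (`alpha1 = beta1 = 1`, `alpha = beta = 2`,
#' `gamma11 = 1`), with the joint prior weight
#' `gamma = gamma11 (N+alpha)(N+beta) / ((a+b+alpha1)(a+c+beta1))` calibrated
#' to independence. Defined for `a = 0`.
#'
#' @param a,b,c,d cell counts (vectorised).
#' @return tibble with columns `e_ic` (bits), `v_ic`, `ic_minus_2sd`.
#' @export
compute_bcpnn <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  p <- bcpnn_priors
  n <- a + b + c + d
  m1 <- a + b   # drug margin
  m2 <- a + c   # event margin
  gamma <- p$gamma11 * (n + p$alpha) * (n + p$beta) /
    ((m1 + p$alpha1) * (m2 + p$beta1))
  e_ic <- log2((a + p$gamma11) * (n + p$alpha) * (n + p$beta) /
                 ((n + gamma) * (m1 + p$alpha1) * (m2 + p$beta1)))
  v_ic <- (1 / log(2)^2) * (
    (n - a + gamma - p$gamma11) / ((a + p$gamma11) * (1 + n + gamma)) +
      (n - m1 + p$alpha - p$alpha1) / ((m1 + p$alpha1) * (1 + n + p$alpha)) +
      (n - m2 + p$beta - p$beta1) / ((m2 + p$beta1) * (1 + n + p$beta))
  )
  tibble::tibble(e_ic = e_ic, v_ic = v_ic,
                 ic_minus_2sd = e_ic - 2 * sqrt(v_ic))
}

#' Monte-Carlo posterior sampler for the information component
#'
#' Independent oracle for [compute_bcpnn()]: draws from the Beta posteriors
#' of the joint and marginal reporting probabilities under the same priors
#' and averages `log2(p11 / (p1 p2))`. The closed form is the
#' log-of-posterior-means ("expectation") variant, so agreement with the
#' sampled posterior mean is exact only up to an `O(1/a)` Jensen term; for
#' cells of a few dozen reports or more the two agree to ~0.01 bits.
#'
#' @param a,b,c,d scalar cell counts.
#' @param n_draws number of posterior draws.
#' @return list with `e_ic_mc` (posterior mean, bits) and `sd_ic_mc`.
#' @export
sample_bcpnn_posterior <- function(a, b, c, d, n_draws = 1e5) {
  p <- bcpnn_priors
  n <- a + b + c + d
  m1 <- a + b
  m2 <- a + c
  gamma <- p$gamma11 * (n + p$alpha) * (n + p$beta) /
    ((m1 + p$alpha1) * (m2 + p$beta1))
  p11 <- stats::rbeta(n_draws, a + p$gamma11, n - a + gamma - p$gamma11)
  p1 <- stats::rbeta(n_draws, m1 + p$alpha1, n - m1 + p$alpha - p$alpha1)
  p2 <- stats::rbeta(n_draws, m2 + p$beta1, n - m2 + p$beta - p$beta1)
  ic <- log2(p11 / (p1 * p2))
  list(e_ic_mc = mean(ic), sd_ic_mc = stats::sd(ic))
}

#' Classify an information-component expectation into a signal tier
#'
#' `E(IC) <= 0` gives `"-"`; `(0, 1.5]` gives `"+"`; `(1.5, 3]` gives
#' `"++"`; above 3 gives `"+++"`.
#'
#' @param e_ic numeric vector of information-component expectations (bits).
#' @return character vector of tiers.
#' @export
classify_tier <- function(e_ic) {
  stopifnot(all(is.finite(e_ic)))
  ifelse(e_ic <= 0, "-",
         ifelse(e_ic <= 1.5, "+",
                ifelse(e_ic <= 3, "++", "+++")))
}

#' Association test for a 2x2 table with automatic method choice
#'
#' When any expected cell count under independence is below 5, a two-sided
#' Fisher exact p-value is computed by summation of the hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one; otherwise the Pearson chi-squared p-value on 1 df
#' is used. The method actually applied is recorded.
#'
#' @param a,b,c,d scalar cell counts.
#' @param correct continuity correction for the chi-squared branch.
#' @return list with `p_value` and `method` (`"fisher"` or `"chisq"`).
#' @export
association_test <- function(a, b, c, d, correct = FALSE) {
  n <- a + b + c + d
  if (n <= 0) abort("association_test needs a non-empty table.",
                    class = "faerspv_data_error")
  expected <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  if (any(expected < 5)) {
    list(p_value = fisher_exact_p(a, b, c, d), method = "fisher")
  } else {
    chi2 <- compute_prr(a, b, c, d, correct = correct)$chi2
    list(p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
         method = "chisq")
  }
}

# Two-sided Fisher exact p by hypergeometric enumeration: sum the point
# probabilities of all a-cell values compatible with the fixed margins whose
# probability does not exceed the observed one (with a small relative slack
# against ties lost to floating point, as in stats::fisher.test).
fisher_exact_p <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- a + c
  n <- a + b + c + d
  support <- max(0L, m1 + m2 - n):min(m1, m2)
  probs <- dhyper(support, m2, n - m2, m1)
  p_obs <- dhyper(a, m2, n - m2, m1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Evaluate signal positivity per method and jointly
#'
#' Positivity rules: ROR and PRR require `a >= 3` and a lower 95% CI bound
#' above 1; the BCPNN rule defaults to `E(IC) > 0` (the tier threshold), with
#' `IC - 2SD > 0` available as the conservative convention (`bcpnn_gate =
#' "ic2sd"`), which is the calibrated choice for null-rate control.
#' Undefined statistics yield `FALSE` flags.
#'
#' @param stats a one-row tibble/list with fields `a`, `ror_low`, `prr_low`,
#'   `e_ic`, `ic_minus_2sd` (as produced by [signal_stats()]).
#' @param bcpnn_gate `"eic"` or `"ic2sd"`.
#' @return list of logicals `positive_ror`, `positive_prr`,
#'   `positive_bcpnn`, `positive_all`.
#' @export
gate_signal <- function(stats, bcpnn_gate = c("eic", "ic2sd")) {
  bcpnn_gate <- match.arg(bcpnn_gate)
  pos_ror <- isTRUE(stats$a >= 3 && is.finite(stats$ror_low) && stats$ror_low > 1)
  pos_prr <- isTRUE(stats$a >= 3 && is.finite(stats$prr_low) && stats$prr_low > 1)
  crit <- if (bcpnn_gate == "eic") stats$e_ic else stats$ic_minus_2sd
  pos_bcpnn <- isTRUE(is.finite(crit) && crit > 0)
  list(positive_ror = pos_ror, positive_prr = pos_prr,
       positive_bcpnn = pos_bcpnn,
       positive_all = pos_ror && pos_prr && pos_bcpnn)
}

#' All disproportionality statistics for given cell counts
#'
#' Vectorised over cells; combines [compute_ror()], [compute_prr()],
#' [compute_bcpnn()], the tier classification, and the per-method positivity
#' flags into one row per table.
#'
#' @param a,b,c,d cell counts (vectorised).
#' @param bcpnn_gate see [gate_signal()].
#' @param correct continuity correction for chi-squared.
#' @return tibble with cells, `ror*`, `prr*`, `chi2`, `e_ic`, `v_ic`,
#'   `ic_minus_2sd`, `tier`, and the four positivity flags.
#' @export
signal_stats <- function(a, b, c, d, bcpnn_gate = c("eic", "ic2sd"),
                         correct = FALSE) {
  bcpnn_gate <- match.arg(bcpnn_gate)
  ror <- compute_ror(a, b, c, d)
  prr <- compute_prr(a, b, c, d, correct = correct)
  bc <- compute_bcpnn(a, b, c, d)
  crit <- if (bcpnn_gate == "eic") bc$e_ic else bc$ic_minus_2sd
  pos_ror <- a >= 3 & is.finite(ror$ror_low) & ror$ror_low > 1
  pos_prr <- a >= 3 & is.finite(prr$prr_low) & prr$prr_low > 1
  pos_bcpnn <- is.finite(crit) & crit > 0
  tibble::tibble(
    a = a, b = b, c = c, d = d,
    ror, prr, bc,
    tier = classify_tier(bc$e_ic),
    positive_ror = pos_ror, positive_prr = pos_prr,
    positive_bcpnn = pos_bcpnn,
    positive_all = pos_ror & pos_prr & pos_bcpnn
  )
}

#' Scan every (drug, event) pair in a cleaned dataset
#'
#' Computes [signal_stats()] for each target drug crossed with each event
#' observed at least once with that drug (`a >= 1`). Rows failing the signal
#' gate are retained with their flags: filtering is presentation-level.
#' Output is sorted by drug, then descending `a`, then event name, and is
#' deterministic for a given input.
#'
#' @param clean a `faers_clean` object.
#' @param drugs canonical drug names to scan; default: all drugs observed as
#'   a matched target in the data.
#' @param event_type `"pt"` (one row per preferred term) or `"category"`
#'   (one row per SMQ category).
#' @param bcpnn_gate,correct passed to [signal_stats()].
#' @param association add exact/chi-squared association p-values per pair.
#' @return tibble with `drug`, `event`, cells and statistics.
#' @export
scan_signals <- function(clean, drugs = NULL,
                         event_type = c("pt", "category"),
                         bcpnn_gate = c("eic", "ic2sd"),
                         correct = FALSE, association = FALSE) {
  event_type <- match.arg(event_type)
  bcpnn_gate <- match.arg(bcpnn_gate)
  cases <- clean$cases
  if (is.null(drugs)) {
    drugs <- sort(unique(cases$target_drug[!is.na(cases$target_drug)]))
  }
  events_tab <- clean$events |>
    dplyr::distinct(caseid, event = .data[[event_type]])
  n_total <- nrow(cases)
  out <- vector("list", length(drugs))
  for (i in seq_along(drugs)) {
    dg <- drugs[i]
    exposed_ids <- cases$caseid[!is.na(cases$target_drug) &
                                  cases$target_drug == dg]
    n_exposed <- length(exposed_ids)
    ev <- events_tab |>
      dplyr::mutate(exposed = caseid %in% exposed_ids) |>
      dplyr::group_by(event) |>
      dplyr::summarise(a = sum(exposed), m2 = dplyr::n(), .groups = "drop") |>
      dplyr::filter(a >= 1)
    if (!nrow(ev)) next
    a <- ev$a
    b <- n_exposed - a
    c <- ev$m2 - a
    d <- n_total - n_exposed - c
    st <- signal_stats(a, b, c, d, bcpnn_gate = bcpnn_gate, correct = correct)
    st <- tibble::tibble(drug = dg, event = ev$event, st)
    if (association) {
      assoc <- mapply(function(a, b, c, d) {
        at <- association_test(a, b, c, d, correct = correct)
        c(at$p_value, at$method)
      }, a, b, c, d)
      st$assoc_p <- as.numeric(assoc[1, ])
      st$assoc_method <- assoc[2, ]
    }
    out[[i]] <- st |> dplyr::arrange(dplyr::desc(a), event)
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(drug = character(0), event = character(0),
                          signal_stats(integer(0), integer(0), integer(0),
                                       integer(0)))
    if (association) {
      res$assoc_p <- numeric(0)
      res$assoc_method <- character(0)
    }
  }
  res
}
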
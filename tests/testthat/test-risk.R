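test_that("univariable ORs equal the closed-form cross-product ratio", {
  counts <- readr::read_csv(faerspv_fixture("univariable_counts"),
                            show_col_types = FALSE)
  # one covariate from the published table: drug, reference Avatrombopag
  sub <- counts[counts$covariate == "DRUG", ]
  inp <- expand_count_table(sub[, c("level", "n_control", "n_case")],
                            covariate = "drug")
  fit <- fit_univariable(inp$data, "drug", weights = inp$weights)
  expect_equal(round(fit$or[fit$level == "Eltrombopag"], 2), 0.42)
  expect_equal(round(fit$or[fit$level == "Romiplostim"], 2), 0.30)
  expect_equal(fit$or[fit$reference], 1)

  # MLE identity: fitted OR vs cross-product, to 1e-6 relative
  ref <- sub[1, ]
  for (j in 2:3) {
    want <- (sub$n_case[j] * ref$n_control) / (sub$n_control[j] * ref$n_case)
    expect_equal(fit$or[j], want, tolerance = 1e-6)
  }

  # identical outcome rates give OR 1
  eq <- expand_count_table(
    data.frame(level = c("x0", "x1"), n_control = c(900, 450),
               n_case = c(100, 50)), covariate = "g")
  f_eq <- fit_univariable(eq$data, "g", weights = eq$weights)
  expect_equal(f_eq$or[2], 1, tolerance = 1e-9)
})

test_that("cross-product identity holds across random count tables", {
  tabs <- withr::with_seed(61, {
    lapply(1:20, function(i) {
      data.frame(level = c("ref", "l1", "l2"),
                 n_control = sample(20:500, 3),
                 n_case = sample(5:200, 3))
    })
  })
  for (tb in tabs) {
    inp <- expand_count_table(tb, covariate = "x")
    fit <- fit_univariable(inp$data, "x", weights = inp$weights)
    for (j in 2:3) {
      want <- (tb$n_case[j] * tb$n_control[1]) / (tb$n_control[j] * tb$n_case[1])
      expect_equal(fit$or[j], want, tolerance = 1e-6)
    }
  }
})

test_that("separation is flagged as non-estimable", {
  inp <- expand_count_table(
    data.frame(level = c("ref", "sep"), n_control = c(100, 50),
               n_case = c(20, 0)), covariate = "x")
  fit <- suppressWarnings(fit_univariable(inp$data, "x", weights = inp$weights))
  expect_false(fit$estimable[fit$level == "sep"])
})

test_that("the covariate screen keys on level-wise Wald p-values", {
  make_fit <- function(p) {
    tibble::tibble(covariate = "x", level = c("ref", "l1"),
                   reference = c(TRUE, FALSE), p_value = c(NA, p))
  }
  fits <- list(strong = make_fit(0.001), weak = make_fit(0.5))
  expect_equal(screen_covariates(fits), "strong")
  expect_equal(screen_covariates(fits, alpha = 1), c("strong", "weak"))
  expect_error(screen_covariates(fits, alpha = 0),
               class = "faerspv_config_error")
})

test_that("a single-covariate multivariable fit equals the univariable fit", {
  dat <- withr::with_seed(62, {
    x <- factor(sample(c("a", "b", "c"), 4000, replace = TRUE))
    p <- c(a = 0.1, b = 0.2, c = 0.3)[as.character(x)]
    tibble::tibble(y = rbinom(4000, 1, p), x = x)
  })
  f1 <- fit_univariable(dat, "x")
  f2 <- fit_multivariable(dat, "x")
  expect_equal(f2$or, f1$or, tolerance = 1e-6)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-6)

  # permutation invariance
  f3 <- fit_multivariable(dat[withr::with_seed(1, sample(nrow(dat))), ], "x")
  expect_equal(f3$or, f2$or, tolerance = 1e-10)
})

test_that("planted multivariable coefficients are recovered", {
  beta <- c(log(5), log(1.5), log(0.3))
  dat <- withr::with_seed(63, {
    n <- 50000
    x1 <- rbinom(n, 1, 0.5)
    x2 <- rbinom(n, 1, 0.3)
    x3 <- rbinom(n, 1, 0.2)
    eta <- -2 + beta[1] * x1 + beta[2] * x2 + beta[3] * x3
    tibble::tibble(y = rbinom(n, 1, stats::plogis(eta)),
                   x1 = factor(x1), x2 = factor(x2), x3 = factor(x3))
  })
  fit <- fit_multivariable(dat, c("x1", "x2", "x3"))
  est <- log(fit$or[!fit$reference])
  se <- (log(fit$or_high) - log(fit$or_low))[!fit$reference] / (2 * 1.96)
  expect_true(all(abs(est - beta) < 4 * se))
  expect_true(attr(fit, "converged"))
})

test_that("adjusted ORs match crude ORs for independent mild covariates", {
  # logistic non-collapsibility is negligible at these effect sizes, so
  # orthogonally assigned covariates should give adjusted ~ crude
  dat <- withr::with_seed(64, {
    n <- 40000
    x1 <- rbinom(n, 1, 0.5)
    x2 <- rbinom(n, 1, 0.5)
    eta <- -2.2 + log(1.3) * x1 + log(1.25) * x2
    tibble::tibble(y = rbinom(n, 1, stats::plogis(eta)),
                   x1 = factor(x1), x2 = factor(x2))
  })
  crude <- fit_univariable(dat, "x1")
  adj <- fit_multivariable(dat, c("x1", "x2"))
  expect_equal(log(adj$or[adj$covariate == "x1" & !adj$reference]),
               log(crude$or[!crude$reference]),
               tolerance = 0.08)
})

test_that("model input assembles outcome and covariates from cleaned cases", {
  g <- generate_faers_reports(faers_sim_config(n_cases = 2500, seed = 65))
  cl <- suppressWarnings(build_clean_cases(g$tables, bundled_dict(),
                                           bundled_smq()))
  mi <- make_model_input(cl)
  expect_equal(nrow(mi), sum(!is.na(cl$cases$target_drug)))
  expect_true(all(levels(mi$drug) ==
                    sort(unique(cl$cases$target_drug[!is.na(cl$cases$target_drug)]))))
  expect_true(all(mi$y %in% 0:1))
  expect_equal(mean(mi$y),
               mean(cl$cases$any_event[!is.na(cl$cases$target_drug)]))
})
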
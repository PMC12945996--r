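test_that("contingency cells enumerate exposed/background event counts", {
  tabs <- tiny_tables(list(
    list(caseid = 1, drug = "Drugexol", role = "PS", pts = "Pulmonary embolism"),
    list(caseid = 2, drug = "Drugexol", role = "PS", pts = "Headache"),
    list(caseid = 3, drug = "Otherdrug", role = "PS", pts = "Pulmonary embolism"),
    list(caseid = 4, drug = "Otherdrug", role = "PS", pts = "Headache")
  ))
  cl <- build_clean_cases(tabs, tiny_dict(), tiny_smq())
  ct <- build_contingency(cl, "Drugex", "Pulmonary embolism")
  expect_equal(unlist(ct[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))
  expect_false(ct$flagged)

  # absent target drug: flagged table with an empty exposed margin
  ct2 <- build_contingency(cl, "Ghostex", "Pulmonary embolism")
  expect_true(ct2$flagged)
  expect_equal(ct2$a + ct2$b, 0)

  empty <- structure(list(cases = cl$cases[0, ], events = cl$events[0, ]),
                     class = "faers_clean")
  expect_error(build_contingency(empty, "Drugex", "Pulmonary embolism"),
               class = "faerspv_data_error")
})

test_that("reporting odds ratio matches the cross-product and its Wald CI", {
  r <- compute_ror(10, 10, 10, 10)
  expect_equal(r$ror, 1)
  expect_equal(log(r$ror_low), -log(r$ror_high))   # symmetric on log scale

  # published-count check: cross-product of a printed 2x2 rounds to 4.86
  expect_equal(round(compute_ror(4812, 27788, 143, 4011)$ror, 2), 4.86)

  # hand-evaluated formula: ror = 4, se = sqrt(1/10+1/20+1/30+1/240)
  r2 <- compute_ror(10, 20, 30, 240)
  expect_equal(r2$ror, 4)
  expect_equal(r2$ror_low, 1.711875, tolerance = 1e-6)
  expect_equal(r2$ror_high, 9.346475, tolerance = 1e-6)

  # zero cell: undefined, never positive
  r3 <- compute_ror(0, 10, 10, 10)
  expect_true(is.na(r3$ror))
  st <- signal_stats(0, 10, 10, 10)
  expect_false(st$positive_ror)
})

test_that("PRR and the Pearson statistic match independent arithmetic", {
  # proportional margins: prr = 1, chi2 = 0
  p0 <- compute_prr(10, 90, 20, 180)
  expect_equal(p0$prr, 1)
  expect_equal(p0$chi2, 0)

  p1 <- compute_prr(10, 90, 10, 890)
  expect_equal(p1$prr, 9)
  expect_equal(p1$chi2, pearson_chi2_oracle(10, 90, 10, 890))

  # continuity-corrected variant agrees with the corrected oracle
  p2 <- compute_prr(10, 90, 10, 890, correct = TRUE)
  expect_equal(p2$chi2,
               unname(suppressWarnings(
                 stats::chisq.test(matrix(c(10, 90, 10, 890), 2,
                                          byrow = TRUE)))$statistic))

  tabs <- random_tables(50)
  with(tabs, {
    got <- compute_prr(a, b, c, d)$chi2
    want <- mapply(pearson_chi2_oracle, a, b, c, d)
    expect_equal(got, want, tolerance = 1e-10)
  })
})

test_that("BCPNN expectation matches closed form, sampler, and shrinkage", {
  # near-independence at scale: E(IC) ~ 0
  b0 <- compute_bcpnn(100, 900, 900, 8100)
  expect_lt(abs(b0$e_ic), 0.05)

  # frozen value for (25, 75, 75, 825), hand-evaluated from the closed form
  b1 <- compute_bcpnn(25, 75, 75, 825)
  expect_equal(b1$e_ic, 1.220133, tolerance = 1e-5)
  expect_equal(b1$ic_minus_2sd, b1$e_ic - 2 * sqrt(b1$v_ic))

  # Monte-Carlo posterior cross-check
  mc <- withr::with_seed(31, sample_bcpnn_posterior(25, 75, 75, 825,
                                                    n_draws = 2e5))
  expect_equal(b1$e_ic, mc$e_ic_mc, tolerance = 0.02)

  # shrinkage toward zero relative to the raw information component
  tabs <- random_tables(100, seed = 32)
  with(tabs, {
    n <- a + b + c + d
    raw <- log2(a * n / ((a + b) * (a + c)))
    e <- compute_bcpnn(a, b, c, d)$e_ic
    expect_true(all(abs(e) <= abs(raw) + 0.02))
  })

  # posterior variance vanishes as all cells scale up
  v <- vapply(c(1, 10, 100, 1000),
              function(k) compute_bcpnn(10 * k, 90 * k, 90 * k, 810 * k)$v_ic,
              numeric(1))
  expect_true(all(diff(v) < 0))
  expect_lt(v[4], 5e-4)
})

test_that("tier classification uses the inclusive expectation thresholds", {
  expect_equal(classify_tier(c(-0.5, 0, 1.5, 1.51, 3, 3.2)),
               c("-", "-", "+", "++", "++", "+++"))
  expect_error(classify_tier(NA_real_))
})

test_that("signal gate needs a >= 3 plus positive lower bounds on all methods", {
  # two reports with a huge ROR still fail the gate
  st <- signal_stats(2, 1, 1, 1000)
  g <- gate_signal(st)
  expect_false(g$positive_ror)
  expect_false(g$positive_all)

  # independence: nothing flags
  st0 <- signal_stats(10, 90, 100, 900)
  g0 <- gate_signal(st0)
  expect_false(any(unlist(g0)))

  # a clear signal flags under both BCPNN gate conventions
  st1 <- signal_stats(30, 70, 50, 1850)
  expect_true(gate_signal(st1)$positive_all)
  expect_true(gate_signal(st1, bcpnn_gate = "ic2sd")$positive_all)
})

test_that("association test picks Fisher under small expected counts", {
  at <- association_test(1, 9, 2, 8)
  expect_equal(at$method, "fisher")

  at2 <- association_test(50, 50, 50, 50)
  expect_equal(at2$method, "chisq")
  expect_equal(at2$p_value, 1)

  at3 <- association_test(3, 7, 2, 18)
  expect_equal(at3$method, "fisher")
  expect_equal(at3$p_value, fisher_bruteforce_oracle(3, 7, 2, 18),
               tolerance = 1e-12)
  expect_equal(at3$p_value,
               stats::fisher.test(matrix(c(3, 7, 2, 18), 2, byrow = TRUE))$p.value,
               tolerance = 1e-9)

  # exact and asymptotic p converge once every expected count is large
  # (at minimum expected counts near 50 the two-sided conventions still
  # disagree by up to ~0.03, so the check uses well-filled tables)
  tabs <- withr::with_seed(34, {
    tibble::tibble(a = sample(300:900, 10), b = sample(3000:9000, 10),
                   c = sample(300:900, 10), d = sample(3000:9000, 10))
  })
  with(tabs, {
    p_f <- mapply(faerspv:::fisher_exact_p, a, b, c, d)
    p_c <- pchisq(compute_prr(a, b, c, d)$chi2, 1, lower.tail = FALSE)
    expect_lt(max(abs(p_f - p_c)), 0.02)
  })
})

test_that("transposition symmetry and the ROR >= PRR identity hold", {
  tabs <- random_tables(100, seed = 33)
  with(tabs, {
    r <- compute_ror(a, b, c, d)$ror
    r_t <- compute_ror(a, c, b, d)$ror    # swap drug/event roles
    expect_equal(r, r_t)                  # OR is transpose-invariant
    expect_equal(compute_ror(b, a, d, c)$ror, 1 / r)  # complement inversion

    prr <- compute_prr(a, b, c, d)$prr
    up <- r > 1
    expect_true(all(r[up] >= prr[up] - 1e-12))
  })
})

test_that("signal scan is deterministic and covers observed pairs", {
  g <- generate_faers_reports(faers_sim_config(n_cases = 1200, seed = 41))
  cl <- suppressWarnings(build_clean_cases(g$tables, bundled_dict(),
                                           bundled_smq()))
  s1 <- scan_signals(cl)
  s2 <- scan_signals(cl)
  expect_identical(s1, s2)
  expect_true(all(s1$a >= 1))

  # row count equals the ground-truth number of exposed (drug, PT) pairs
  truth <- g$truth
  exposed <- truth$cases[truth$cases$role == "PS" &
                           truth$cases$drug %in%
                           c("Avatrombopag", "Eltrombopag", "Romiplostim"), ]
  te_pts <- smq_map(faerspv_fixture("smq_map"))$table$pt
  pair_counts <- merge(truth$events, exposed, by = "caseid")
  pair_counts <- pair_counts[pair_counts$pt %in% te_pts, ]
  want <- nrow(unique(pair_counts[, c("drug", "pt")]))
  expect_equal(nrow(s1), want)

  # category-level scan aggregates PTs
  sc <- scan_signals(cl, event_type = "category")
  expect_true(all(sc$event %in% c("venous_thromboembolic",
                                  "arterial_thromboembolic",
                                  "mixed_other_embolic")))
  expect_true(all(sc$a >= 1))
})
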
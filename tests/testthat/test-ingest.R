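test_that("the dialect reader enforces the header and counts malformed rows", {
  dir <- withr::local_tempdir()
  writeLines("primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$wt$wt_cod$reporter_country$occp_cod",
             file.path(dir, "DEMO.txt"))
  writeLines(c("primaryid$caseid$drug_seq$role_cod$drugname",
               "101$1$1$PS$Drugexol",
               "102$2$1$PS$Brandex$EXTRA"),
             file.path(dir, "DRUG.txt"))
  writeLines(c("primaryid$caseid$pt", "101$1$Pulmonary embolism"),
             file.path(dir, "REAC.txt"))
  writeLines("primaryid$caseid$dsg_drug_seq$start_dt",
             file.path(dir, "THER.txt"))

  expect_warning(tabs <- read_faers_tables(dir), "malformed")
  expect_equal(nrow(tabs$demo), 0L)
  expect_equal(attr(tabs$demo, "n_malformed"), 0L)
  expect_equal(nrow(tabs$drug), 1L)          # malformed row rejected
  expect_equal(attr(tabs$drug, "n_malformed"), 1L)

  # missing mandatory column is a format error naming file and column
  writeLines(c("primaryid$caseid", "101$1"), file.path(dir, "REAC.txt"))
  expect_error(suppressWarnings(read_faers_tables(dir)), regexp = "REAC.*pt",
               class = "faerspv_format_error")
})

test_that("deduplication keeps latest FDA date, then highest PRIMARYID", {
  demo <- tibble::tibble(
    primaryid = c(1, 2, 7, 9, 5),
    caseid = c("A", "A", "B", "B", "C"),
    fda_dt = c("20230101", "20230301", "20230101", "20230101", "20220601")
  )
  out <- deduplicate_cases(demo)
  expect_equal(out$primaryid, c(2, 9, 5))
  expect_equal(out$caseid, c("A", "B", "C"))

  # idempotence and permutation invariance
  expect_identical(deduplicate_cases(out), out)
  for (s in 1:5) {
    shuffled <- demo[withr::with_seed(s, sample(nrow(demo))), ]
    expect_identical(deduplicate_cases(shuffled), out)
  }
})

test_that("partial FDA dates order with missing components earliest", {
  demo <- tibble::tibble(
    primaryid = c(1, 2, 3),
    caseid = c("A", "A", "A"),
    fda_dt = c("202303", "20230301", "2023")
  )
  # 2023 < 202303 < 20230301
  expect_equal(deduplicate_cases(demo)$primaryid, 2)
})

test_that("drug matching is exact-synonym with whitespace/case folding", {
  dict <- bundled_dict()
  expect_equal(match_drug(" ELTROMBOPAG ", dict), "Eltrombopag")
  expect_equal(match_drug("Promacta", dict), "Eltrombopag")
  expect_equal(match_drug("doptelet", dict), "Avatrombopag")
  expect_equal(match_drug("nplate", dict), "Romiplostim")
  expect_equal(match_drug("eltrombopag  olamine", dict), "Eltrombopag")
  expect_true(is.na(match_drug("eltrombopag olamine tablet", dict)))
  expect_true(is.na(match_drug("Aspirin", dict)))
  expect_error(drug_dictionary(data.frame(canonical = "x", wrong = "y")),
               class = "faerspv_format_error")
})

test_that("event mapping respects the map and the scope", {
  sm <- tiny_smq()
  got <- map_events(c("Pulmonary embolism", "Headache", "Broadterm"), sm)
  expect_equal(got$pt, "Pulmonary embolism")
  expect_equal(got$category, "venous")
  both <- map_events(c("Pulmonary embolism", "Broadterm"), sm,
                     scope = "narrow+broad")
  expect_equal(nrow(both), 2L)
  # case-insensitive PT matching, map spelling returned
  expect_equal(map_events("PULMONARY EMBOLISM", sm)$pt, "Pulmonary embolism")
})

test_that("age normalisation converts units and rejects implausible values", {
  expect_equal(normalize_age(24, "MON"), 2)
  expect_equal(normalize_age(730, "DY"), 730 / 365.25)
  expect_equal(normalize_age(50, "YR"), 50)
  expect_equal(normalize_age(5, "DEC"), 50)
  expect_warning(out <- normalize_age(c(-4, 500, 30), c("YR", "YR", "YR")))
  expect_equal(out, c(NA, NA, 30))
  expect_warning(out2 <- normalize_age(10, "FORTNIGHT"))
  expect_true(is.na(out2))
})

test_that("weight normalisation converts pounds and rejects implausible values", {
  expect_equal(normalize_weight(70, "KG"), 70)
  expect_equal(normalize_weight(220, "LBS"), 220 * 0.45359237)
  expect_warning(out <- normalize_weight(-5, "KG"))
  expect_true(is.na(out))
})

test_that("covariate bins follow the declared boundary conventions", {
  ages <- bin_covariates(age_yr = c(17.9, 18, 64.9, 65, 84.9, 85, NA))$age_group
  expect_equal(as.character(ages),
               c("<18", "18-65", "18-65", "65-85", "65-85", ">85", NA))
  wts <- bin_covariates(wt_kg = c(49.9, 50, 100, 100.1, NA))$wt_group
  expect_equal(as.character(wts), c("<50", "50-100", "50-100", ">100", NA))
  dur <- bin_covariates(duration_days = c(0, 364, 365, 730, 731))$duration_group
  expect_equal(as.character(dur), c("<365", "<365", "365-730", "365-730", ">730"))
})

test_that("role policy drives which cases count as exposed", {
  tabs <- tiny_tables(list(
    list(caseid = 1, drug = "Drugexol", role = "C",
         pts = "Pulmonary embolism"),
    list(caseid = 2, drug = c("Drugexol", "Drugexol"), role = c("PS", "C"),
         pts = "Pulmonary embolism"),
    list(caseid = 3, drug = "Brandex", role = "SS", pts = "Headache"),
    list(caseid = 4, drug = "Otherdrug", role = "PS", pts = "Headache")
  ))
  cl <- build_clean_cases(tabs, tiny_dict(), tiny_smq())
  expect_equal(cl$cases$target_drug,
               c(NA, "Drugex", NA, NA))
  expect_equal(cl$cases$excluded_by_role, c(TRUE, FALSE, TRUE, FALSE))

  cl2 <- build_clean_cases(tabs, tiny_dict(), tiny_smq(),
                           allowed_roles = c("PS", "SS"))
  expect_equal(cl2$cases$target_drug[3], "Drugex")

  expect_error(build_clean_cases(tabs, tiny_dict(), tiny_smq(),
                                 allowed_roles = character(0)),
               class = "faerspv_config_error")

  # flow-count conservation
  lg <- cl$log
  expect_equal(lg$cases_in,
               lg$cases_retained + lg$cases_excluded_by_role +
                 lg$cases_without_target_drug)
})

test_that("filter_by_role selects caseids carrying an allowed role", {
  rows <- tibble::tibble(
    caseid = c(1, 1, 2, 3),
    role_cod = c("C", "PS", "C", "SS"),
    canonical = c("Drugex", "Drugex", "Drugex", "Drugex")
  )
  expect_equal(filter_by_role(rows), 1)
  expect_equal(filter_by_role(rows, c("PS", "SS")), c(1, 3))
  expect_error(filter_by_role(rows, character(0)),
               class = "faerspv_config_error")
})

test_that("cleaning a generated database reproduces ground-truth bookkeeping", {
  g <- generate_faers_reports(
    faers_sim_config(n_cases = 1500, seed = 21))
  cl <- suppressWarnings(build_clean_cases(g$tables, bundled_dict(),
                                           bundled_smq()))
  # one row per case, truth alignment of the suspect drug for PS cases
  expect_equal(nrow(cl$cases), 1500)
  truth <- g$truth$cases
  ps_target <- truth$drug %in% c("Avatrombopag", "Eltrombopag", "Romiplostim") &
    truth$role == "PS"
  expect_equal(sum(!is.na(cl$cases$target_drug)), sum(ps_target))
  got <- cl$cases$target_drug[match(truth$caseid[ps_target], cl$cases$caseid)]
  expect_equal(got, truth$drug[ps_target])
})
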
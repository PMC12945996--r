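# Shared fixtures: everything is built in code at test time.

bundled_dict <- function() drug_dictionary(faerspv_fixture("drug_dictionary"))
bundled_smq <- function() smq_map(faerspv_fixture("smq_map"))

tiny_dict <- function() {
  drug_dictionary(data.frame(
    canonical = c("Drugex", "Drugex"),
    synonym = c("Drugexol", "Brandex")
  ))
}

tiny_smq <- function() {
  smq_map(data.frame(
    pt = c("Pulmonary embolism", "Deep vein thrombosis", "Broadterm"),
    category = c("venous", "venous", "venous"),
    scope = c("narrow", "narrow", "broad")
  ))
}

# Minimal raw-table set built by hand. `spec` is a list of case descriptors:
# list(caseid=, drug=, role=, pts=, start=, event=, fda=)
tiny_tables <- function(spec) {
  demo <- drug <- reac <- ther <- list()
  for (s in spec) {
    pid <- s$caseid * 100 + 1
    demo[[length(demo) + 1]] <- tibble::tibble(
      primaryid = pid, caseid = s$caseid,
      fda_dt = s$fda %||% "20230101", event_dt = s$event %||% NA_character_,
      age = s$age %||% NA_real_, age_cod = s$age_cod %||% NA_character_,
      sex = s$sex %||% NA_character_, wt = NA_real_, wt_cod = NA_character_,
      reporter_country = "US", occp_cod = "MD"
    )
    drug[[length(drug) + 1]] <- tibble::tibble(
      primaryid = pid, caseid = s$caseid,
      drug_seq = seq_along(s$drug), role_cod = s$role, drugname = s$drug
    )
    reac[[length(reac) + 1]] <- tibble::tibble(
      primaryid = pid, caseid = s$caseid, pt = s$pts
    )
    if (!is.null(s$start)) {
      ther[[length(ther) + 1]] <- tibble::tibble(
        primaryid = pid, caseid = s$caseid, dsg_drug_seq = 1,
        start_dt = s$start
      )
    }
  }
  empty_ther <- tibble::tibble(primaryid = numeric(), caseid = numeric(),
                               dsg_drug_seq = numeric(), start_dt = character())
  list(
    demo = dplyr::bind_rows(demo), drug = dplyr::bind_rows(drug),
    reac = dplyr::bind_rows(reac),
    ther = if (length(ther)) dplyr::bind_rows(ther) else empty_ther
  )
}

# random 2x2 tables with all cells positive, for property checks
random_tables <- function(n, seed = 101) {
  withr::with_seed(seed, {
    tibble::tibble(
      a = sample(1:80, n, replace = TRUE),
      b = sample(1:800, n, replace = TRUE),
      c = sample(1:800, n, replace = TRUE),
      d = sample(100:8000, n, replace = TRUE)
    )
  })
}

# independent textbook Pearson statistic: sum (O - E)^2 / E over the 2x2
pearson_chi2_oracle <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# brute-force two-sided Fisher p: enumerate all tables with the observed
# margins via binomial coefficients (no dhyper)
fisher_bruteforce_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- a + c; n <- a + b + c + d
  support <- max(0, m1 + m2 - n):min(m1, m2)
  logp <- vapply(support, function(k) {
    lchoose(m2, k) + lchoose(n - m2, m1 - k) - lchoose(n, m1)
  }, numeric(1))
  p <- exp(logp)
  p_obs <- p[support == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}
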
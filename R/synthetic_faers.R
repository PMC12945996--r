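# Synthetic spontaneous-report generator.
#
# Emits DEMO/DRUG/REAC/THER tables in the FAERS quarterly dialect together
# with a ground-truth ledger (final case versions, suspect drug, true onset
# day, planted drug-event rate ratios), so that deduplication, drug matching,
# disproportionality statistics and time-to-onset handling can all be tested
# against known answers.

#' Default drug panel for the synthetic generator
#'
#' Three thrombopoietin-receptor agonists (the exposure class of interest,
#' with their brand names as synonyms) plus five unrelated background agents
#' that provide the comparator reporting mass. `share` is the market-share
#' weight with which a report's suspect drug is drawn.
#'
#' @return a tibble with columns `canonical`, `synonyms` (list column),
#'   `share`.
#' @export
default_drug_panel <- function() {
  tibble::tibble(
    canonical = c(
      "Avatrombopag", "Eltrombopag", "Romiplostim",
      "Rituximab", "Prednisone", "Ibrutinib", "Metformin", "Amoxicillin"
    ),
    synonyms = list(
      c("Avatrombopag", "Doptelet"),
      c("Eltrombopag", "Promacta", "Revolade"),
      c("Romiplostim", "Nplate"),
      "Rituximab", "Prednisone", "Ibrutinib", "Metformin", "Amoxicillin"
    ),
    share = c(0.05, 0.25, 0.20, 0.12, 0.12, 0.10, 0.08, 0.08)
  )
}

#' Default event panel for the synthetic generator
#'
#' A short list of thromboembolic preferred terms (those carrying an SMQ
#' category in the bundled map) plus common background PTs. `background_prob`
#' is the per-report probability of the PT being reported when no signal is
#' planted; probabilities were chosen so that, at the default database size,
#' pair counts span the range from a few reports to a few hundred.
#'
#' @return a tibble with columns `pt`, `background_prob`.
#' @export
default_event_panel <- function() {
  tibble::tibble(
    pt = c(
      "Pulmonary embolism", "Deep vein thrombosis",
      "Acute myocardial infarction", "Embolism arterial",
      "Portal vein thrombosis", "Cerebral venous sinus thrombosis",
      "Renal vein thrombosis",
      "Headache", "Nausea", "Fatigue", "Pyrexia", "Rash",
      "Diarrhoea", "Dizziness", "Platelet count decreased", "Epistaxis"
    ),
    background_prob = c(
      0.012, 0.010, 0.008, 0.002, 0.002, 0.001, 0.0008,
      0.10, 0.09, 0.08, 0.06, 0.05, 0.05, 0.04, 0.03, 0.02
    )
  )
}

#' Default demographic model for the synthetic generator
#'
#' Category weights and per-field missingness probabilities chosen to mirror
#' the marginal structure typical of spontaneous-report demographics: roughly
#' 30% missing age, 70% missing weight, an elderly-skewed age distribution,
#' United States as the most common reporting country, and physicians as the
#' dominant reporter occupation.
#'
#' @return a named list of field specifications.
#' @export
default_demographics <- function() {
  list(
    sex = list(levels = c("F", "M"), weights = c(0.54, 0.46), missing = 0.11),
    age = list(mean = 63, sd = 20, min = 1, max = 100, missing = 0.30,
               unit_codes = c(YR = 0.85, MON = 0.05, DY = 0.05, DEC = 0.05)),
    weight = list(mean = 76, sd = 16, min = 35, max = 160, missing = 0.70,
                  unit_codes = c(KG = 0.80, LBS = 0.20)),
    country = list(levels = c("US", "JP", "FR", "CA", "IT", "ES", "DE", "GB"),
                   weights = c(0.38, 0.12, 0.12, 0.10, 0.08, 0.07, 0.07, 0.06),
                   missing = 0.05),
    reporter = list(levels = c("MD", "CN", "HP", "PH"),
                    weights = c(0.50, 0.23, 0.10, 0.05), missing = 0.12)
  )
}

#' Build and validate a synthetic-report generator configuration
#'
#' @param n_cases number of distinct patient cases to emit (`0` allowed).
#' @param drugs drug panel tibble (see [default_drug_panel()]): columns
#'   `canonical`, `synonyms` (list), `share`.
#' @param events event panel tibble (see [default_event_panel()]): columns
#'   `pt`, `background_prob`.
#' @param planted_signals `NULL`, or a tibble/data.frame with columns `drug`,
#'   `pt`, `multiplier` giving the reporting-rate multiplier (>= 0) applied to
#'   that pair's background probability. The default (none) is the global-null
#'   calibration condition: every drug-event pair independent.
#' @param demographics demographic model (see [default_demographics()]).
#' @param duplicate_fraction probability that a case emits 2-4 report
#'   versions sharing a CASEID.
#' @param partial_date_fraction probability that a therapy-start or event date
#'   is emitted without day (or day+month) precision.
#' @param role_weights named probabilities over the role codes
#'   `PS`, `SS`, `C`, `I` for the suspect-drug entry.
#' @param concomitant_prob probability that a report carries an additional
#'   concomitant (role `C`) drug entry.
#' @param therapy list describing the true onset-day distribution; family
#'   `"lognormal"` with `meanlog`, `sdlog`. The default (median 81 days,
#'   quartiles ~25 and ~263 days) reproduces the onset profile reported for
#'   thrombopoietin-receptor agonists.
#' @param therapy_record_prob probability that a report carries a therapy row
#'   with a start date at all.
#' @param missing_event_date_prob probability the event onset date is absent.
#' @param seed integer seed; identical configurations (including seed) give
#'   byte-identical tables.
#' @return a validated object of class `faers_sim_config`.
#' @export
faers_sim_config <- function(n_cases = 5000,
                             drugs = default_drug_panel(),
                             events = default_event_panel(),
                             planted_signals = NULL,
                             demographics = default_demographics(),
                             duplicate_fraction = 0.15,
                             partial_date_fraction = 0.12,
                             role_weights = c(PS = 0.78, SS = 0.10, C = 0.10, I = 0.02),
                             concomitant_prob = 0.30,
                             therapy = list(family = "lognormal",
                                            meanlog = log(81), sdlog = 1.74),
                             therapy_record_prob = 0.85,
                             missing_event_date_prob = 0.15,
                             seed = 1L) {
  stop_cfg <- function(msg) abort(msg, class = "faerspv_config_error")

  if (length(n_cases) != 1L || is.na(n_cases) || n_cases < 0 ||
      n_cases != round(n_cases)) {
    stop_cfg("`n_cases` must be a single non-negative integer.")
  }
  drugs <- tibble::as_tibble(drugs)
  if (!all(c("canonical", "synonyms", "share") %in% names(drugs))) {
    stop_cfg("`drugs` needs columns canonical, synonyms, share.")
  }
  if (any(!is.finite(drugs$share)) || any(drugs$share < 0) ||
      sum(drugs$share) <= 0) {
    stop_cfg("drug `share` weights must be non-negative, finite, and not all zero.")
  }
  events <- tibble::as_tibble(events)
  if (!all(c("pt", "background_prob") %in% names(events))) {
    stop_cfg("`events` needs columns pt, background_prob.")
  }
  if (any(!is.finite(events$background_prob)) ||
      any(events$background_prob < 0 | events$background_prob > 1)) {
    stop_cfg("event background probabilities must lie in [0, 1].")
  }
  if (!is.null(planted_signals)) {
    planted_signals <- tibble::as_tibble(planted_signals)
    if (!all(c("drug", "pt", "multiplier") %in% names(planted_signals))) {
      stop_cfg("`planted_signals` needs columns drug, pt, multiplier.")
    }
    if (any(!is.finite(planted_signals$multiplier)) ||
        any(planted_signals$multiplier < 0)) {
      stop_cfg("planted multipliers must be finite and >= 0.")
    }
    bad <- setdiff(planted_signals$drug, drugs$canonical)
    if (length(bad)) stop_cfg(paste0("planted signal names unknown drug: ", bad[1]))
    bad <- setdiff(planted_signals$pt, events$pt)
    if (length(bad)) stop_cfg(paste0("planted signal names unknown PT: ", bad[1]))
  }
  probs <- c(duplicate_fraction, partial_date_fraction, concomitant_prob,
             therapy_record_prob, missing_event_date_prob)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    stop_cfg("all fraction/probability parameters must lie in [0, 1].")
  }
  if (is.null(names(role_weights)) ||
      !setequal(names(role_weights), c("PS", "SS", "C", "I")) ||
      any(role_weights < 0) || sum(role_weights) <= 0) {
    stop_cfg("`role_weights` must be non-negative weights named PS, SS, C, I.")
  }
  if (!identical(therapy$family, "lognormal")) {
    stop_cfg("only the lognormal onset-day family is implemented.")
  }

  structure(
    list(
      n_cases = as.integer(n_cases), drugs = drugs, events = events,
      planted_signals = planted_signals, demographics = demographics,
      duplicate_fraction = duplicate_fraction,
      partial_date_fraction = partial_date_fraction,
      role_weights = role_weights[c("PS", "SS", "C", "I")],
      concomitant_prob = concomitant_prob, therapy = therapy,
      therapy_record_prob = therapy_record_prob,
      missing_event_date_prob = missing_event_date_prob,
      seed = as.integer(seed)
    ),
    class = "faers_sim_config"
  )
}

empty_faers_tables <- function() {
  list(
    demo = tibble::tibble(
      primaryid = numeric(), caseid = numeric(), fda_dt = character(),
      event_dt = character(), age = numeric(), age_cod = character(),
      sex = character(), wt = numeric(), wt_cod = character(),
      reporter_country = character(), occp_cod = character()
    ),
    drug = tibble::tibble(
      primaryid = numeric(), caseid = numeric(), drug_seq = numeric(),
      role_cod = character(), drugname = character()
    ),
    reac = tibble::tibble(
      primaryid = numeric(), caseid = numeric(), pt = character()
    ),
    ther = tibble::tibble(
      primaryid = numeric(), caseid = numeric(), dsg_drug_seq = numeric(),
      start_dt = character()
    )
  )
}

sample_categorical <- function(n, levels, weights, missing_prob) {
  out <- sample(levels, n, replace = TRUE, prob = weights)
  out[runif(n) < missing_prob] <- NA_character_
  out
}

# Truncated-normal draw by clamping; adequate for demographic noise.
rnorm_clamped <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Generate synthetic FAERS-dialect raw tables with ground truth
#'
#' @param config a [faers_sim_config()] object.
#' @return a list with elements `tables` (named list `demo`, `drug`, `reac`,
#'   `ther` of tibbles in the FAERS column dialect) and `truth` (a list with
#'   `cases` - one row per patient case with final PRIMARYID, suspect drug,
#'   role, true onset day, version count; `events` - one row per true
#'   (case, PT); `pairs` - one row per (drug, PT) with the true
#'   reporting-rate ratio).
#' @export
generate_faers_reports <- function(config) {
  stopifnot(inherits(config, "faers_sim_config"))
  withr::with_seed(config$seed, generate_faers_reports_impl(config))
}

generate_faers_reports_impl <- function(config) {
  n <- config$n_cases
  pairs <- tidyr::expand_grid(
    drug = config$drugs$canonical, pt = config$events$pt
  )
  pairs$multiplier <- 1
  if (!is.null(config$planted_signals)) {
    key <- paste(pairs$drug, pairs$pt, sep = "\r")
    pkey <- paste(config$planted_signals$drug, config$planted_signals$pt, sep = "\r")
    pairs$multiplier[match(pkey, key)] <- config$planted_signals$multiplier
  }
  bg <- config$events$background_prob
  pairs$background_prob <- rep(bg, times = nrow(config$drugs))
  pairs$event_prob <- pmin(pairs$background_prob * pairs$multiplier, 0.95)
  pairs$rate_ratio <- ifelse(pairs$background_prob > 0,
                             pairs$event_prob / pairs$background_prob, NA_real_)

  if (n == 0L) {
    return(list(
      tables = empty_faers_tables(),
      truth = list(
        cases = tibble::tibble(
          caseid = numeric(), final_primaryid = numeric(), drug = character(),
          role = character(), onset_day = numeric(), n_versions = integer()
        ),
        events = tibble::tibble(caseid = numeric(), pt = character()),
        pairs = pairs
      )
    ))
  }

  caseid <- 10000000 + seq_len(n)
  drug_idx <- sample.int(nrow(config$drugs), n, replace = TRUE,
                         prob = config$drugs$share)
  drug_canonical <- config$drugs$canonical[drug_idx]
  role <- sample(names(config$role_weights), n, replace = TRUE,
                 prob = config$role_weights)

  # verbatim drug names: random synonym, randomly upper-cased, occasional
  # stray whitespace -- exercises the ingest-side normalisation
  syns <- config$drugs$synonyms
  verbatim <- vapply(drug_idx, function(i) sample(syns[[i]], 1L), character(1))
  up <- runif(n) < 0.5
  verbatim[up] <- toupper(verbatim[up])
  pad <- runif(n) < 0.05
  verbatim[pad] <- paste0(" ", verbatim[pad], " ")

  # reactions: independent Bernoulli per PT with planted multipliers on the
  # suspect drug; every report gets at least one PT
  k <- nrow(config$events)
  pmat <- matrix(pairs$event_prob, nrow = nrow(config$drugs), ncol = k,
                 byrow = TRUE)[drug_idx, , drop = FALSE]
  hit <- matrix(runif(n * k), n, k) < pmat
  ev_case <- rep(caseid, times = k)[as.vector(hit)]
  ev_pt <- rep(config$events$pt, each = n)[as.vector(hit)]
  # a report always carries >= 1 reaction; cases where no panel PT fired get
  # a dedicated filler PT instead of a redraw, so the realised panel-PT
  # probabilities stay exactly background x multiplier for every drug
  none <- !rowSums(hit)
  if (any(none)) {
    ev_case <- c(ev_case, caseid[none])
    ev_pt <- c(ev_pt, rep("Drug ineffective", sum(none)))
  }
  truth_events <- tibble::tibble(caseid = ev_case, pt = ev_pt) |>
    dplyr::arrange(caseid, pt)

  dm <- config$demographics
  sex <- sample_categorical(n, dm$sex$levels, dm$sex$weights, dm$sex$missing)
  age_yr <- rnorm_clamped(n, dm$age$mean, dm$age$sd, dm$age$min, dm$age$max)
  age_cod <- sample(names(dm$age$unit_codes), n, replace = TRUE,
                    prob = dm$age$unit_codes)
  age_val <- round(age_yr * c(YR = 1, MON = 12, DY = 365.25, DEC = 0.1)[age_cod], 1)
  age_missing <- runif(n) < dm$age$missing
  age_val[age_missing] <- NA_real_
  age_cod[age_missing] <- NA_character_

  wt_kg <- rnorm_clamped(n, dm$weight$mean, dm$weight$sd, dm$weight$min, dm$weight$max)
  wt_cod <- sample(names(dm$weight$unit_codes), n, replace = TRUE,
                   prob = dm$weight$unit_codes)
  wt_val <- round(ifelse(wt_cod == "KG", wt_kg, wt_kg / 0.45359237), 1)
  wt_missing <- runif(n) < dm$weight$missing
  wt_val[wt_missing] <- NA_real_
  wt_cod[wt_missing] <- NA_character_

  country <- sample_categorical(n, dm$country$levels, dm$country$weights,
                                dm$country$missing)
  reporter <- sample_categorical(n, dm$reporter$levels, dm$reporter$weights,
                                 dm$reporter$missing)

  # calendar scaffold: therapy start, true onset day, event date, FDA receipt
  origin <- as.Date("2009-01-01")
  horizon <- as.integer(as.Date("2024-06-30") - origin)
  start_date <- origin + sample.int(horizon, n, replace = TRUE) - 1L
  onset_day <- pmin(round(rlnorm(n, config$therapy$meanlog, config$therapy$sdlog)), 4000)
  event_date <- start_date + onset_day
  fda_date <- event_date + sample.int(120L, n, replace = TRUE) - 1L

  start_dt <- format_faers_date(start_date)
  event_dt <- format_faers_date(event_date)
  fda_dt <- format_faers_date(fda_date)

  chop <- function(x) {
    sel <- runif(n) < config$partial_date_fraction
    lvl <- sample(c("month", "year"), n, replace = TRUE)
    x[sel] <- ifelse(lvl[sel] == "month",
                     truncate_faers_date(x[sel], "month"),
                     truncate_faers_date(x[sel], "year"))
    x
  }
  start_dt <- chop(start_dt)
  event_dt <- chop(event_dt)
  event_dt[runif(n) < config$missing_event_date_prob] <- NA_character_
  has_ther <- runif(n) < config$therapy_record_prob

  primaryid <- caseid * 100 + 1

  demo <- tibble::tibble(
    primaryid, caseid, fda_dt, event_dt,
    age = age_val, age_cod, sex, wt = wt_val, wt_cod,
    reporter_country = country, occp_cod = reporter
  )

  drug_tab <- tibble::tibble(
    primaryid, caseid, drug_seq = 1, role_cod = role, drugname = verbatim
  )
  conc <- runif(n) < config$concomitant_prob
  if (any(conc)) {
    c_idx <- sample.int(nrow(config$drugs), sum(conc), replace = TRUE,
                        prob = config$drugs$share)
    drug_tab <- dplyr::bind_rows(drug_tab, tibble::tibble(
      primaryid = primaryid[conc], caseid = caseid[conc], drug_seq = 2,
      role_cod = "C",
      drugname = vapply(c_idx, function(i) sample(syns[[i]], 1L), character(1))
    )) |> dplyr::arrange(caseid, drug_seq)
  }

  reac <- truth_events |>
    dplyr::mutate(primaryid = caseid * 100 + 1) |>
    dplyr::select(primaryid, caseid, pt)

  ther <- tibble::tibble(
    primaryid = primaryid[has_ther], caseid = caseid[has_ther],
    dsg_drug_seq = 1, start_dt = start_dt[has_ther]
  )

  tables <- list(demo = demo, drug = drug_tab, reac = reac, ther = ther)
  dup <- plant_duplicates(tables, config$duplicate_fraction)
  truth_cases <- tibble::tibble(
    caseid, drug = drug_canonical, role, onset_day = as.numeric(onset_day)
  ) |>
    dplyr::left_join(dup$dup_map, by = "caseid") |>
    dplyr::arrange(caseid)

  list(
    tables = dup$tables,
    truth = list(cases = truth_cases, events = truth_events, pairs = pairs)
  )
}

#' Expand selected cases into multiple report versions
#'
#' Emulates resubmitted/follow-up reports: each selected case emits 2-4
#' versions sharing its CASEID, with distinct PRIMARYIDs and non-decreasing
#' FDA dates. The final version (latest FDA date; ties broken by highest
#' PRIMARYID) keeps the original field values; earlier versions may mutate
#' weight and reporter occupation so that the deduplication choice is
#' observable.
#'
#' @param tables single-version raw tables as produced internally by
#'   [generate_faers_reports()] (list `demo`, `drug`, `reac`, `ther`).
#' @param duplicate_fraction probability in `[0, 1]` that a case is expanded.
#' @param seed optional integer; when supplied the operation is run under its
#'   own seed, otherwise it consumes the current RNG stream.
#' @return list with `tables` (augmented) and `dup_map` (tibble `caseid`,
#'   `final_primaryid`, `n_versions`).
#' @export
plant_duplicates <- function(tables, duplicate_fraction, seed = NULL) {
  if (duplicate_fraction < 0 || duplicate_fraction > 1) {
    abort("`duplicate_fraction` must lie in [0, 1].",
          class = "faerspv_config_error")
  }
  if (!is.null(seed)) {
    return(withr::with_seed(seed, plant_duplicates(tables, duplicate_fraction)))
  }
  caseids <- tables$demo$caseid
  n <- length(caseids)
  dup_map <- tibble::tibble(
    caseid = caseids,
    final_primaryid = tables$demo$primaryid,
    n_versions = rep(1L, n)
  )
  if (n == 0L || duplicate_fraction == 0) {
    return(list(tables = tables, dup_map = dup_map))
  }
  sel <- runif(n) < duplicate_fraction
  if (!any(sel)) return(list(tables = tables, dup_map = dup_map))

  nver <- integer(n)
  nver[!sel] <- 1L
  nver[sel] <- sample(2:4, sum(sel), replace = TRUE)
  dup_map$n_versions <- nver
  dup_map$final_primaryid <- caseids * 100 + nver

  # expanded version frame for the selected cases: versions 1..nver, the last
  # one carrying the original FDA date, earlier ones pushed back in time
  vcase <- rep(caseids[sel], times = nver[sel])
  vnum <- unlist(lapply(nver[sel], seq_len), use.names = FALSE)
  vtot <- rep(nver[sel], times = nver[sel])
  back <- ifelse(vnum == vtot, 0L,
                 (vtot - vnum) * sample.int(45L, length(vnum), replace = TRUE))
  base_fda <- rep(parse_faers_date(tables$demo$fda_dt[sel]), times = nver[sel])
  vframe <- tibble::tibble(
    caseid = vcase,
    version = vnum,
    primaryid = vcase * 100 + vnum,
    fda_dt = format_faers_date(base_fda - back)
  )

  expand <- function(tab) {
    keep <- tab[!tab$caseid %in% caseids[sel], , drop = FALSE]
    body <- tab[tab$caseid %in% caseids[sel], , drop = FALSE]
    body$primaryid <- NULL
    if ("fda_dt" %in% names(body)) body$fda_dt <- NULL
    out <- dplyr::inner_join(vframe, body, by = "caseid",
                             relationship = "many-to-many")
    out <- out[, setdiff(names(out), "version"), drop = FALSE]
    dplyr::bind_rows(keep, out[, names(tab), drop = FALSE]) |>
      dplyr::arrange(caseid, primaryid)
  }

  demo2 <- expand(tables$demo)
  # mutate non-key fields on non-final versions so tie-breaking is observable
  nonfinal <- !demo2$primaryid %in% dup_map$final_primaryid &
    demo2$caseid %in% caseids[sel]
  touch_wt <- nonfinal & runif(nrow(demo2)) < 0.3
  demo2$wt[touch_wt] <- NA_real_
  demo2$wt_cod[touch_wt] <- NA_character_
  touch_rep <- nonfinal & runif(nrow(demo2)) < 0.3
  demo2$occp_cod[touch_rep] <- "CN"

  list(
    tables = list(demo = demo2, drug = expand(tables$drug),
                  reac = expand(tables$reac), ther = expand(tables$ther)),
    dup_map = dup_map
  )
}

#' Planted-signal recovery scenario
#'
#' A generator configuration used to validate signal recovery: a rate
#' multiplier of 8 planted on (Avatrombopag, Embolism arterial), a pair with
#' a low background probability so that the reporting odds ratio and the
#' planted rate ratio essentially coincide, and a primary-suspect-only role
#' mix (`PS = 1`), under which every exposed report is analysable by the
#' default role policy and the planted ratio is the exact oracle for the
#' estimate. Expected exposed-event count is ~24 reports at the default
#' size.
#'
#' @param seed generator seed.
#' @param n_cases database size.
#' @param multiplier planted reporting-rate multiplier.
#' @return a [faers_sim_config()].
#' @export
recovery_scenario <- function(seed, n_cases = 30000, multiplier = 8) {
  faers_sim_config(
    n_cases = n_cases,
    planted_signals = tibble::tibble(
      drug = "Avatrombopag", pt = "Embolism arterial",
      multiplier = multiplier
    ),
    role_weights = c(PS = 1, SS = 0, C = 0, I = 0),
    seed = seed
  )
}

#' Write raw tables in the FAERS quarterly ASCII dialect
#'
#' "$"-delimited, first line a header, one file per table
#' (`DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt`). Missing values are
#' written as empty fields. Output is byte-deterministic for a given input.
#'
#' @param tables named list of tibbles (`demo`, `drug`, `reac`, `ther`).
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_faers_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("demo", "drug", "reac", "ther")) {
    tab <- tables[[nm]]
    path <- file.path(dir, paste0(toupper(nm), ".txt"))
    cells <- vapply(tab, function(col) {
      x <- if (is.numeric(col)) {
        ifelse(is.na(col), "", format(col, trim = TRUE, scientific = FALSE))
      } else {
        ifelse(is.na(col), "", as.character(col))
      }
      x
    }, character(nrow(tab)))
    if (nrow(tab) == 1L) cells <- matrix(cells, nrow = 1L)
    lines <- c(
      paste(names(tab), collapse = "$"),
      if (nrow(tab)) apply(cells, 1L, paste, collapse = "$")
    )
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Serialize generator ground truth as CSV files plus a YAML sidecar
#'
#' @param truth the `truth` element returned by [generate_faers_reports()].
#' @param dir output directory.
#' @param config optional [faers_sim_config()] echoed into the sidecar.
#' @return invisibly, the paths written.
#' @export
write_ground_truth <- function(truth, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "truth_cases.csv")
  p2 <- file.path(dir, "truth_events.csv")
  p3 <- file.path(dir, "truth_pairs.csv")
  readr::write_csv(truth$cases, p1)
  readr::write_csv(truth$events, p2)
  readr::write_csv(truth$pairs, p3)
  side <- list(
    files = basename(c(p1, p2, p3)),
    n_cases = nrow(truth$cases),
    generator = if (!is.null(config)) {
      list(n_cases = config$n_cases, seed = config$seed,
           duplicate_fraction = config$duplicate_fraction,
           partial_date_fraction = config$partial_date_fraction)
    }
  )
  p4 <- file.path(dir, "truth.yaml")
  yaml::write_yaml(side, p4)
  invisible(c(p1, p2, p3, p4))
}
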
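# Pipeline orchestration: raw tables (read or simulated) -> cleaned cases ->
# demographics, signal scan, time-to-onset, logistic models -> CSV bundle
# with a run manifest. Every output file carries the manifest hash in a
# leading comment line so a bundle can be traced to its exact configuration.

#' Bundled fixture paths
#'
#' The package ships a drug-synonym dictionary for the three
#' thrombopoietin-receptor agonists and a synthetic PT-to-SMQ map assigning
#' 45 thromboembolic preferred terms to venous / arterial / mixed-other
#' categories (a working stand-in for the licensed MedDRA SMQ dictionary,
#' which cannot be redistributed; the category assignment is the package's
#' own and is flagged as such).
#'
#' @param which `"drug_dictionary"`, `"smq_map"`, `"univariable_counts"`,
#'   `"tto_bins"`, or `"report_counts"`.
#' @return path to the installed CSV file.
#' @export
faerspv_fixture <- function(which = c("drug_dictionary", "smq_map",
                                      "univariable_counts", "tto_bins",
                                      "report_counts")) {
  which <- match.arg(which)
  fname <- c(
    drug_dictionary = "tpora_drug_dictionary.csv",
    smq_map = "tpora_smq_map_synthetic.csv",
    univariable_counts = "tpora_univariable_counts.csv",
    tto_bins = "tpora_tto_bins.csv",
    report_counts = "tpora_report_counts.csv"
  )[[which]]
  path <- system.file("extdata", fname, package = "faerspv")
  if (!nzchar(path)) abort(paste0("bundled fixture not found: ", fname))
  path
}

#' Descriptive demographics table per drug
#'
#' Counts and percentages per category with an explicit `NA` row;
#' percentages are computed over all cases of the drug (missing included in
#' the denominator), printed to 1 dp. Countries are limited to the top 5 by
#' total count, descending.
#'
#' @param clean a `faers_clean` object.
#' @param drugs drugs to summarise; default all matched target drugs.
#' @return tidy tibble: `drug`, `characteristic`, `level`, `n`, `percent`.
#' @export
summarize_demographics <- function(clean, drugs = NULL) {
  cases <- clean$cases[!is.na(clean$cases$target_drug), , drop = FALSE]
  if (is.null(drugs)) drugs <- sort(unique(cases$target_drug))
  top_countries <- cases |>
    dplyr::filter(!is.na(country)) |>
    dplyr::count(country, sort = TRUE) |>
    head(5)

  one_block <- function(sub, characteristic, values, levels) {
    f <- factor(values, levels = levels)
    counts <- table(f, useNA = "always")
    lv <- c(levels, "NA")
    tibble::tibble(
      characteristic = characteristic,
      level = lv,
      n = as.integer(counts),
      percent = round(100 * as.integer(counts) / max(nrow(sub), 1L), 1)
    )
  }

  if (!length(drugs)) {
    return(tibble::tibble(drug = character(0), characteristic = character(0),
                          level = character(0), n = integer(0),
                          percent = numeric(0)))
  }
  out <- lapply(drugs, function(dg) {
    sub <- cases[cases$target_drug == dg, , drop = FALSE]
    blocks <- dplyr::bind_rows(
      one_block(sub, "sex", sub$sex, c("F", "M")),
      one_block(sub, "age_group", sub$age_group,
                levels(sub$age_group) %||% c("<18", "18-65", "65-85", ">85")),
      one_block(sub, "wt_group", sub$wt_group,
                levels(sub$wt_group) %||% c("<50", "50-100", ">100")),
      one_block(sub, "country",
                ifelse(sub$country %in% top_countries$country,
                       sub$country, NA_character_),
                top_countries$country),
      one_block(sub, "reporter", sub$reporter,
                sort(unique(cases$reporter[!is.na(cases$reporter)])))
    )
    tibble::tibble(drug = dg, blocks)
  })
  dplyr::bind_rows(out)
}

default_run_options <- function() {
  list(
    allowed_roles = "PS",
    scope = "narrow",
    background_policy = "all-other-drugs-in-dataset",
    bcpnn_gate = "eic",
    chi2_continuity_correction = FALSE,
    alpha = 0.05,
    quantile_method = "linear interpolation (type 7)",
    age_bins = "[0,18) [18,65) [65,85) [85,Inf)",
    weight_bins = "(0,50) [50,100] (100,Inf)",
    duration_bins = "[0,365) [365,730] (730,Inf)"
  )
}

write_output_csv <- function(x, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# manifest_hash: ", hash), con)
  close(con)
  readr::write_csv(tibble::as_tibble(x), path, append = TRUE, col_names = TRUE)
  path
}

#' Run the full pharmacovigilance pipeline and write a CSV bundle
#'
#' Stages: obtain raw tables (simulate from a [faers_sim_config()], read
#' from a directory of FAERS-dialect files, or use an in-memory table list);
#' clean; per-drug demographics; signal scan at PT and SMQ-category level;
#' time-to-onset records and summary; univariable screening and the
#' multivariable logistic model. Each output CSV carries the manifest hash;
#' the manifest records every option, the seed, and the flow counts. A stage
#' failure aborts with the stage name.
#'
#' @param input a `faers_sim_config`, a directory path, or a named list of
#'   raw tables.
#' @param out_dir output directory for the bundle.
#' @param dictionary a [drug_dictionary()]; default: the bundled panel.
#' @param map an [smq_map()]; default: the bundled synthetic map.
#' @param options named list overriding [default_run_options()] entries.
#' @param seed integer seed recorded in the manifest (and used for
#'   simulation when `input` is a generator configuration without one).
#' @return invisibly, a list with the in-memory results (`clean`,
#'   `demographics`, `signals_pt`, `signals_smq`, `tto`, `tto_summary`,
#'   `univariable`, `multivariable`, `manifest`).
#' @export
run_pipeline <- function(input, out_dir,
                         dictionary = drug_dictionary(faerspv_fixture("drug_dictionary")),
                         map = smq_map(faerspv_fixture("smq_map")),
                         options = list(), seed = 1L) {
  opts <- utils::modifyList(default_run_options(), options)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "faerspv_pipeline_error")
    })
  }

  tables <- stage("input", {
    if (inherits(input, "faers_sim_config")) {
      generate_faers_reports(input)$tables
    } else if (is.character(input)) {
      read_faers_tables(input)
    } else {
      input
    }
  })

  clean <- stage("clean", suppressWarnings(
    build_clean_cases(tables, dictionary, map,
                      allowed_roles = opts$allowed_roles, scope = opts$scope)
  ))

  demographics <- stage("demographics", summarize_demographics(clean))
  signals_pt <- stage("signals_pt",
                      scan_signals(clean, event_type = "pt",
                                   bcpnn_gate = opts$bcpnn_gate,
                                   correct = opts$chi2_continuity_correction))
  signals_smq <- stage("signals_smq",
                       scan_signals(clean, event_type = "category",
                                    bcpnn_gate = opts$bcpnn_gate,
                                    correct = opts$chi2_continuity_correction))
  tto <- stage("tto", tto_records(clean))
  tto_sum <- stage("tto_summary", summarize_tto(tto))

  model_input <- stage("model_input", make_model_input(clean))
  covs <- c("age_group", "wt_group", "sex", "duration_group", "drug")
  covs <- covs[vapply(covs, function(cv) {
    v <- droplevels(factor(model_input[[cv]]))
    nlevels(v) >= 2 && length(unique(model_input$y[!is.na(model_input[[cv]])])) == 2
  }, logical(1))]
  uni <- stage("univariable", {
    fits <- lapply(covs, function(cv)
      fit_univariable(model_input, cv, outcome = "y"))
    names(fits) <- covs
    fits
  })
  selected <- screen_covariates(uni, alpha = opts$alpha)
  multi <- stage("multivariable", {
    if (length(selected) >= 1 && nrow(model_input) > 0) {
      fit_multivariable(model_input, selected, outcome = "y")
    } else {
      NULL
    }
  })

  manifest <- list(
    package = "faerspv",
    version = as.character(utils::packageVersion("faerspv")),
    seed = as.integer(seed),
    options = opts,
    covariates_screened = covs,
    covariates_selected = selected,
    flow = clean$log
  )
  hash <- rlang::hash(manifest)
  manifest$manifest_hash <- hash

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage("write", {
    write_output_csv(demographics, file.path(out_dir, "demographics.csv"), hash)
    write_output_csv(signals_pt, file.path(out_dir, "signals_pt.csv"), hash)
    write_output_csv(signals_smq, file.path(out_dir, "signals_smq.csv"), hash)
    forest <- signals_pt |>
      dplyr::mutate(log_ror = log(.data$ror),
                    log_ror_low = log(.data$ror_low),
                    log_ror_high = log(.data$ror_high)) |>
      dplyr::select(drug, event, a, dplyr::starts_with("log_ror"))
    write_output_csv(forest, file.path(out_dir, "forest_data.csv"), hash)
    write_output_csv(tto, file.path(out_dir, "tto_records.csv"), hash)
    write_output_csv(tto_sum$bins, file.path(out_dir, "tto_summary.csv"), hash)
    uni_tab <- if (length(uni)) {
      dplyr::bind_rows(lapply(uni, tibble::as_tibble))
    } else {
      tibble::tibble(covariate = character(0), level = character(0),
                     reference = logical(0), n_control = integer(0),
                     n_case = integer(0), or = numeric(0),
                     or_low = numeric(0), or_high = numeric(0),
                     p_value = numeric(0), estimable = logical(0))
    }
    write_output_csv(uni_tab, file.path(out_dir, "univariable.csv"), hash)
    if (!is.null(multi)) {
      write_output_csv(tibble::as_tibble(multi),
                       file.path(out_dir, "multivariable.csv"), hash)
    }
    flow <- tibble::tibble(stage = names(clean$log),
                           n = unlist(clean$log, use.names = FALSE))
    write_output_csv(flow, file.path(out_dir, "flow_log.csv"), hash)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  })

  invisible(list(
    clean = clean, demographics = demographics, signals_pt = signals_pt,
    signals_smq = signals_smq, tto = tto, tto_summary = tto_sum,
    univariable = uni, multivariable = multi, manifest = manifest
  ))
}

#' Demo scenario configuration
#'
#' A synthetic-database configuration with planted thromboembolic signals on
#' the three thrombopoietin-receptor agonists (strong portal-vein and
#' renal-vein signals on avatrombopag, moderate venous signals on
#' eltrombopag, an arterial-embolism signal on romiplostim), used by the
#' README worked example and the pipeline tests.
#'
#' @param n_cases database size.
#' @param seed generator seed.
#' @return a [faers_sim_config()].
#' @export
demo_scenario <- function(n_cases = 20000, seed = 42L) {
  faers_sim_config(
    n_cases = n_cases,
    planted_signals = tibble::tibble(
      drug = c("Avatrombopag", "Avatrombopag", "Avatrombopag",
               "Eltrombopag", "Eltrombopag",
               "Romiplostim", "Romiplostim"),
      pt = c("Portal vein thrombosis", "Renal vein thrombosis",
             "Pulmonary embolism",
             "Pulmonary embolism", "Deep vein thrombosis",
             "Embolism arterial", "Deep vein thrombosis"),
      multiplier = c(40, 60, 4, 3, 3, 25, 6)
    ),
    seed = seed
  )
}
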
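# Reading and cleaning of FAERS-dialect raw tables: "$"-delimited ASCII with
# a header line, one file each for DEMO, DRUG, REAC, THER.

faers_required_columns <- list(
  demo = c("primaryid", "caseid", "fda_dt"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "caseid", "pt"),
  ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt")
)

faers_numeric_columns <- c("primaryid", "caseid", "drug_seq", "dsg_drug_seq",
                           "age", "wt")

read_one_faers_table <- function(path, table) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) {
    abort(paste0("file has no header line: ", path),
          class = "faerspv_format_error")
  }
  header <- strsplit(lines[1], "$", fixed = TRUE)[[1]]
  header <- tolower(trimws(header))
  missing_cols <- setdiff(faers_required_columns[[table]], header)
  if (length(missing_cols)) {
    abort(sprintf("file %s is missing mandatory column(s): %s",
                  path, paste(missing_cols, collapse = ", ")),
          class = "faerspv_format_error")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  n_cols <- length(header)
  parts <- strsplit(body, "$", fixed = TRUE)
  # a trailing empty field is dropped by strsplit; restore it
  lens <- lengths(parts)
  short_by_one <- lens == n_cols - 1L & endsWith(body, "$")
  parts[short_by_one] <- lapply(parts[short_by_one], function(p) c(p, ""))
  lens[short_by_one] <- n_cols
  ok <- lens == n_cols
  n_malformed <- sum(!ok)
  if (n_malformed > 0) {
    warn(sprintf("%s: rejected %d malformed row(s) with a field count != %d",
                 basename(path), n_malformed, n_cols))
  }
  mat <- if (any(ok)) {
    matrix(unlist(parts[ok], use.names = FALSE), ncol = n_cols, byrow = TRUE)
  } else {
    matrix(character(0), ncol = n_cols)
  }
  out <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                           .name_repair = "minimal")
  names(out) <- header
  for (col in intersect(names(out), faers_numeric_columns)) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  for (col in setdiff(names(out), faers_numeric_columns)) {
    out[[col]][out[[col]] == ""] <- NA_character_
  }
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Read FAERS-dialect raw tables from disk
#'
#' Expects the "$"-delimited quarterly ASCII dialect with a header line.
#' Rows whose field count disagrees with the header are rejected with a
#' warning (their count is kept in the `n_malformed` attribute of each
#' table); verbatim strings are otherwise preserved.
#'
#' @param dir directory containing `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `THER.txt`, or a named character vector/list of the four paths
#'   (names `demo`, `drug`, `reac`, `ther`).
#' @return named list of tibbles (`demo`, `drug`, `reac`, `ther`).
#' @export
read_faers_tables <- function(dir) {
  if (length(dir) == 1L && is.character(dir) && dir.exists(dir)) {
    paths <- file.path(dir, c("DEMO.txt", "DRUG.txt", "REAC.txt", "THER.txt"))
    names(paths) <- c("demo", "drug", "reac", "ther")
  } else {
    paths <- unlist(dir)
    if (!all(c("demo", "drug", "reac", "ther") %in% names(paths))) {
      abort("supply a directory or paths named demo, drug, reac, ther.",
            class = "faerspv_format_error")
    }
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("input file does not exist: ", missing[1]),
          class = "faerspv_format_error")
  }
  lapply(setNames(names(paths), names(paths)),
         function(nm) read_one_faers_table(paths[[nm]], nm))
}

#' Keep one report version per case
#'
#' For report versions sharing a CASEID the entry with the latest FDA date is
#' retained; when CASEID and FDA date are both identical, the record with the
#' highest PRIMARYID wins. Partial FDA dates participate in the ordering at
#' their available precision with missing components treated as earliest.
#' The result is sorted by CASEID, so the output is invariant to the input
#' row order and the operation is idempotent.
#'
#' @param demo a DEMO tibble (columns `primaryid`, `caseid`, `fda_dt`, ...).
#' @return the selected rows of `demo`, one per `caseid`, sorted by `caseid`.
#' @export
deduplicate_cases <- function(demo) {
  if (!nrow(demo)) return(demo)
  key <- pad_faers_date(demo$fda_dt)
  ord <- order(demo$caseid, key, demo$primaryid)
  sorted <- demo[ord, , drop = FALSE]
  last <- !duplicated(sorted$caseid, fromLast = TRUE)
  out <- sorted[last, , drop = FALSE]
  out[order(out$caseid), , drop = FALSE]
}

normalize_string <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Build a drug synonym dictionary
#'
#' @param x a data frame with columns `canonical` and `synonym` (one row per
#'   synonym; brand and generic spellings), or a path to such a CSV file.
#' @return an object of class `drug_dictionary`.
#' @export
drug_dictionary <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!all(c("canonical", "synonym") %in% names(x))) {
    abort("drug dictionary needs columns canonical, synonym.",
          class = "faerspv_format_error")
  }
  canon <- unique(x$canonical)
  if (anyDuplicated(normalize_string(canon))) {
    abort("canonical drug names must be unique (case-insensitively).",
          class = "faerspv_format_error")
  }
  # every canonical name is also its own synonym
  x <- dplyr::bind_rows(x, tibble::tibble(canonical = canon, synonym = canon))
  x$key <- normalize_string(x$synonym)
  x <- x[!duplicated(x$key), , drop = FALSE]
  structure(list(table = x, lookup = setNames(x$canonical, x$key)),
            class = "drug_dictionary")
}

#' Match verbatim drug names against a synonym dictionary
#'
#' Matching is exact on the synonym after trimming, collapsing internal
#' whitespace, and lower-casing -- no substring matching, so combination
#' product strings do not match unless enumerated in the dictionary.
#'
#' @param verbatim character vector of verbatim drug-name strings.
#' @param dictionary a [drug_dictionary()].
#' @return character vector of canonical names, `NA` where unmatched.
#' @export
match_drug <- function(verbatim, dictionary) {
  stopifnot(inherits(dictionary, "drug_dictionary"))
  unname(dictionary$lookup[normalize_string(verbatim)])
}

#' Build a PT-to-SMQ event map
#'
#' @param x a data frame with columns `pt`, `category`, `scope`
#'   (scope values `narrow` or `broad`), or a path to such a CSV.
#' @return an object of class `smq_map`.
#' @export
smq_map <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!all(c("pt", "category", "scope") %in% names(x))) {
    abort("SMQ map needs columns pt, category, scope.",
          class = "faerspv_format_error")
  }
  if (!all(x$scope %in% c("narrow", "broad"))) {
    abort("SMQ scope must be 'narrow' or 'broad'.",
          class = "faerspv_format_error")
  }
  x$key <- normalize_string(x$pt)
  if (anyDuplicated(x$key)) {
    abort("each PT may appear only once in the SMQ map.",
          class = "faerspv_format_error")
  }
  structure(list(table = x), class = "smq_map")
}

#' Map reaction PTs to SMQ event categories
#'
#' PTs absent from the map (or outside the requested scope) are dropped from
#' the event set; the report itself stays in the dataset as background.
#'
#' @param reactions character vector of MedDRA PT strings.
#' @param map an [smq_map()].
#' @param scope `"narrow"` (default) keeps narrow-scope PTs only;
#'   `"narrow+broad"` keeps both.
#' @return tibble with columns `pt` (map spelling), `category` for the
#'   retained reactions, in input order.
#' @export
map_events <- function(reactions, map, scope = c("narrow", "narrow+broad")) {
  stopifnot(inherits(map, "smq_map"))
  scope <- match.arg(scope)
  tab <- map$table
  if (scope == "narrow") tab <- tab[tab$scope == "narrow", , drop = FALSE]
  idx <- match(normalize_string(reactions), tab$key)
  keep <- !is.na(idx)
  tibble::tibble(pt = tab$pt[idx[keep]], category = tab$category[idx[keep]])
}

#' Normalize reported age to years
#'
#' Unit codes: `YR` years, `DEC` decades, `MON` months, `WK` weeks, `DY`
#' days. Unknown units, non-positive ages, and ages above 120 years are set
#' to missing; a single warning summarises how many values were dropped.
#'
#' @param value numeric vector of reported age values.
#' @param unit_code character vector of unit codes (recycled if length 1).
#' @return numeric vector of ages in years, `NA` where invalid.
#' @export
normalize_age <- function(value, unit_code) {
  if (length(unit_code) == 1L) unit_code <- rep(unit_code, length(value))
  factors <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.1775, DY = 1 / 365.25)
  f <- factors[toupper(unit_code)]
  unknown <- !is.na(value) & !is.na(unit_code) & is.na(f)
  out <- value * f
  invalid <- !is.na(out) & (out <= 0 | out > 120)
  out[invalid] <- NA_real_
  n_bad <- sum(unknown) + sum(invalid)
  if (n_bad > 0) {
    warn(sprintf("normalize_age: %d value(s) set to missing (unknown unit or outside (0, 120] years)",
                 n_bad))
  }
  unname(out)
}

#' Normalize reported body weight to kilograms
#'
#' Unit codes: `KG`, `LBS`. Unknown units, non-positive weights, and weights
#' above 500 kg are set to missing with a summary warning.
#'
#' @param value numeric vector of reported weight values.
#' @param unit_code character vector of unit codes (recycled if length 1).
#' @return numeric vector of weights in kg, `NA` where invalid.
#' @export
normalize_weight <- function(value, unit_code) {
  if (length(unit_code) == 1L) unit_code <- rep(unit_code, length(value))
  factors <- c(KG = 1, LBS = 0.45359237)
  f <- factors[toupper(unit_code)]
  unknown <- !is.na(value) & !is.na(unit_code) & is.na(f)
  out <- value * f
  invalid <- !is.na(out) & (out <= 0 | out > 500)
  out[invalid] <- NA_real_
  n_bad <- sum(unknown) + sum(invalid)
  if (n_bad > 0) {
    warn(sprintf("normalize_weight: %d value(s) set to missing (unknown unit or outside (0, 500] kg)",
                 n_bad))
  }
  unname(out)
}

#' Bin continuous covariates into the analysis categories
#'
#' Boundary convention (declared, and echoed by [run_pipeline()] into its
#' manifest): age half-open lower-inclusive `[0,18) [18,65) [65,85) [85,Inf)`;
#' weight `(0,50) [50,100] (100,Inf)`; therapy duration
#' `[0,365) [365,730] (730,Inf)` days. Missing input maps to `NA`.
#'
#' @param age_yr numeric age in years (or `NULL`).
#' @param wt_kg numeric weight in kg (or `NULL`).
#' @param duration_days numeric duration in days (or `NULL`).
#' @return a list of factors (`age_group`, `wt_group`, `duration_group`) for
#'   the supplied inputs, with levels ordered as above.
#' @export
bin_covariates <- function(age_yr = NULL, wt_kg = NULL, duration_days = NULL) {
  out <- list()
  if (!is.null(age_yr)) {
    out$age_group <- cut(age_yr, breaks = c(0, 18, 65, 85, Inf),
                         labels = c("<18", "18-65", "65-85", ">85"),
                         right = FALSE, include.lowest = TRUE)
  }
  if (!is.null(wt_kg)) {
    lab <- ifelse(is.na(wt_kg), NA_character_,
                  ifelse(wt_kg < 50, "<50",
                         ifelse(wt_kg <= 100, "50-100", ">100")))
    out$wt_group <- factor(lab, levels = c("<50", "50-100", ">100"))
  }
  if (!is.null(duration_days)) {
    lab <- ifelse(is.na(duration_days), NA_character_,
                  ifelse(duration_days < 365, "<365",
                         ifelse(duration_days <= 730, "365-730", ">730")))
    out$duration_group <- factor(lab, levels = c("<365", "365-730", ">730"))
  }
  out
}

#' Clean raw FAERS-dialect tables into analysis-ready cases
#'
#' Runs the full cleaning cascade: deduplication to one version per case,
#' synonym-based matching of the suspect drug, role filtering, PT-to-SMQ
#' event mapping, and demographic normalisation. Every case in the input is
#' retained in the output (cases whose only dictionary drug carries a
#' disallowed role, and cases with no dictionary drug at all, stay available
#' as comparator background); the `target_drug` column is `NA` for them and
#' the flow log records the partition.
#'
#' @param tables named list of raw tibbles (`demo`, `drug`, `reac`, `ther`)
#'   from [read_faers_tables()] or [generate_faers_reports()].
#' @param dictionary a [drug_dictionary()] of the target drugs.
#' @param map an [smq_map()] of the event PTs of interest.
#' @param allowed_roles non-empty subset of `c("PS","SS","C","I")`; a case
#'   counts as exposed only if >= 1 dictionary-drug entry carries an allowed
#'   role. Default `"PS"` (primary suspect only).
#' @param scope SMQ scope passed to [map_events()].
#' @return an object of class `faers_clean`: list with
#'   `cases` (one row per case: identifiers, `target_drug`,
#'   `excluded_by_role`, normalised demographics and bins, `start_dt`,
#'   `event_dt`, `any_event`), `events` (one row per (case, mapped PT) with
#'   its SMQ `category`), and `log` (named counts of the cleaning flow).
#' @export
build_clean_cases <- function(tables, dictionary, map,
                              allowed_roles = "PS",
                              scope = c("narrow", "narrow+broad")) {
  scope <- match.arg(scope)
  if (!length(allowed_roles) ||
      !all(allowed_roles %in% c("PS", "SS", "C", "I"))) {
    abort("`allowed_roles` must be a non-empty subset of PS, SS, C, I.",
          class = "faerspv_config_error")
  }
  n_versions_in <- nrow(tables$demo)
  demo <- deduplicate_cases(tables$demo)
  kept_pid <- demo$primaryid

  drug_rows <- tables$drug[tables$drug$primaryid %in% kept_pid, , drop = FALSE]
  drug_rows$canonical <- match_drug(drug_rows$drugname, dictionary)
  dict_rows <- drug_rows[!is.na(drug_rows$canonical), , drop = FALSE]

  # per case: does any dictionary entry carry an allowed role, and if so
  # which canonical drug (deterministic: first by role order PS>SS>C>I,
  # then drug_seq)
  role_rank <- c(PS = 1, SS = 2, C = 3, I = 4)
  dict_rows$role_ok <- dict_rows$role_cod %in% allowed_roles
  picked <- dict_rows |>
    dplyr::filter(.data$role_ok) |>
    dplyr::arrange(caseid, role_rank[role_cod], drug_seq) |>
    dplyr::distinct(caseid, .keep_all = TRUE) |>
    dplyr::select(caseid, target_drug = canonical,
                  target_drug_seq = drug_seq)
  has_dict_drug <- unique(dict_rows$caseid)

  reac_rows <- tables$reac[tables$reac$primaryid %in% kept_pid, , drop = FALSE]
  tab <- map$table
  if (scope == "narrow") tab <- tab[tab$scope == "narrow", , drop = FALSE]
  idx <- match(normalize_string(reac_rows$pt), tab$key)
  keep <- !is.na(idx)
  events <- tibble::tibble(
    caseid = reac_rows$caseid[keep],
    pt = tab$pt[idx[keep]],
    category = tab$category[idx[keep]]
  ) |>
    dplyr::distinct(caseid, pt, .keep_all = TRUE) |>
    dplyr::arrange(caseid, pt)

  # earliest complete therapy start date among the case's target-drug rows
  ther_rows <- tables$ther[tables$ther$primaryid %in% kept_pid, , drop = FALSE]
  ther_rows <- dplyr::inner_join(
    ther_rows,
    picked |> dplyr::select(caseid, target_drug_seq),
    by = "caseid"
  )
  ther_rows <- ther_rows[ther_rows$dsg_drug_seq == ther_rows$target_drug_seq, ,
                         drop = FALSE]
  ther_pick <- ther_rows |>
    dplyr::mutate(..sort_key = ifelse(faers_date_complete(start_dt),
                                      start_dt, "99999999")) |>
    dplyr::arrange(caseid, .data$..sort_key) |>
    dplyr::distinct(caseid, .keep_all = TRUE) |>
    dplyr::select(caseid, start_dt)

  cases <- demo |>
    dplyr::left_join(picked |> dplyr::select(caseid, target_drug),
                     by = "caseid") |>
    dplyr::left_join(ther_pick, by = "caseid")
  cases$excluded_by_role <- is.na(cases$target_drug) &
    cases$caseid %in% has_dict_drug
  cases$age_yr <- normalize_age(cases$age, cases$age_cod)
  cases$wt_kg <- normalize_weight(cases$wt, cases$wt_cod)
  bins <- bin_covariates(age_yr = cases$age_yr, wt_kg = cases$wt_kg)
  cases$age_group <- bins$age_group
  cases$wt_group <- bins$wt_group
  cases$any_event <- cases$caseid %in% events$caseid

  cases <- cases |>
    dplyr::select(caseid, primaryid, fda_dt, target_drug, excluded_by_role,
                  sex, age_yr, age_group, wt_kg, wt_group,
                  country = dplyr::any_of("reporter_country"),
                  reporter = dplyr::any_of("occp_cod"),
                  start_dt, event_dt, any_event) |>
    dplyr::arrange(caseid)

  log <- list(
    versions_in = n_versions_in,
    cases_in = nrow(cases),
    cases_retained = sum(!is.na(cases$target_drug)),
    cases_excluded_by_role = sum(cases$excluded_by_role),
    cases_without_target_drug = sum(is.na(cases$target_drug) &
                                      !cases$excluded_by_role)
  )
  structure(list(cases = cases, events = events, log = log),
            class = "faers_clean")
}

#' @export
print.faers_clean <- function(x, ...) {
  cat("<faers_clean>\n")
  cat(sprintf("  report versions in: %d\n", x$log$versions_in))
  cat(sprintf("  unique cases:       %d\n", x$log$cases_in))
  cat(sprintf("  with target drug:   %d (role-excluded: %d, no target drug: %d)\n",
              x$log$cases_retained, x$log$cases_excluded_by_role,
              x$log$cases_without_target_drug))
  cat(sprintf("  mapped event rows:  %d\n", nrow(x$events)))
  invisible(x)
}

#' Restrict exposed cases by drug role code
#'
#' Returns the cases whose matched target drug carries at least one allowed
#' role. This is a convenience view over [build_clean_cases()], which already
#' applies the role policy when matching; use it to re-filter a `cases`
#' tibble by an explicit role set.
#'
#' @param drug_rows a DRUG tibble with `caseid`, `role_cod`, and a
#'   `canonical` column (from [match_drug()]).
#' @param allowed_roles non-empty subset of `c("PS","SS","C","I")`.
#' @return vector of caseids with a dictionary drug in an allowed role.
#' @export
filter_by_role <- function(drug_rows, allowed_roles = "PS") {
  if (!length(allowed_roles) ||
      !all(allowed_roles %in% c("PS", "SS", "C", "I"))) {
    abort("`allowed_roles` must be a non-empty subset of PS, SS, C, I.",
          class = "faerspv_config_error")
  }
  keep <- !is.na(drug_rows$canonical) & drug_rows$role_cod %in% allowed_roles
  sort(unique(drug_rows$caseid[keep]))
}
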
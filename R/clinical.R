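#' Derive sustained SRI-4 response labels from longitudinal visits
#'
#' A patient is a responder to a drug when, from some visit at least 3 months
#' after the first visit on the drug, the SRI-4 composite holds and keeps
#' holding at every later on-drug visit: SLEDAI reduced by >= 4 points from
#' baseline, no meaningful PGA worsening (increase < 0.3), and -- when BILAG
#' columns are supplied -- no new BILAG A and at most one new BILAG B.
#' Transient responses that are later lost do not count.
#'
#' @param visits data frame of visit records with columns `patient_id`,
#'   `drug`, `visit_month` (months since first visit on the drug), `sledai`,
#'   `pga`, and optionally `bilag_new_a`, `bilag_new_b` (counts of new A/B
#'   flags at the visit). Several patients/drugs may be present; each
#'   patient-drug series is labelled separately.
#' @param pga_worsening PGA increase treated as worsening (default 0.3, the
#'   standard SRI-4 convention).
#' @param use_bilag apply the BILAG clause; ignored with a message when the
#'   columns are absent.
#' @return tibble with `patient_id`, `drug`, `label`
#'   ("responder"/"non-responder"), `criterion = "SRI4"`, `onset_month` (first
#'   month of sustained response, NA for non-responders).
#' @export
derive_sri4_response <- function(visits, pga_worsening = 0.3,
                                 use_bilag = TRUE) {
  req <- c("patient_id", "drug", "visit_month", "sledai", "pga")
  missing_cols <- setdiff(req, names(visits))
  if (length(missing_cols))
    stopf("visits is missing columns: %s", paste(missing_cols, collapse = ", "))
  has_bilag <- all(c("bilag_new_a", "bilag_new_b") %in% names(visits))
  if (any(visits$visit_month < 0)) stopf("visit_month must be >= 0")

  one <- function(v) {
    v <- dplyr::arrange(v, .data$visit_month)
    if (nrow(v) < 2)
      stopf("patient %s: need >= 2 visits on %s", v$patient_id[1], v$drug[1])
    if (max(v$visit_month) < 3)
      stopf("patient %s: no visit at month >= 3 on %s",
            v$patient_id[1], v$drug[1])
    base_sledai <- v$sledai[1]; base_pga <- v$pga[1]
    ok <- (base_sledai - v$sledai >= 4) & (v$pga - base_pga < pga_worsening)
    if (use_bilag && has_bilag)
      ok <- ok & (v$bilag_new_a == 0) & (v$bilag_new_b <= 1)
    candidate <- which(v$visit_month >= 3)
    # sustained: ok at this visit and all later ones
    sustained_from <- rev(cumprod(rev(ok))) > 0
    hit <- candidate[sustained_from[candidate]]
    tibble::tibble(
      patient_id = v$patient_id[1], drug = v$drug[1],
      label = if (length(hit)) "responder" else "non-responder",
      criterion = "SRI4",
      onset_month = if (length(hit)) v$visit_month[min(hit)] else NA_real_
    )
  }
  visits |>
    dplyr::group_by(.data$patient_id, .data$drug) |>
    dplyr::group_split() |>
    purrr::map(one) |>
    purrr::list_rbind()
}

#' Derive sustained renal (UPCR) response labels
#'
#' Responder: urine protein/creatinine ratio reduced below 500 mg/g at some
#' visit at least 3 months after starting the drug and kept below 500 at every
#' visit through the last on-drug visit. "Reduced" requires a baseline
#' >= 500 mg/g; patients already below 500 at baseline who stay below are
#' labelled responders with `already_low = TRUE` so they can be excluded
#' downstream if desired.
#'
#' @param visits data frame with `patient_id`, `drug`, `visit_month`, `upcr`
#'   (mg/g).
#' @return tibble with `patient_id`, `drug`, `label`, `criterion = "UPCR"`,
#'   `onset_month`, `already_low`.
#' @export
derive_upcr_response <- function(visits) {
  req <- c("patient_id", "drug", "visit_month", "upcr")
  missing_cols <- setdiff(req, names(visits))
  if (length(missing_cols))
    stopf("visits is missing columns: %s", paste(missing_cols, collapse = ", "))
  one <- function(v) {
    v <- dplyr::arrange(v, .data$visit_month)
    v <- v[!is.na(v$upcr), ]
    if (nrow(v) < 2 || max(v$visit_month) < 3)
      stopf("patient %s: UPCR needed at >= 2 visits incl. one at month >= 3",
            v$patient_id[1])
    below <- v$upcr < 500
    sustained_from <- rev(cumprod(rev(below))) > 0
    candidate <- which(v$visit_month >= 3)
    hit <- candidate[sustained_from[candidate]]
    already_low <- below[1]
    responder <- length(hit) > 0 && (v$upcr[1] >= 500 || all(below))
    tibble::tibble(
      patient_id = v$patient_id[1], drug = v$drug[1],
      label = if (responder) "responder" else "non-responder",
      criterion = "UPCR",
      onset_month = if (responder) v$visit_month[min(hit)] else NA_real_,
      already_low = responder && already_low
    )
  }
  visits |>
    dplyr::group_by(.data$patient_id, .data$drug) |>
    dplyr::group_split() |>
    purrr::map(one) |>
    purrr::list_rbind()
}

#' Group summaries of a cohort table with Wilcoxon / Fisher tests
#'
#' Produces Table-1-style responder vs non-responder summaries per drug:
#' means (SD) with two-sided Wilcoxon rank-sum p for continuous variables,
#' counts (percentages) with two-sided Fisher exact p for categorical ones.
#' Patient-level variables are collapsed to one row per patient before
#' testing; sample-level variables use all visits.
#'
#' @param cohort data frame with at least `patient_id`, `drug`, `response`
#'   plus the variables named in `variable_spec`.
#' @param variable_spec data frame with columns `variable`, `type`
#'   ("continuous"/"categorical"), `level` ("patient"/"sample").
#' @param exact_max use the exact Wilcoxon distribution when both groups have
#'   at most this many observations (default 25); larger groups use the
#'   normal approximation with continuity correction.
#' @return tibble: one row per drug x variable (x category level for
#'   categorical variables) with group summaries, `p_value`, `test`,
#'   significance `stars` (<0.05 *, <0.005 **, <0.0005 ***, <0.00005 ****),
#'   `n_missing` dropped rows, and a `flag` for degenerate cases where the
#'   test was skipped.
#' @export
summarize_cohort <- function(cohort, variable_spec, exact_max = 25) {
  stopifnot(all(c("variable", "type", "level") %in% names(variable_spec)))
  absent <- setdiff(variable_spec$variable, names(cohort))
  if (length(absent))
    stopf("variables absent from cohort: %s", paste(absent, collapse = ", "))

  rows <- list()
  for (d in unique(cohort$drug)) {
    dat_d <- cohort[cohort$drug == d, ]
    if (length(unique(dat_d$response)) < 2)
      stopf("drug %s: need both response groups", d)
    for (i in seq_len(nrow(variable_spec))) {
      vs <- variable_spec[i, ]
      dat <- dat_d
      if (vs$level == "patient")
        dat <- dplyr::distinct(dat, .data$patient_id, .keep_all = TRUE)
      v <- dat[[vs$variable]]
      keep <- !is.na(v)
      n_missing <- sum(!keep)
      dat <- dat[keep, ]; v <- v[keep]
      grp <- dat$response == "responder"
      if (vs$type == "continuous") {
        exact <- sum(grp) <= exact_max && sum(!grp) <= exact_max
        p <- tryCatch(
          suppressWarnings(stats::wilcox.test(v[grp], v[!grp], exact = exact,
                                              correct = TRUE)$p.value),
          error = function(e) NA_real_)
        rows[[length(rows) + 1]] <- tibble::tibble(
          drug = d, variable = vs$variable, category = NA_character_,
          level = vs$level,
          n_responder = sum(grp), n_nonresponder = sum(!grp),
          responder = sprintf("%.2f (± %.1f)", mean(v[grp]), sd(v[grp])),
          nonresponder = sprintf("%.2f (± %.1f)", mean(v[!grp]), sd(v[!grp])),
          value_responder = mean(v[grp]), value_nonresponder = mean(v[!grp]),
          test = "wilcoxon", p_value = p, n_missing = n_missing,
          flag = NA_character_)
      } else {
        lev <- sort(unique(as.character(v)))
        if (length(lev) < 2) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            drug = d, variable = vs$variable, category = lev[1] %||% NA_character_,
            level = vs$level,
            n_responder = sum(grp), n_nonresponder = sum(!grp),
            responder = NA_character_, nonresponder = NA_character_,
            value_responder = NA_real_, value_nonresponder = NA_real_,
            test = "fisher", p_value = NA_real_, n_missing = n_missing,
            flag = "single-level variable; test skipped")
          next
        }
        tab <- table(factor(as.character(v), lev), factor(grp, c(TRUE, FALSE)))
        p <- stats::fisher.test(tab)$p.value
        for (l in lev) {
          cr <- sum(v[grp] == l); cn <- sum(v[!grp] == l)
          rows[[length(rows) + 1]] <- tibble::tibble(
            drug = d, variable = vs$variable, category = l, level = vs$level,
            n_responder = sum(grp), n_nonresponder = sum(!grp),
            responder = sprintf("%d (%.1f%%)", cr, 100 * cr / sum(grp)),
            nonresponder = sprintf("%d (%.1f%%)", cn, 100 * cn / sum(!grp)),
            value_responder = 100 * cr / sum(grp),
            value_nonresponder = 100 * cn / sum(!grp),
            test = "fisher", p_value = p, n_missing = n_missing,
            flag = NA_character_)
        }
      }
    }
  }
  out <- purrr::list_rbind(rows)
  out$stars <- significance_stars(out$p_value)
  out
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.00005 ~ "****",
    p < 0.0005 ~ "***",
    p < 0.005 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Expand the packaged Table-1 count fixture to a patient-level cohort
#'
#' The package ships a small CSV of patient counts per drug and response group
#' (patients, females, race categories) transcribed from the study cohort's
#' characteristics table. This helper expands those counts into one row per
#' patient so [summarize_cohort()] can recompute the printed percentages.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return patient-level tibble with `patient_id`, `drug`, `response`, `sex`,
#'   `race`.
#' @export
table1_cohort <- function(path = system.file("extdata", "table1_counts.csv",
                                             package = "lupusnr")) {
  counts <- readr::read_csv(path, show_col_types = FALSE)
  rows <- purrr::pmap(counts, function(drug, response, n_patients, n_female,
                                       n_race_c, n_race_aa, n_race_other) {
    sex <- c(rep("F", n_female), rep("M", n_patients - n_female))
    race <- c(rep("C", n_race_c), rep("AA", n_race_aa),
              rep("O", n_race_other))
    stopifnot(length(race) == n_patients)
    tibble::tibble(drug = drug, response = response, sex = sex, race = race)
  })
  out <- purrr::list_rbind(rows)
  out$patient_id <- sprintf("T1P%03d", seq_len(nrow(out)))
  out[, c("patient_id", "drug", "response", "sex", "race")]
}
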
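#' Estimate cell-type fractions by constrained least squares
#'
#' Reference-based deconvolution under the linear mixture model
#' `y = B f + e`: per sample, non-negative least squares on the basis genes,
#' with the coefficient vector renormalized to sum to 1. Cell types that are
#' not blood-circulating (e.g. macrophages, mastocytes in a blood cohort) can
#' be excluded before renormalization.
#'
#' @param expr genes x samples matrix on the basis scale (linear).
#' @param basis genes x cell-types non-negative reference matrix with
#'   linearly independent columns.
#' @param exclude_types cell types dropped from the result (fractions
#'   renormalized afterwards).
#' @return An `lnr_fractions` tibble: `sample_id`, one column per retained
#'   cell type (rows sum to 1), and `residual_norm`.
#' @export
deconvolve <- function(expr, basis, exclude_types = character(0)) {
  common <- intersect(rownames(basis), rownames(expr))
  if (!length(common)) stopf("no overlapping genes between basis and matrix")
  B <- as.matrix(basis[common, , drop = FALSE])
  if (qr(B)$rank < ncol(B)) stopf("basis columns are linearly dependent")
  Y <- as.matrix(expr[common, , drop = FALSE])
  res <- apply(Y, 2, function(y) {
    fit <- pracma::lsqnonneg(B, y)
    c(fit$x, sqrt(fit$resid.norm))
  })
  fr <- t(res[seq_len(ncol(B)), , drop = FALSE])
  colnames(fr) <- colnames(B)
  rn <- res[ncol(B) + 1, ]
  keep <- setdiff(colnames(fr), exclude_types)
  fr <- fr[, keep, drop = FALSE]
  tot <- rowSums(fr)
  if (any(tot == 0)) warnf("%d sample(s) with all-zero fit", sum(tot == 0))
  fr <- sweep(fr, 1, ifelse(tot > 0, tot, 1), "/")
  out <- tibble::as_tibble(fr)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(expr)), out)
  out$residual_norm <- rn
  structure(out, cell_types = keep,
            class = c("lnr_fractions", class(out)))
}

#' Stratify patients as rich or poor per cell type
#'
#' For each cell type, a patient is "rich" when their mean fraction across
#' samples is strictly above the median of patient means, "poor" otherwise
#' (ties at the median are poor, deterministically).
#'
#' @param fractions an `lnr_fractions` tibble (or sample x type tibble with
#'   `sample_id`).
#' @param patients patient id per sample, aligned with `fractions` rows.
#' @return tibble: `patient_id`, `cell_type`, `fraction` (patient mean),
#'   `median` (across patients), `label` ("rich"/"poor").
#' @export
stratify_rich_poor <- function(fractions, patients) {
  types <- attr(fractions, "cell_types") %||%
    setdiff(names(fractions), c("sample_id", "residual_norm"))
  stopifnot(length(patients) == nrow(fractions))
  if (length(unique(patients)) < 2) stopf("need >= 2 patients to stratify")
  long <- fractions |>
    dplyr::mutate(patient_id = as.character(patients)) |>
    tidyr::pivot_longer(dplyr::all_of(types), names_to = "cell_type",
                        values_to = "fraction") |>
    dplyr::group_by(.data$patient_id, .data$cell_type) |>
    dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop") |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::mutate(median = stats::median(.data$fraction),
                  label = ifelse(.data$fraction > .data$median,
                                 "rich", "poor")) |>
    dplyr::ungroup()
  flat <- long |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(all_same = dplyr::n_distinct(.data$fraction) == 1)
  if (any(flat$all_same))
    warnf("cell type(s) with identical fractions everywhere (all poor): %s",
          paste(flat$cell_type[flat$all_same], collapse = ", "))
  long
}

#' Test response-rate differences between rich and poor strata
#'
#' Response rates are computed over samples (a patient contributes all
#' visits) within each stratum of each cell type, and compared with a
#' two-sided Fisher exact test on the 2x2 stratum x response table.
#'
#' @param labels tibble from [stratify_rich_poor()].
#' @param samples tibble with `patient_id`, `response` (one row per sample),
#'   and optionally `drug` (tested separately per drug when present).
#' @return tibble per cell type (x drug): sample counts, `rate_rich`,
#'   `rate_poor` (responder fractions), `p_value`, `flag` for untestable
#'   strata.
#' @export
response_rate_test <- function(labels, samples) {
  stopifnot(all(c("patient_id", "response") %in% names(samples)))
  if (!"drug" %in% names(samples)) samples$drug <- "all"
  joined <- dplyr::inner_join(samples, labels, by = "patient_id",
                              relationship = "many-to-many")
  joined |>
    dplyr::group_by(.data$drug, .data$cell_type) |>
    dplyr::group_map(function(g, key) {
      resp <- g$response == "responder"
      rich <- g$label == "rich"
      row <- tibble::tibble(
        drug = key$drug, cell_type = key$cell_type,
        n_rich = sum(rich), n_poor = sum(!rich),
        rate_rich = NA_real_, rate_poor = NA_real_,
        p_value = NA_real_, flag = NA_character_)
      if (!any(rich) || !any(!rich)) {
        row$flag <- "empty stratum"
        return(row)
      }
      row$rate_rich <- mean(resp[rich])
      row$rate_poor <- mean(resp[!rich])
      tab <- table(factor(rich, c(TRUE, FALSE)),
                   factor(resp, c(TRUE, FALSE)))
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stopf("%s/%s: zero margin in the stratum x response table; untestable",
              key$drug, key$cell_type)
      row$p_value <- stats::fisher.test(tab)$p.value
      row
    }) |>
    purrr::list_rbind()
}
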
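#' Tidy a moderated differential-expression result
#'
#' @param x an `lnr_de` object.
#' @param ... unused.
#' @return tibble of per-gene statistics (gene, logFC, t, p_value,
#'   p_bonferroni, direction).
#' @method tidy lnr_de
#' @export
tidy.lnr_de <- function(x, ...) {
  tibble::as_tibble(x)[, c("gene", "logFC", "t", "p_value",
                           "p_bonferroni", "direction")]
}

#' @rdname tidy.lnr_de
#' @return `glance`: one-row tibble with the empirical-Bayes
#'   hyperparameters (`d0`, `s0_2`), the consensus correlation `rho`, and
#'   the numbers of genes tested/significant.
#' @method glance lnr_de
#' @export
glance.lnr_de <- function(x, ...) {
  tibble::tibble(
    d0 = attr(x, "d0"), s0_2 = attr(x, "s0_2"), rho = attr(x, "rho"),
    n_genes = nrow(x), n_tested = attr(x, "n_tested"),
    n_significant = sum(x$p_bonferroni < 0.05, na.rm = TRUE))
}

#' Tidy a nested cross-validation report
#'
#' @param x an `lnr_cv` object.
#' @param ... unused.
#' @return tibble: one row per model x outer fold with its MCC.
#' @method tidy lnr_cv
#' @export
tidy.lnr_cv <- function(x, ...) {
  x$report |>
    dplyr::select("model", "fold_mcc") |>
    dplyr::mutate(fold = list(seq_along(.data$fold_mcc[[1]]))) |>
    tidyr::unnest(c("fold", "fold_mcc")) |>
    dplyr::select("model", "fold", mcc = "fold_mcc")
}

#' @rdname tidy.lnr_cv
#' @return `glance`: one row per model with its mean MCC.
#' @method glance lnr_cv
#' @export
glance.lnr_cv <- function(x, ...) {
  x$report[, c("model", "mean_mcc")]
}

#' Tidy a GSEA comparison result
#'
#' @param x an `lnr_gsea` object.
#' @param ... unused.
#' @return one-row tibble with es, nes, p_value, set sizes.
#' @method tidy lnr_gsea
#' @export
tidy.lnr_gsea <- function(x, ...) tibble::as_tibble(x)
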
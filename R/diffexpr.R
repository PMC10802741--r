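#' Build a design matrix for the response contrast with clinical covariates
#'
#' Columns: intercept, non-responder indicator (the tested coefficient;
#' positive log-fold-changes mean higher expression in non-responders), and
#' the configured covariates. Race is excluded by default because of the
#' group imbalance in this cohort type; doses enter as continuous values.
#'
#' @param cohort per-sample tibble with `response` plus covariate columns.
#' @param covariates character vector of cohort columns to adjust for.
#' @return numeric design matrix (samples x terms) with a
#'   `"nonresponder"` column; attribute `coef` names the tested column.
#' @export
response_design <- function(cohort,
                            covariates = c("sex", "sledai",
                                           "prednisone_dose", "drug_dose")) {
  covariates <- intersect(covariates, names(cohort))
  df <- data.frame(nonresponder = as.numeric(cohort$response == "non-responder"))
  for (cv in covariates) {
    v <- cohort[[cv]]
    if (length(unique(v)) < 2) next  # constant in this subset; nothing to adjust
    df[[cv]] <- v
  }
  X <- stats::model.matrix(~ ., df)
  # drop aliased columns (e.g. a covariate constant within this subset)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    if (!(2 %in% keep)) stopf("response indicator is aliased in the design")
    X <- X[, sort(keep), drop = FALSE]
  }
  rownames(X) <- cohort$sample_id
  attr(X, "coef") <- "nonresponder"
  X
}

#' Consensus intra-patient correlation for repeated measures
#'
#' Longitudinal samples from one patient are correlated; rather than fitting
#' one random-effect model per gene, a single consensus intra-block
#' correlation is pooled across genes and reused in generalized least
#' squares. Per gene, fixed effects are removed by OLS and the intra-block
#' correlation of the residuals is estimated as the mean within-block
#' cross-product over the residual variance; the consensus is the
#' tanh of a 15%-trimmed mean of the atanh-transformed per-gene values.
#'
#' @param expr genes x samples log2 matrix.
#' @param blocks patient id per sample (aligned with `expr` columns).
#' @param design design matrix from [response_design()].
#' @param trim trimming fraction for the pooled mean.
#' @return scalar consensus correlation in (-1, 1); 0 with a warning when all
#'   blocks are singletons.
#' @export
estimate_consensus_correlation <- function(expr, blocks, design, trim = 0.15) {
  stopifnot(ncol(expr) == nrow(design), length(blocks) == ncol(expr))
  blocks <- as.character(blocks)
  sizes <- table(blocks)
  if (all(sizes < 2)) {
    warnf("all patient blocks are singletons; consensus correlation set to 0")
    return(0)
  }
  fit <- stats::lm.fit(design, t(expr))
  E <- fit$residuals                      # samples x genes
  n <- nrow(E); p <- qr(design)$rank
  bl <- split(seq_len(n), blocks)
  pairs <- sum(vapply(bl, function(i) length(i) * (length(i) - 1), 0))
  cross <- rowSums(vapply(bl, function(i) {
    if (length(i) < 2) return(numeric(ncol(E)))
    colSums(E[i, , drop = FALSE])^2 - colSums(E[i, , drop = FALSE]^2)
  }, numeric(ncol(E))))
  v <- colSums(E^2) / (n - p)
  r <- (cross / pairs) / v
  r <- pmin(pmax(r, -0.99), 0.99)
  r <- r[is.finite(r)]
  tanh(mean(atanh(r), trim = trim))
}

#' Moderated differential expression under block-equicorrelated errors
#'
#' Per gene, a generalized least squares fit under the working covariance
#' `sigma^2 [(1-rho) I + rho J]` within each patient block (rho from
#' [estimate_consensus_correlation()]), followed by empirical-Bayes variance
#' shrinkage: the residual variances `s_g^2` (d_g df) are assumed to follow a
#' scaled inverse-chi-square prior with hyperparameters `(d0, s0^2)` fitted
#' by moment-matching the marginal distribution of `log s_g^2`
#' (digamma/trigamma inversion). The posterior variance
#' `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` yields the moderated
#' t-statistic on `d0 + d_g` degrees of freedom.
#'
#' @param expr genes x samples log2 matrix.
#' @param design design matrix with the tested coefficient named in
#'   `attr(design, "coef")` (or pass `coef`).
#' @param blocks patient id per sample.
#' @param rho consensus correlation; computed from the data when NULL.
#' @param coef name of the tested design column.
#' @param d0_override force the prior degrees of freedom (0 disables
#'   shrinkage; mainly for testing limits).
#' @return An `lnr_de` tibble: gene, logFC, s2 (residual variance),
#'   df_residual, s2_post, t, p_value, p_bonferroni, direction, flag;
#'   attributes `d0`, `s0_2`, `rho`. Genes with zero variance are flagged
#'   "constant" and carry NA statistics.
#' @export
moderated_de <- function(expr, design, blocks, rho = NULL, coef = NULL,
                         d0_override = NULL) {
  coef <- coef %||% attr(design, "coef") %||% "nonresponder"
  stopifnot(coef %in% colnames(design), ncol(expr) == nrow(design))
  if (is.null(rho))
    rho <- estimate_consensus_correlation(expr, blocks, design)

  constant <- unname(apply(expr, 1, function(x) stats::sd(x) == 0))
  if (any(constant))
    warnf("%d constant gene rows flagged and skipped", sum(constant))

  # block whitening: R^{-1/2} = a (I - P1) + b P1 per block
  tw <- whiten_blocks(ncol(expr), as.character(blocks), rho)
  Yw <- t(tw(t(expr)))
  Xw <- tw(design)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(Xw)) stopf("design not full rank after GLS transform")
  n <- ncol(expr); p <- ncol(Xw); d_g <- n - p
  if (d_g <= 0) stopf("zero residual degrees of freedom")

  fit <- stats::lm.fit(Xw, t(Yw))
  j <- match(coef, colnames(design))
  beta <- unname(fit$coefficients[j, ])
  res <- as.matrix(fit$residuals)
  s2 <- unname(colSums(res^2)) / d_g
  xtxi <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  unscaled_se <- sqrt(xtxi[j, j])

  use <- !constant & s2 > 0
  if (!any(use)) stopf("no usable genes")
  if (!is.null(d0_override)) {
    d0 <- d0_override
    s0_2 <- if (d0 > 0) fit_fdist(s2[use], d_g)$s0_2 else NA_real_
  } else {
    fd <- fit_fdist(s2[use], d_g)
    d0 <- fd$d0; s0_2 <- fd$s0_2
  }
  if (d0 == 0) {
    s2_post <- s2
    df_total <- d_g
  } else if (!is.finite(d0) || d0 >= 1e6) {
    d0 <- 1e6
    s2_post <- rep(s0_2, length(s2))
    df_total <- d0 + d_g
  } else {
    s2_post <- (d0 * s0_2 + d_g * s2) / (d0 + d_g)
    df_total <- d0 + d_g
  }
  tstat <- beta / (unscaled_se * sqrt(s2_post))
  pval <- 2 * stats::pt(-abs(tstat), df_total)
  m <- sum(use)
  out <- tibble::tibble(
    gene = rownames(expr),
    logFC = beta,
    s2 = s2, df_residual = d_g, s2_post = s2_post,
    t = tstat, p_value = pval,
    p_bonferroni = pmin(1, pval * m),
    direction = ifelse(beta > 0, "up", "down"),
    flag = ifelse(constant, "constant", NA_character_)
  )
  out$t[!use] <- NA_real_
  out$p_value[!use] <- NA_real_
  out$p_bonferroni[!use] <- NA_real_
  structure(out, d0 = d0, s0_2 = s0_2, rho = rho, n_tested = m,
            class = c("lnr_de", class(out)))
}

# Returns a function applying the block-wise inverse square-root correlation
# transform to a (samples x k) matrix.
whiten_blocks <- function(n, blocks, rho) {
  bl <- split(seq_len(n), blocks)
  function(M) {
    M <- as.matrix(M)
    out <- M
    for (i in bl) {
      m <- length(i)
      a <- 1 / sqrt(1 - rho)
      b <- 1 / sqrt(1 - rho + m * rho)
      sub <- M[i, , drop = FALSE]
      mns <- matrix(colMeans(sub), m, ncol(M), byrow = TRUE)
      out[i, ] <- a * (sub - mns) + b * mns
    }
    out
  }
}

#' Fit the scaled inverse-chi-square prior of residual variances
#'
#' Moment-matching on `z = log s^2`: with `s^2 ~ s0^2 F(d, d0)`,
#' `E z = log s0^2 + psi(d/2) - log(d/2) - psi(d0/2) + log(d0/2)` and
#' `Var z = psi'(d/2) + psi'(d0/2)`. The trigamma equation is inverted by
#' Newton iteration (tolerance 1e-8); a non-positive excess variance returns
#' the infinity sentinel `d0 = 1e6` (all variances equal, no residual
#' spread beyond chi-square sampling noise).
#'
#' @param s2 positive residual variances.
#' @param df residual degrees of freedom (scalar or per-gene).
#' @return list with `d0` and `s0_2`.
#' @export
fit_fdist <- function(s2, df) {
  stopifnot(all(s2 > 0), all(df > 0))
  df <- rep_len(df, length(s2))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1)
  if (evar < 1e-12) {
    # no spread at all (degenerate input): the prior is the common variance
    return(list(d0 = 1e6, s0_2 = exp(mean(z))))
  }
  excess <- evar - mean(trigamma(df / 2))
  if (excess > 0 && is.finite(excess)) {
    d0 <- 2 * trigamma_inverse(excess)
    if (d0 >= 1e6) {
      d0 <- 1e6
      s0_2 <- exp(emean)
    } else {
      s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    }
  } else {
    d0 <- 1e6
    s0_2 <- exp(emean)
  }
  list(d0 = d0, s0_2 = s0_2)
}

# Solve trigamma(y) = x by Newton iteration.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) < 1e-8 * y) break
  }
  y
}

#' Extract Bonferroni-significant up/down signatures
#'
#' @param results an `lnr_de` table.
#' @param alpha significance level on the Bonferroni-corrected p-value
#'   (strict `<`).
#' @param drug label stored with the signature.
#' @return An `lnr_signature`: list with `drug`, `up`, `down` gene vectors
#'   (up = higher in non-responders) and the source statistics of the
#'   selected genes.
#' @export
bonferroni_signatures <- function(results, alpha = 0.05, drug = "drug") {
  stopifnot(nrow(results) > 0)
  sig <- results[!is.na(results$p_bonferroni) &
                   results$p_bonferroni < alpha, ]
  structure(list(
    drug = drug,
    up = sig$gene[sig$logFC > 0],
    down = sig$gene[sig$logFC < 0],
    stats = sig
  ), class = "lnr_signature")
}

#' @export
print.lnr_signature <- function(x, ...) {
  cat(sprintf("<lnr_signature %s: %d up, %d down>\n",
              x$drug, length(x$up), length(x$down)))
  invisible(x)
}

#' Up/down expression-ratio score per sample
#'
#' The ratio of the mean log2 expression over the up-signature genes to the
#' mean over the down-signature genes; a simple per-sample summary that
#' separates responders from non-responders when the signature is real.
#'
#' @param expr genes x samples log2 matrix.
#' @param signature an `lnr_signature` (or list with `up`/`down`).
#' @param offset added to the matrix before scoring; use a positive offset to
#'   re-anchor data whose down-gene mean is not positive.
#' @return tibble with `sample_id`, `score`.
#' @export
ratio_score <- function(expr, signature, offset = 0) {
  up <- intersect(signature$up, rownames(expr))
  dn <- intersect(signature$down, rownames(expr))
  if (!length(up) || !length(dn))
    stopf("signature up/down lists must be non-empty and present in the matrix")
  e <- expr + offset
  mu_up <- unname(colMeans(e[up, , drop = FALSE]))
  mu_dn <- unname(colMeans(e[dn, , drop = FALSE]))
  if (any(mu_dn <= 0))
    stopf(paste("down-gene mean <= 0 for some samples; re-anchor the matrix",
                "with a positive `offset`"))
  tibble::tibble(sample_id = colnames(expr), score = mu_up / mu_dn)
}

#' Compare ratio scores between response groups
#'
#' @param scores tibble from [ratio_score()].
#' @param groups group label per sample (aligned with `scores`).
#' @return tibble with group means and the two-sided Wilcoxon p-value.
#' @export
compare_ratio_scores <- function(scores, groups) {
  g <- as.factor(groups)
  stopifnot(nlevels(g) == 2)
  sp <- split(scores$score, g)
  tibble::tibble(
    group1 = levels(g)[1], group2 = levels(g)[2],
    mean1 = mean(sp[[1]]), mean2 = mean(sp[[2]]),
    p_value = stats::wilcox.test(sp[[1]], sp[[2]])$p.value
  )
}
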
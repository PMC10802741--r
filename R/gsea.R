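#' Weighted Kolmogorov-Smirnov enrichment score of a gene set
#'
#' The classic GSEA running sum over a ranked gene list: walking the list in
#' decreasing weight order, hits increment by `|w|^p / sum_set |w|^p` and
#' misses decrement by `1 / (N - N_set)`; the enrichment score (ES) is the
#' running sum's most extreme deviation from zero. Used here to compare the
#' non-response signature of one drug against the fold-change ranking of
#' another. Significance is assessed by gene-label permutation (random sets
#' of the same size), and the normalized ES divides by the mean |permuted ES|
#' of the same sign.
#'
#' @param ranked named numeric vector: ranking weights (e.g. log
#'   fold-changes) named by gene; sorted internally in decreasing order.
#' @param gene_set character vector, a strict non-empty subset of the ranked
#'   universe.
#' @param weight_exponent the GSEA exponent p (1 default; 0 gives the
#'   unweighted Kolmogorov-Smirnov statistic).
#' @param n_perm number of permutations (0 skips the permutation step; NES
#'   and p are then NA).
#' @param seed integer seed for the permutation RNG (required when
#'   `n_perm > 0`).
#' @return An `lnr_gsea` tibble row: `es`, `nes`, `p_value`, `n_set`,
#'   `n_universe`; the running sum is kept in attribute `running`.
#' @export
gsea_compare <- function(ranked, gene_set, weight_exponent = 1,
                         n_perm = 1000, seed = NULL) {
  stopifnot(is.numeric(ranked), !is.null(names(ranked)))
  universe <- names(ranked)
  gene_set <- unique(gene_set)
  if (!length(gene_set) || !all(gene_set %in% universe))
    stopf("gene_set must be a non-empty subset of the ranked universe")
  if (length(gene_set) >= length(universe))
    stopf("gene_set must be a strict subset of the universe")
  if (n_perm > 0 && is.null(seed))
    stopf("seed is required when n_perm > 0")

  ord <- order(ranked, decreasing = TRUE)
  w <- ranked[ord]
  hit <- names(w) %in% gene_set
  es_obs <- running_es(w, hit, weight_exponent)

  nes <- p_value <- NA_real_
  if (n_perm > 0) {
    null_es <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        h <- logical(length(w))
        h[sample(length(w), sum(hit))] <- TRUE
        running_es(w, h, weight_exponent)$es
      }, 0)
    })
    same <- null_es[sign(null_es) == sign(es_obs$es)]
    if (length(same)) {
      nes <- es_obs$es / mean(abs(same))
      p_value <- (1 + sum(abs(same) >= abs(es_obs$es))) / (1 + length(same))
    } else {
      nes <- sign(es_obs$es) * Inf
      p_value <- 1 / (1 + n_perm)
    }
  }
  structure(
    tibble::tibble(es = es_obs$es, nes = nes, p_value = p_value,
                   n_set = sum(hit), n_universe = length(w)),
    running = es_obs$running,
    class = c("lnr_gsea", class(tibble::tibble()))
  )
}

# Running sum and its extreme deviation for a ranked list with hit mask.
running_es <- function(w, hit, p) {
  n <- length(w)
  nh <- sum(hit)
  wp <- abs(w)^p
  nr <- sum(wp[hit])
  inc <- numeric(n)
  if (nr > 0) inc[hit] <- wp[hit] / nr else inc[hit] <- 1 / nh
  inc[!hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}
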
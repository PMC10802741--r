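#' Gini-Simpson and Gini-evenness diversity of a cell's count vector
#'
#' Both indices are computed on the detected (non-zero) genes so sparsity
#' does not dominate: `simpson = 1 - sum p_i^2` (Gini-Simpson) with `p_i`
#' the count fraction among detected genes, and `gini_diversity = 1 - G`
#' where `G` is the Gini coefficient of the detected-gene counts (so perfect
#' evenness gives 1). Low values mark cells whose library is concentrated in
#' a handful of genes.
#'
#' @param counts non-negative count vector for one cell.
#' @return named vector with `gini_diversity` and `simpson_diversity`.
#' @export
diversity_indices <- function(counts) {
  x <- counts[counts > 0]
  if (!length(x)) stopf("all-zero count vector")
  p <- x / sum(x)
  simpson <- 1 - sum(p^2)
  xs <- sort(x)
  n <- length(xs)
  gini <- (2 * sum(seq_len(n) * xs) / (n * sum(xs))) - (n + 1) / n
  c(gini_diversity = 1 - gini, simpson_diversity = simpson)
}

#' Per-cell QC metrics
#'
#' @param counts genes x cells count matrix; mitochondrial and ribosomal
#'   genes are identified by row-name prefix.
#' @param mito_prefix,ribo_prefix regular expressions matched against gene
#'   names (defaults "MT-" and "RPS"/"RPL").
#' @return tibble: `barcode`, `total_counts`, `n_features`, `mito_fraction`,
#'   `ribo_fraction`, `gini_diversity`, `simpson_diversity`.
#' @export
sc_qc_metrics <- function(counts, mito_prefix = "^MT-",
                          ribo_prefix = "^RP[SL]") {
  counts <- as.matrix(counts)
  mito <- grepl(mito_prefix, rownames(counts))
  ribo <- grepl(ribo_prefix, rownames(counts))
  tot <- colSums(counts)
  div <- apply(counts, 2, diversity_indices)
  tibble::tibble(
    barcode = colnames(counts),
    total_counts = tot,
    n_features = colSums(counts > 0),
    mito_fraction = if (any(mito)) colSums(counts[mito, , drop = FALSE]) / tot
                    else NA_real_,
    ribo_fraction = if (any(ribo)) colSums(counts[ribo, , drop = FALSE]) / tot
                    else NA_real_,
    gini_diversity = div["gini_diversity", ],
    simpson_diversity = div["simpson_diversity", ]
  )
}

#' Filter low-quality cells and uninformative genes
#'
#' Removes cells failing any active rule, all evaluated on the pre-filter
#' statistics (so rule order cannot matter): mitochondrial fraction > 25%,
#' ribosomal fraction > 25%, features or total counts outside the
#' [0.5, 99.5] percentile band of all cells, fewer than 200 detected
#' features, or Gini/Simpson diversity below 0.8. Afterwards genes expressed
#' in fewer than 5 kept cells, and the mitochondrial/ribosomal genes
#' themselves, are dropped. Any threshold can be set to NULL to disable the
#' rule; a mito/ribo rule with no matching genes is skipped with a warning.
#'
#' @param counts genes x cells count matrix.
#' @param mito_max,ribo_max fraction thresholds (default 0.25).
#' @param band percentile band for features/total counts
#'   (default c(0.005, 0.995)).
#' @param min_features minimum detected features (default 200).
#' @param min_diversity minimum Gini/Simpson diversity (default 0.8).
#' @param min_cells_per_gene gene kept if detected in at least this many
#'   kept cells (default 5).
#' @param mito_prefix,ribo_prefix gene-name patterns.
#' @return list: `counts` (filtered), `kept` barcodes, `report` (per-cell
#'   metrics with one logical column per rule and `kept`), `genes_removed`.
#' @export
qc_filter <- function(counts, mito_max = 0.25, ribo_max = 0.25,
                      band = c(0.005, 0.995), min_features = 200,
                      min_diversity = 0.8, min_cells_per_gene = 5,
                      mito_prefix = "^MT-", ribo_prefix = "^RP[SL]") {
  counts <- as.matrix(counts)
  rep <- sc_qc_metrics(counts, mito_prefix, ribo_prefix)
  fail <- rep(FALSE, ncol(counts))
  add_rule <- function(name, mask) {
    rep[[name]] <<- unname(mask)
    fail <<- fail | unname(mask)
  }
  if (!is.null(mito_max)) {
    if (all(is.na(rep$mito_fraction))) {
      warnf("no mitochondrial genes match '%s'; mito rule skipped", mito_prefix)
    } else add_rule("fail_mito", rep$mito_fraction > mito_max)
  }
  if (!is.null(ribo_max)) {
    if (all(is.na(rep$ribo_fraction))) {
      warnf("no ribosomal genes match '%s'; ribo rule skipped", ribo_prefix)
    } else add_rule("fail_ribo", rep$ribo_fraction > ribo_max)
  }
  if (!is.null(band)) {
    qf <- stats::quantile(rep$n_features, band)
    qt <- stats::quantile(rep$total_counts, band)
    add_rule("fail_band",
             rep$n_features < qf[1] | rep$n_features > qf[2] |
               rep$total_counts < qt[1] | rep$total_counts > qt[2])
  }
  if (!is.null(min_features))
    add_rule("fail_min_features", rep$n_features < min_features)
  if (!is.null(min_diversity))
    add_rule("fail_diversity", rep$gini_diversity < min_diversity |
               rep$simpson_diversity < min_diversity)
  rep$kept <- !fail
  kept <- colnames(counts)[!fail]
  sub <- counts[, !fail, drop = FALSE]
  drop_gene <- rowSums(sub > 0) < (min_cells_per_gene %||% 0)
  drop_gene <- drop_gene | grepl(mito_prefix, rownames(sub)) |
    grepl(ribo_prefix, rownames(sub))
  list(counts = sub[!drop_gene, , drop = FALSE],
       kept = kept, report = rep,
       genes_removed = rownames(sub)[drop_gene])
}

#' Library-size normalization to 1000 counts with log transform
#'
#' Each cell's counts are scaled to a fixed total of 1000 and `log(1 + x)`
#' transformed. Optional per-gene centering/scaling for downstream use.
#'
#' @param counts genes x cells count matrix (QC-filtered).
#' @param scale_total fixed per-cell total (default 1000).
#' @param center,scale standardize genes after the log transform.
#' @return genes x cells numeric matrix.
#' @export
sc_normalize <- function(counts, scale_total = 1000, center = FALSE,
                         scale = FALSE) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  if (any(tot == 0))
    stopf("zero-count cell(s): %s",
          paste(colnames(counts)[tot == 0], collapse = ", "))
  norm <- log1p(sweep(counts, 2, scale_total / tot, "*"))
  if (center || scale) {
    norm <- t(scale(t(norm), center = center, scale = scale))
    norm[is.na(norm)] <- 0
  }
  norm
}

#' Control-binned module score of a gene signature per cell
#'
#' The per-cell mean expression of a gene set minus the mean over matched
#' control genes: all genes are binned into `n_bins` by their mean expression
#' across cells, and for each signature gene `n_ctrl` control genes are drawn
#' from its bin (never from the signature itself; with replacement when a
#' bin is thin). A positive score means the set is expressed above
#' expression-matched background in that cell.
#'
#' @param norm_expr genes x cells normalized matrix from [sc_normalize()].
#' @param gene_set character vector of signature genes (those absent from
#'   the matrix are dropped; an entirely absent set is an error).
#' @param n_bins number of mean-expression bins (default 24).
#' @param n_ctrl control genes per signature gene (default 100).
#' @param seed integer seed for control sampling.
#' @return An `lnr_module_score` tibble: `barcode`, `score`; attributes
#'   record the gene set used, binning parameters and seed.
#' @export
module_score <- function(norm_expr, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  set_genes <- intersect(unique(gene_set), rownames(norm_expr))
  if (!length(set_genes)) stopf("gene set entirely absent from the matrix")
  gmeans <- rowMeans(norm_expr)
  bins <- dplyr::ntile(rank(gmeans, ties.method = "first"),
                       min(n_bins, length(gmeans)))
  names(bins) <- rownames(norm_expr)
  ctrl <- with_seed(seed, {
    unlist(lapply(set_genes, function(g) {
      # widen to neighbouring bins when the signature monopolizes its bin
      width <- 0
      repeat {
        in_bin <- abs(bins - bins[g]) <= width
        pool <- setdiff(names(bins)[in_bin], set_genes)
        if (length(pool) || width > max(bins)) break
        width <- width + 1
      }
      if (!length(pool))
        stopf("no control genes available for %s", g)
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }))
  })
  score <- colMeans(norm_expr[set_genes, , drop = FALSE]) -
    colMeans(norm_expr[ctrl, , drop = FALSE])
  structure(
    tibble::tibble(barcode = colnames(norm_expr), score = score),
    gene_set = set_genes, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed,
    class = c("lnr_module_score", class(tibble::tibble()))
  )
}

#' Cluster-vs-rest marker genes by Wilcoxon rank-sum test
#'
#' For every gene and cluster, a two-sided Wilcoxon rank-sum test of the
#' cluster's cells against all other cells, with the log fold change of mean
#' normalized expression and a Bonferroni correction over genes within each
#' cluster.
#'
#' @param norm_expr genes x cells normalized matrix.
#' @param labels cluster label per cell.
#' @param top_n convenience: number of markers flagged per cluster by
#'   adjusted p (default 10).
#' @return tibble: `cluster`, `gene`, `log_fc`, `p_value`, `p_bonferroni`,
#'   `rank`, `top` (within the top_n of the cluster).
#' @export
cluster_markers <- function(norm_expr, labels, top_n = 10) {
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(norm_expr))
  cl <- unique(labels)
  if (length(cl) < 2) stopf("need >= 2 clusters")
  out <- list()
  for (k in cl) {
    in_k <- labels == k
    if (sum(in_k) < 2) {
      warnf("cluster %s is a singleton; skipped", k)
      next
    }
    # exact distribution when both groups are small and tie-free (base R's
    # default choice); normal approximation with continuity correction
    # otherwise
    p <- unname(apply(norm_expr, 1, function(x)
      suppressWarnings(stats::wilcox.test(x[in_k], x[!in_k])$p.value)))
    lfc <- rowMeans(norm_expr[, in_k, drop = FALSE]) -
      rowMeans(norm_expr[, !in_k, drop = FALSE])
    tab <- tibble::tibble(cluster = k, gene = rownames(norm_expr),
                          log_fc = lfc, p_value = p,
                          p_bonferroni = pmin(1, p * nrow(norm_expr)))
    tab <- dplyr::arrange(tab, .data$p_bonferroni, dplyr::desc(abs(.data$log_fc)))
    tab$rank <- seq_len(nrow(tab))
    tab$top <- tab$rank <= top_n
    out[[k]] <- tab
  }
  purrr::list_rbind(out)
}

#' Maximum per-subcluster mean module score within each major cell type
#'
#' Summarizes a per-cell module score at the subcluster level (mean score)
#' and reports, for each major cell population, the maximum subcluster mean
#' and which subcluster attains it -- the summary used to attribute a
#' drug-non-response signature to specific cell subsets. Negative means are
#' kept as-is (no clipping).
#'
#' @param scores an `lnr_module_score` tibble (barcode, score).
#' @param labels subcluster label per cell, aligned with `scores`.
#' @param major_type major cell-type label per cell (or a named vector
#'   mapping subcluster -> major type).
#' @return tibble: `major_type`, `max_score`, `top_subcluster`, and
#'   `subcluster_means` list-column of the per-subcluster means.
#' @export
summarize_cluster_scores <- function(scores, labels, major_type) {
  stopifnot(length(labels) == nrow(scores))
  if (!is.null(names(major_type))) {
    major <- unname(major_type[as.character(labels)])
  } else {
    stopifnot(length(major_type) == nrow(scores))
    major <- as.character(major_type)
  }
  df <- tibble::tibble(score = scores$score,
                       subcluster = as.character(labels),
                       major_type = major)
  sub_means <- df |>
    dplyr::group_by(.data$major_type, .data$subcluster) |>
    dplyr::summarise(mean_score = mean(.data$score), n = dplyr::n(),
                     .groups = "drop")
  if (any(sub_means$n == 0)) stopf("empty subcluster")
  sub_means |>
    dplyr::group_by(.data$major_type) |>
    dplyr::summarise(
      max_score = max(.data$mean_score),
      top_subcluster = .data$subcluster[which.max(.data$mean_score)],
      subcluster_means = list(stats::setNames(.data$mean_score,
                                              .data$subcluster)),
      .groups = "drop")
}
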
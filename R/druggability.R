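#' Node input values from expression by reference-anchored rank scaling
#'
#' Each gene is scaled into (0, 1) by its mid-rank among the reference
#' samples, `(#{ref < x} + (#{ref == x} + 1)/2) / (n + 1)`; a node's value is
#' the mean of its member genes' scaled values. Anchoring the scaling on a
#' fixed reference matrix (by default the matrix itself) means a perturbed
#' expression value is re-ranked against the unperturbed distribution, so an
#' in-silico inhibition moves the node value down even though every sample is
#' perturbed identically.
#'
#' @param expr genes x samples matrix on a positive (linear) scale.
#' @param circuit an `lnr_circuit`.
#' @param reference matrix supplying the rank anchor (defaults to `expr`).
#' @return nodes x samples matrix of values in (0, 1).
#' @export
compute_node_values <- function(expr, circuit, reference = expr) {
  n_ref <- ncol(reference)
  scale_gene <- function(g) {
    ref <- reference[g, ]
    x <- expr[g, ]
    vapply(x, function(xi)
      (sum(ref < xi) + (sum(ref == xi) + 1) / 2) / (n_ref + 1), 0)
  }
  vals <- matrix(NA_real_, nrow(circuit$nodes), ncol(expr),
                 dimnames = list(circuit$nodes$node, colnames(expr)))
  for (i in seq_len(nrow(circuit$nodes))) {
    genes <- circuit$nodes$genes[[i]]
    present <- intersect(genes, rownames(expr))
    if (!length(present))
      stopf("node %s has no measured genes", circuit$nodes$node[i])
    if (length(present) < length(genes))
      warnf("node %s: dropping unmeasured genes %s", circuit$nodes$node[i],
            paste(setdiff(genes, present), collapse = ", "))
    sc <- vapply(present, scale_gene, numeric(ncol(expr)))
    vals[i, ] <- if (is.matrix(sc)) rowMeans(sc) else mean(sc)
  }
  vals
}

#' Propagate signal through a signed circuit
#'
#' In topological order, a receptor passes its own value through
#' (`S_r = v_r`); every other node combines its inputs as
#' `S_n = v_n * (1 - prod_activators (1 - S_a)) * prod_inhibitors (1 - S_i)`:
#' the node fires in proportion to its own availability, the probability
#' that at least one activator is active, and the probability that no
#' inhibitor is. The circuit's activity is the effector's signal. All
#' signals stay in [0, 1] for inputs in [0, 1].
#'
#' @param circuit an `lnr_circuit` (acyclic; cycles are an error naming the
#'   offending nodes).
#' @param node_values nodes x samples matrix from [compute_node_values()]
#'   (a plain named vector is treated as one sample).
#' @return list: `signal` (nodes x samples matrix) and `activity` (effector
#'   signal per sample).
#' @export
propagate <- function(circuit, node_values) {
  if (is.null(dim(node_values)))
    node_values <- matrix(node_values, ncol = 1,
                          dimnames = list(names(node_values), "s1"))
  ord <- topo_sort_circuit(circuit)
  stopifnot(all(ord %in% rownames(node_values)))
  S <- node_values[ord, , drop = FALSE] * NA_real_
  for (v in ord) {
    parents <- circuit$edges[circuit$edges$to == v, ]
    if (nrow(parents) == 0) {
      S[v, ] <- node_values[v, ]
    } else {
      act <- parents$from[parents$sign == 1L]
      inh <- parents$from[parents$sign == -1L]
      act_term <- if (length(act))
        1 - apply(1 - S[act, , drop = FALSE], 2, prod) else 0
      inh_term <- if (length(inh))
        apply(1 - S[inh, , drop = FALSE], 2, prod) else 1
      S[v, ] <- node_values[v, ] * act_term * inh_term
    }
  }
  effector <- circuit$nodes$node[circuit$nodes$role == "effector"]
  list(signal = S, activity = S[effector, ])
}

#' Simulate target inhibition on an expression matrix
#'
#' Multiplies the expression of the target genes by `factor` (0.1 by
#' default, the standard in-silico knock-down), leaving all other genes
#' untouched. Expression must be on a positive (linear) scale; anti-log
#' log2 data first.
#'
#' @param expr genes x samples matrix, positive scale.
#' @param targets character vector of target genes; an empty overlap with
#'   the matrix is an error listing the missing genes.
#' @param factor multiplicative inhibition factor.
#' @return the perturbed matrix.
#' @export
simulate_inhibition <- function(expr, targets, factor = 0.1) {
  if (!length(targets)) stopf("targets must be non-empty")
  hit <- intersect(targets, rownames(expr))
  if (!length(hit))
    stopf("no target overlaps the matrix; missing: %s",
          paste(targets, collapse = ", "))
  out <- expr
  out[hit, ] <- out[hit, ] * factor
  out
}

#' Per-patient response score to in-silico target inhibition
#'
#' For each sample, circuit activities are computed before and after
#' multiplying the target genes by `factor` (node values of the perturbed
#' matrix are re-ranked against the unperturbed reference); the response
#' score is the sum over circuits of the absolute change in activity. A
#' large score marks a patient whose circuit activities are strongly wired
#' through the targets.
#'
#' @param expr genes x samples matrix, positive scale.
#' @param circuits list of `lnr_circuit` objects.
#' @param targets character vector of target genes.
#' @param factor inhibition factor (default 0.1).
#' @return tibble: `sample_id`, `score` (>= 0), plus one
#'   `delta_<circuit id>` column per circuit.
#' @export
response_score <- function(expr, circuits, targets, factor = 0.1) {
  if (inherits(circuits, "lnr_circuit")) circuits <- list(circuits)
  circuit_genes <- unlist(lapply(circuits, function(cc) unlist(cc$nodes$genes)))
  if (!any(targets %in% circuit_genes))
    warnf("no circuit annotates any target gene; scores will be 0")
  perturbed <- simulate_inhibition(expr, targets, factor)
  deltas <- lapply(circuits, function(cc) {
    before <- propagate(cc, compute_node_values(expr, cc))$activity
    after <- propagate(cc, compute_node_values(perturbed, cc,
                                               reference = expr))$activity
    unname(abs(after - before))
  })
  out <- tibble::tibble(sample_id = colnames(expr),
                        score = Reduce(`+`, deltas))
  for (i in seq_along(circuits))
    out[[paste0("delta_", circuits[[i]]$id)]] <- deltas[[i]]
  out
}

#' Fraction of patients with a favorable anticipated response
#'
#' Favorable response to an in-silico inhibition: a response score greater
#' than or equal to the mean score over the whole cohort. The rate is the
#' fraction of favorable patients within a group of interest (typically the
#' non-responders to a drug), while the mean threshold is always taken over
#' all patients supplied.
#'
#' @param scores numeric response scores, one per patient (named or not).
#' @param group logical/index vector selecting the group whose rate is
#'   reported; defaults to all patients.
#' @return tibble: `rate` (fraction favorable in the group), `mean_score`
#'   (cohort threshold), `n_group`, `n_favorable`.
#' @export
favorable_rate <- function(scores, group = NULL) {
  if (!length(scores)) stopf("need >= 1 patient")
  thr <- mean(scores)
  g <- if (is.null(group)) rep(TRUE, length(scores)) else group
  sel <- scores[g]
  if (!length(sel)) stopf("empty group")
  tibble::tibble(rate = mean(sel >= thr), mean_score = thr,
                 n_group = length(sel), n_favorable = sum(sel >= thr))
}
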
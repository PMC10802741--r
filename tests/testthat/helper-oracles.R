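# Independent oracles used to cross-check the package's implementations.
# These are deliberately naive (enumeration / step-by-step recursion) and
# share no code with the functions they verify.

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins, summing tables at most as probable.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (no ties). Mirrors the classical doubling rule.
wilcox_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  all_v <- c(x, y)
  stopifnot(!any(duplicated(all_v)))
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  ws <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  lower <- mean(ws <= w_obs); upper <- mean(ws >= w_obs)
  min(1, 2 * min(lower, upper))
}

# GSEA running sum evaluated one step at a time.
gsea_oracle <- function(weights, hits, p) {
  weights <- unname(weights)
  n <- length(weights)
  nr <- sum(abs(weights[hits])^p)
  cur <- 0; best <- 0
  for (i in seq_len(n)) {
    if (hits[i]) {
      cur <- cur + if (nr > 0) abs(weights[i])^p / nr else 1 / sum(hits)
    } else {
      cur <- cur - 1 / (n - sum(hits))
    }
    if (abs(cur) > abs(best)) best <- cur
  }
  best
}

# Recursive (memoized) recomputation of circuit signal propagation.
propagate_oracle <- function(circuit, v) {
  memo <- new.env()
  eff <- circuit$nodes$node[circuit$nodes$role == "effector"]
  rec <- function(node) {
    if (!is.null(memo[[node]])) return(memo[[node]])
    parents <- circuit$edges[circuit$edges$to == node, ]
    s <- if (nrow(parents) == 0) {
      v[[node]]
    } else {
      act <- parents$from[parents$sign == 1]
      inh <- parents$from[parents$sign == -1]
      a <- if (length(act)) 1 - prod(1 - vapply(act, rec, 0)) else 0
      i <- if (length(inh)) prod(1 - vapply(inh, rec, 0)) else 1
      v[[node]] * a * i
    }
    memo[[node]] <- s
    s
  }
  vapply(circuit$nodes$node, rec, 0)
}

# Small hand-built activation chain R -> A -> E used across tests.
toy_chain <- function() {
  lupusnr:::new_circuit(
    nodes = tibble::tibble(
      node = c("R", "A", "E"),
      role = c("receptor", "intermediate", "effector"),
      genes = list("gR", "gA", "gE")),
    edges = tibble::tibble(from = c("R", "A"), to = c("A", "E"),
                           sign = c(1L, 1L)),
    id = "chain")
}

# Minimal visit table builder for label tests.
visits_tbl <- function(months, sledai, pga = rep(2, length(months)),
                       upcr = NULL, patient = "P1", drug = "MMF") {
  tb <- tibble::tibble(patient_id = patient, drug = drug,
                       visit_month = months, sledai = sledai, pga = pga)
  if (!is.null(upcr)) tb$upcr <- upcr
  tb
}
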
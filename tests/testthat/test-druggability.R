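test_that("rank scaling maps the sample maximum of 9 samples to 0.9", {
  expr <- matrix(1:9, 1, 9, dimnames = list("gR", sprintf("s%d", 1:9)))
  chain <- toy_chain()
  one_node <- lupusnr:::new_circuit(
    nodes = tibble::tibble(node = c("R", "E"),
                           role = c("receptor", "effector"),
                           genes = list("gR", "gR")),
    edges = tibble::tibble(from = "R", to = "E", sign = 1L))
  nv <- compute_node_values(expr, one_node)
  expect_equal(unname(nv["R", "s9"]), 0.9)
  expect_equal(unname(nv["R", "s1"]), 0.1)
  # single-gene nodes equal the gene's scaled value
  expect_equal(nv["R", ], nv["E", ])
})

test_that("inhibiting a top-ranked gene strictly decreases its scaled value", {
  expr <- matrix(c(1, 2, 3, 4, 50), 1, 5,
                 dimnames = list("gR", sprintf("s%d", 1:5)))
  circ <- lupusnr:::new_circuit(
    nodes = tibble::tibble(node = c("R", "E"),
                           role = c("receptor", "effector"),
                           genes = list("gR", "gR")),
    edges = tibble::tibble(from = "R", to = "E", sign = 1L))
  before <- compute_node_values(expr, circ)
  after <- compute_node_values(simulate_inhibition(expr, "gR"), circ,
                               reference = expr)
  expect_lt(after["R", "s5"], before["R", "s5"])
})

test_that("propagation reproduces hand-computed chain and inhibitor examples", {
  chain <- toy_chain()
  nv <- matrix(0.5, 3, 1, dimnames = list(c("R", "A", "E"), "s1"))
  pr <- propagate(chain, nv)
  expect_equal(unname(pr$signal["R", 1]), 0.5)
  expect_equal(unname(pr$signal["A", 1]), 0.25)
  expect_equal(unname(pr$signal["E", 1]), 0.125)
  expect_equal(unname(pr$activity), 0.125)
  # effector with one activator (S = 0.25) and one inhibitor (S = 0.5)
  mixed <- lupusnr:::new_circuit(
    nodes = tibble::tibble(node = c("A", "I", "E"),
                           role = c("receptor", "receptor", "effector"),
                           genes = list("ga", "gi", "ge")),
    edges = tibble::tibble(from = c("A", "I"), to = "E",
                           sign = c(1L, -1L)))
  nv2 <- matrix(c(0.25, 0.5, 0.5), 3, 1,
                dimnames = list(c("A", "I", "E"), "s1"))
  expect_equal(unname(propagate(mixed, nv2)$activity), 0.5 * 0.25 * 0.5)
  # a zero receptor extinguishes the chain
  nv0 <- nv; nv0["R", ] <- 0
  expect_true(all(propagate(chain, nv0)$signal[c("A", "E"), ] == 0))
})

test_that("propagation matches a brute-force recursion on random circuits", {
  circuits <- generate_circuits(100, 8, inhibitor_fraction = 0.3, seed = 17)
  withr::with_seed(18, {
    for (cc in circuits) {
      v <- stats::setNames(runif(nrow(cc$nodes)), cc$nodes$node)
      got <- propagate(cc, v)$signal[, 1]
      want <- propagate_oracle(cc, as.list(v))
      expect_equal(got[names(want)], want, tolerance = 1e-12)
      expect_true(all(got >= 0 & got <= 1))
    }
  })
})

test_that("signal is monotone in activators and anti-monotone in inhibitors", {
  circuits <- generate_circuits(30, 6, inhibitor_fraction = 0.4, seed = 19)
  withr::with_seed(20, {
    for (cc in circuits) {
      v <- stats::setNames(runif(nrow(cc$nodes), 0.2, 0.8), cc$nodes$node)
      base_act <- propagate(cc, v)$activity
      eff <- cc$nodes$node[cc$nodes$role == "effector"]
      for (e in seq_len(nrow(cc$edges))) {
        src <- cc$edges$from[e]
        if (cc$edges$to[e] != eff) next
        # a node with other outgoing edges can reach the effector along
        # paths of mixed sign; the edge-wise monotonicity claim is about
        # nodes acting purely through this edge
        if (sum(cc$edges$from == src) > 1) next
        v2 <- v; v2[src] <- min(1, v[src] + 0.15)
        new_act <- propagate(cc, v2)$activity
        if (cc$edges$sign[e] == 1L) expect_gte(new_act + 1e-12, base_act)
        else expect_lte(new_act - 1e-12, base_act)
      }
    }
  })
})

test_that("target inhibition multiplies expression by the factor", {
  expr <- matrix(c(8, 2), 2, 1, dimnames = list(c("t", "u"), "s1"))
  out <- simulate_inhibition(expr, "t", factor = 0.1)
  expect_equal(out["t", 1], 0.8)
  expect_equal(out["u", 1], 2)
  expect_identical(simulate_inhibition(expr, "t", factor = 1), expr)
  expect_error(simulate_inhibition(expr, "absent"), "missing: absent")
  expect_error(simulate_inhibition(expr, character(0)), "non-empty")
})

test_that("the response score reproduces the hand-computed chain value", {
  # construct expression so that before: v = 0.5 everywhere, and inhibiting
  # gA drops v_A to 0.05: 9 reference samples, target sample in the middle,
  # inhibited value below every reference
  chain <- toy_chain()
  n <- 9
  expr <- rbind(gR = 1:n, gA = 1:n, gE = 1:n)
  colnames(expr) <- sprintf("s%d", 1:n)
  before <- propagate(chain, compute_node_values(expr, chain))$activity
  expect_equal(unname(before["s5"]), 0.125)   # v = 0.5 at mid-rank, 0.5^3
  perturbed <- simulate_inhibition(expr, "gA", 0.01)
  after <- propagate(chain, compute_node_values(perturbed, chain,
                                                reference = expr))$activity
  # v_A after inhibition: every perturbed value ranks below all references
  expect_equal(unname(compute_node_values(perturbed, chain,
                                          reference = expr)["A", "s5"]),
               0.05)
  sc <- response_score(expr, chain, "gA", factor = 0.01)
  # after: S_A = 0.05 * 0.5 = 0.025, S_E = 0.5 * 0.025 = 0.0125
  expect_equal(sc$score[5], abs(0.125 - 0.0125), tolerance = 1e-12)
  expect_equal(sc$score[5], 0.1125, tolerance = 1e-12)
})

test_that("scores vanish for out-of-circuit targets and identity perturbations", {
  chain <- toy_chain()
  expr <- rbind(gR = 1:5, gA = 1:5, gE = 1:5, gX = 1:5)
  colnames(expr) <- sprintf("s%d", 1:5)
  expect_warning(sc <- response_score(expr, chain, "gX"), "no circuit")
  expect_true(all(sc$score == 0))
  sc1 <- response_score(expr, chain, "gA", factor = 1)
  expect_true(all(sc1$score == 0))
})

test_that("favorable rate uses an inclusive cohort-mean threshold", {
  out <- favorable_rate(c(1, 2, 3, 10))
  expect_equal(out$rate, 0.25)
  expect_equal(out$mean_score, 4)
  # equal scores: everyone favorable
  expect_equal(favorable_rate(rep(2, 5))$rate, 1)
  # single patient is its own mean
  expect_equal(favorable_rate(5)$rate, 1)
  # group filter: rate within group, mean over all
  out2 <- favorable_rate(c(1, 2, 3, 10), group = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out2$rate, 0)
  expect_equal(out2$mean_score, 4)
  expect_error(favorable_rate(numeric(0)), ">= 1 patient")
  expect_error(favorable_rate(c(1, 2), group = c(FALSE, FALSE)),
               "empty group")
})

test_that("up-shifted target pathways raise the arm's mean response score", {
  chain <- toy_chain()
  withr::with_seed(23, {
    n <- 40
    expr <- matrix(2^rnorm(3 * n, 7, 1), 3, n,
                   dimnames = list(c("gR", "gA", "gE"),
                                   sprintf("s%d", 1:n)))
    shifted <- seq_len(n) <= n / 2
    expr["gA", shifted] <- expr["gA", shifted] * 4
    expr["gR", shifted] <- expr["gR", shifted] * 4
  })
  sc <- response_score(expr, chain, c("gR", "gA"))
  expect_gt(mean(sc$score[shifted]), mean(sc$score[!shifted]))
})
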
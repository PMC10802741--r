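make_gls_fixture <- function(np = 50, nv = 3, ng = 300, sigma_p = 0.5,
                             sigma_e = 0.5, seed = 1) {
  withr::with_seed(seed, {
    pat <- rep(sprintf("P%02d", 1:np), each = nv)
    grp <- rep(rep(0:1, length.out = np), each = nv)
    X <- cbind("(Intercept)" = 1, nonresponder = grp)
    attr(X, "coef") <- "nonresponder"
    b <- rnorm(np, 0, sigma_p)
    Y <- matrix(rnorm(ng * np * nv, 0, sigma_e), ng) +
      rep(b, each = nv)[col(matrix(0, ng, np * nv))]
    dimnames(Y) <- list(sprintf("g%03d", 1:ng), sprintf("s%03d", 1:(np * nv)))
    list(Y = Y, X = X, pat = pat)
  })
}

test_that("consensus correlation recovers the intra-patient ICC", {
  fx <- make_gls_fixture(np = 50, nv = 3, ng = 500, sigma_p = 0.5,
                         sigma_e = 0.5, seed = 2)
  rho <- estimate_consensus_correlation(fx$Y, fx$pat, fx$X)
  expect_lt(abs(rho - 0.5), 0.1)   # ICC = sigma_p^2 / (sigma_p^2 + sigma_e^2)
  fx0 <- make_gls_fixture(np = 50, nv = 3, ng = 500, sigma_p = 0,
                          sigma_e = 0.5, seed = 3)
  rho0 <- estimate_consensus_correlation(fx0$Y, fx0$pat, fx0$X)
  expect_lt(abs(rho0), 0.05)
})

test_that("all-singleton blocks give rho 0 with a warning", {
  fx <- make_gls_fixture(np = 30, nv = 1, ng = 50, seed = 4)
  expect_warning(rho <- estimate_consensus_correlation(fx$Y, fx$pat, fx$X),
                 "singleton")
  expect_identical(rho, 0)
})

test_that("consensus correlation agrees with the established mixed-model estimate", {
  skip_if_not_installed("limma")
  fx <- make_gls_fixture(np = 40, nv = 3, ng = 300, seed = 5)
  rho <- estimate_consensus_correlation(fx$Y, fx$pat, fx$X)
  ref <- limma::duplicateCorrelation(fx$Y, fx$X, block = fx$pat)
  expect_lt(abs(rho - ref$consensus.correlation), 0.05)
})

test_that("with rho = 0 and no covariates the moderated fit matches an OLS oracle", {
  fx <- make_gls_fixture(np = 20, nv = 1, ng = 40, sigma_p = 0, seed = 6)
  de <- moderated_de(fx$Y, fx$X, fx$pat, rho = 0, d0_override = 0)
  grp <- fx$X[, "nonresponder"]
  for (i in c(1, 7, 40)) {
    fit <- summary(stats::lm(fx$Y[i, ] ~ grp))$coefficients
    expect_equal(de$logFC[i], fit["grp", "Estimate"], tolerance = 1e-8)
    expect_equal(de$t[i], fit["grp", "t value"], tolerance = 1e-8)
    expect_equal(de$p_value[i], fit["grp", "Pr(>|t|)"], tolerance = 1e-8)
  }
})

test_that("d0 = 0 disables shrinkage and identical variances hit the infinity sentinel", {
  fx <- make_gls_fixture(np = 15, nv = 2, ng = 60, seed = 7)
  plain <- moderated_de(fx$Y, fx$X, fx$pat, rho = 0.3, d0_override = 0)
  expect_equal(plain$s2_post, plain$s2, tolerance = 1e-12)
  # force identical residual variances by scaling each gene's residual spread
  fd <- fit_fdist(rep(2, 100), 10)
  expect_identical(fd$d0, 1e6)
  expect_equal(fd$s0_2, 2, tolerance = 1e-10)
})

test_that("posterior variances interpolate between the gene and prior variances", {
  fx <- make_gls_fixture(np = 30, nv = 2, ng = 400, seed = 8)
  de <- moderated_de(fx$Y, fx$X, fx$pat)
  s0 <- attr(de, "s0_2")
  lo <- pmin(de$s2, s0); hi <- pmax(de$s2, s0)
  expect_true(all(de$s2_post >= lo - 1e-12 & de$s2_post <= hi + 1e-12))
})

test_that("empirical-Bayes hyperparameters are recovered from simulated variances", {
  withr::with_seed(10, {
    d0 <- 4; s0_2 <- 2; d <- 10; m <- 2000
    sigma2 <- s0_2 * d0 / rchisq(m, d0)
    s2 <- sigma2 * rchisq(m, d) / d
  })
  fd <- fit_fdist(s2, 10)
  expect_lt(abs(fd$d0 - 4), 1)
  expect_lt(abs(fd$s0_2 - 2), 0.3)
})

test_that("moderated statistics match the established empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  # heterogeneous true variances from the scaled inverse-chi-square prior so
  # the shrinkage hyperparameters are genuinely estimated
  fx <- withr::with_seed(11, {
    np <- 25; ng <- 200
    grp <- rep(0:1, length.out = np)
    X <- cbind("(Intercept)" = 1, nonresponder = grp)
    attr(X, "coef") <- "nonresponder"
    sigma <- sqrt(1 * 5 / rchisq(ng, 5))
    Y <- matrix(rnorm(ng * np), ng) * sigma
    dimnames(Y) <- list(sprintf("g%03d", 1:ng), sprintf("s%03d", 1:np))
    list(Y = Y, X = X, pat = sprintf("P%02d", 1:np))
  })
  de <- moderated_de(fx$Y, fx$X, fx$pat, rho = 0)
  lfit <- limma::eBayes(limma::lmFit(fx$Y, fx$X))
  expect_equal(de$logFC, unname(lfit$coefficients[, "nonresponder"]),
               tolerance = 1e-10)
  expect_equal(attr(de, "d0"), lfit$df.prior, tolerance = 0.05)
  expect_equal(de$t, unname(lfit$t[, "nonresponder"]), tolerance = 1e-4)
})

test_that("constant genes are flagged and excluded from testing", {
  fx <- make_gls_fixture(np = 10, nv = 2, ng = 30, seed = 12)
  fx$Y[3, ] <- 5
  expect_warning(de <- moderated_de(fx$Y, fx$X, fx$pat, rho = 0),
                 "constant")
  expect_identical(de$flag[3], "constant")
  expect_true(is.na(de$p_value[3]))
})

test_that("Bonferroni signature selection uses a strict threshold", {
  de <- tibble::tibble(gene = sprintf("g%d", 1:100),
                       logFC = rep(c(1, -1), 50),
                       p_value = rep(1, 100),
                       p_bonferroni = rep(1, 100))
  de$p_value[1] <- 4e-4
  de$p_bonferroni[1] <- min(1, 4e-4 * 100)   # 0.04 < 0.05 -> selected
  de$p_value[2] <- 5e-4
  de$p_bonferroni[2] <- min(1, 5e-4 * 100)   # exactly alpha -> excluded
  sg <- bonferroni_signatures(de, alpha = 0.05, drug = "MMF")
  expect_identical(sg$up, "g1")
  expect_length(sg$down, 0)
  # all-null input gives an empty but valid signature
  sg0 <- bonferroni_signatures(de[3:100, ], drug = "MMF")
  expect_length(sg0$up, 0)
  expect_length(sg0$down, 0)
})

test_that("ratio score is the mean-up over mean-down ratio", {
  expr <- matrix(c(4, 6, 2, 3), 4, 1,
                 dimnames = list(c("u1", "u2", "d1", "d2"), "s1"))
  sg <- list(up = c("u1", "u2"), down = c("d1", "d2"))
  expect_equal(ratio_score(expr, sg)$score, 2.0)
  expect_equal(ratio_score(expr, list(up = c("u1", "u2"),
                                      down = c("u1", "u2")))$score, 1.0)
  neg <- matrix(c(1, -2), 2, 1, dimnames = list(c("u", "d"), "s1"))
  expect_error(ratio_score(neg, list(up = "u", down = "d")), "offset")
  expect_error(ratio_score(expr, list(up = character(0), down = "d1")),
               "non-empty")
})

test_that("planted signatures separate arms by the ratio score", {
  sim <- generate_bulk_cohort(bulk_sim_config(n_patients_per_arm = 20,
                                              visits_per_patient = 1,
                                              n_genes = 200, effect_size = 1,
                                              noise_sd = 0.5, drugs = "MMF",
                                              seed = 21))
  sg <- list(up = sim$truth$planted$MMF$up, down = sim$truth$planted$MMF$down)
  rs <- ratio_score(sim$expr, sg)
  cmp <- compare_ratio_scores(rs, sim$cohort$response)
  expect_lt(cmp$p_value, 0.01)
})
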
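#' Configuration for the synthetic longitudinal bulk cohort
#'
#' Defines the statistical structure of the simulated cohort: a two-arm
#' (responder / non-responder) longitudinal design per drug, log2-scale
#' expression with a per-patient random intercept (the repeated-measures
#' component), planted up/down non-response signatures applied only to
#' non-responders of the matching drug, and clinical covariates with
#' visit-level SLEDAI/PGA/UPCR trajectories.
#'
#' @param n_patients_per_arm patients per response arm, per drug.
#' @param visits_per_patient visits per patient; visits are spaced 3 months
#'   apart starting at month 0.
#' @param n_genes total genes in the expression matrix.
#' @param n_up,n_down planted up-/down-regulated genes per drug (up = higher
#'   in non-responders, the fixed contrast orientation used throughout).
#' @param effect_size planted shift delta, in log2 units.
#' @param patient_sd standard deviation sigma_p of the patient random
#'   intercept (log2 units).
#' @param noise_sd residual standard deviation sigma_e (log2 units).
#' @param beta_sex,beta_sledai covariate effect sizes: log2 shift applied to a
#'   random 10% of genes per covariate.
#' @param drugs character vector of drug arms to simulate.
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A `bulk_sim_config` list.
#' @export
bulk_sim_config <- function(n_patients_per_arm = 15,
                            visits_per_patient = 3,
                            n_genes = 1000,
                            n_up = 20,
                            n_down = 20,
                            effect_size = 1,
                            patient_sd = 0.5,
                            noise_sd = 0.5,
                            beta_sex = 0.2,
                            beta_sledai = 0.02,
                            drugs = c("MMF", "AZA"),
                            seed = 1L) {
  cfg <- list(
    n_patients_per_arm = as.integer(n_patients_per_arm),
    visits_per_patient = as.integer(visits_per_patient),
    n_genes = as.integer(n_genes),
    n_up = as.integer(n_up), n_down = as.integer(n_down),
    effect_size = effect_size,
    patient_sd = patient_sd, noise_sd = noise_sd,
    beta_sex = beta_sex, beta_sledai = beta_sledai,
    drugs = drugs, seed = as.integer(seed)
  )
  if (any(c(cfg$n_patients_per_arm, cfg$visits_per_patient, cfg$n_genes) < 1))
    stopf("cohort dimensions must be >= 1")
  if (cfg$patient_sd < 0 || cfg$noise_sd < 0)
    stopf("standard deviations must be non-negative")
  needed <- length(cfg$drugs) * (cfg$n_up + cfg$n_down)
  if (needed > cfg$n_genes)
    stopf("planted genes (%d) exceed n_genes (%d); up/down sets must be disjoint",
          needed, cfg$n_genes)
  structure(cfg, class = "bulk_sim_config")
}

#' Simulate a longitudinal bulk expression cohort with known ground truth
#'
#' Generates log2-scale expression `y_gij = mu_g + b_i + covariates + planted
#' effect + e_ij` with patient intercept `b_i ~ N(0, sigma_p^2)` and residual
#' `e_ij ~ N(0, sigma_e^2)`. Planted up (down) genes are shifted by +delta
#' (-delta) in non-responders of the matching drug arm only, so signatures are
#' drug-specific by construction. Visit-level SLEDAI/PGA/UPCR series are
#' emitted so the clinical labelling stage reproduces the planted response
#' arms: responders drop >= 4 SLEDAI points by month 3 and keep the drop,
#' non-responders never do; responders' UPCR falls below 500 mg/g and stays
#' there.
#'
#' @param config a [bulk_sim_config()].
#' @return list with `expr` (genes x samples log2 matrix), `cohort`
#'   (per-sample clinical tibble), and `truth` (planted gene sets per drug and
#'   true per-patient response labels).
#' @export
generate_bulk_cohort <- function(config = bulk_sim_config()) {
  stopifnot(inherits(config, "bulk_sim_config"))
  c_ <- config
  with_seed(c_$seed, {
    genes <- sprintf("G%04d", seq_len(c_$n_genes))
    # disjoint planted blocks, one up + one down set per drug
    planted <- list()
    idx <- 0
    for (d in c_$drugs) {
      up <- genes[idx + seq_len(c_$n_up)]; idx <- idx + c_$n_up
      dn <- genes[idx + seq_len(c_$n_down)]; idx <- idx + c_$n_down
      planted[[d]] <- list(up = up, down = dn)
    }

    arms <- tidyr::expand_grid(
      drug = c_$drugs,
      response = c("responder", "non-responder"),
      rep = seq_len(c_$n_patients_per_arm)
    )
    arms$patient_id <- sprintf("P%03d", seq_len(nrow(arms)))

    months <- 3 * (seq_len(c_$visits_per_patient) - 1)
    cohort <- tidyr::expand_grid(arms, visit_month = months)
    cohort$sample_id <- sprintf("S%04d", seq_len(nrow(cohort)))

    n_pat <- nrow(arms)
    b_pat <- stats::setNames(rnorm(n_pat, 0, c_$patient_sd), arms$patient_id)
    cohort$sex <- stats::setNames(sample(c("F", "M"), n_pat, TRUE, c(0.9, 0.1)),
                                  arms$patient_id)[cohort$patient_id]
    cohort$race <- stats::setNames(
      sample(c("C", "AA", "O"), n_pat, TRUE, c(0.45, 0.45, 0.1)),
      arms$patient_id)[cohort$patient_id]

    nonresp <- cohort$response == "non-responder"
    first <- cohort$visit_month == 0
    post <- cohort$visit_month >= 3
    # SLEDAI: everyone starts ~10; responders drop >= 4 from month 3 onward
    sled <- integer(nrow(cohort))
    sled[first] <- 10L + sample(0:2, sum(first), TRUE)
    base_by_pat <- stats::setNames(sled[first], cohort$patient_id[first])
    base <- base_by_pat[cohort$patient_id]
    sled[post & !nonresp] <- pmax(0L, base[post & !nonresp] - 4L -
                                    sample(0:2, sum(post & !nonresp), TRUE))
    sled[post & nonresp] <- pmax(0L, base[post & nonresp] -
                                   sample(0:2, sum(post & nonresp), TRUE))
    cohort$sledai <- sled
    # PGA: stable for responders (< 0.3 worsening), worsening for some NR
    pga0 <- round(runif(n_pat, 1.2, 2.4), 1)
    cohort$pga <- stats::setNames(pga0, arms$patient_id)[cohort$patient_id] +
      ifelse(post, round(runif(nrow(cohort), -0.2, 0.2), 2), 0)
    # UPCR: baseline >= 500, responders fall and stay below
    up0 <- runif(n_pat, 600, 1500)
    cohort$upcr <- stats::setNames(up0, arms$patient_id)[cohort$patient_id]
    cohort$upcr[post & !nonresp] <- runif(sum(post & !nonresp), 100, 450)
    cohort$upcr[post & nonresp] <- runif(sum(post & nonresp), 520, 1600)
    cohort$upcr <- round(cohort$upcr)

    cohort$prednisone_dose <- round(ifelse(nonresp, rgamma(nrow(cohort), 2, 0.3),
                                           rgamma(nrow(cohort), 2, 0.5)), 1)
    cohort$drug_dose <- round(ifelse(cohort$drug == "MMF", 1500, 150) *
                                runif(nrow(cohort), 0.7, 1.3))

    # expression: baseline means, patient intercept, covariates, planted shift
    mu <- rnorm(c_$n_genes, 7, 1)
    n_smp <- nrow(cohort)
    expr <- matrix(rnorm(c_$n_genes * n_smp, 0, c_$noise_sd),
                   c_$n_genes, n_smp, dimnames = list(genes, cohort$sample_id))
    expr <- expr + mu + rep(b_pat[cohort$patient_id], each = c_$n_genes)
    sex_genes <- sample(c_$n_genes, ceiling(c_$n_genes / 10))
    sled_genes <- sample(c_$n_genes, ceiling(c_$n_genes / 10))
    expr[sex_genes, ] <- expr[sex_genes, ] +
      c_$beta_sex * rep(as.numeric(cohort$sex == "M"), each = length(sex_genes))
    expr[sled_genes, ] <- expr[sled_genes, ] +
      c_$beta_sledai * rep(cohort$sledai, each = length(sled_genes))
    for (d in c_$drugs) {
      tgt <- nonresp & cohort$drug == d
      expr[planted[[d]]$up, tgt] <- expr[planted[[d]]$up, tgt] + c_$effect_size
      expr[planted[[d]]$down, tgt] <- expr[planted[[d]]$down, tgt] - c_$effect_size
    }

    cohort <- tibble::as_tibble(cohort[, c("sample_id", "patient_id", "drug",
                                           "response", "visit_month", "sex",
                                           "race", "sledai", "pga", "upcr",
                                           "prednisone_dose", "drug_dose")])
    truth <- list(
      planted = planted,
      response = dplyr::distinct(cohort, .data$patient_id, .data$drug,
                                 .data$response),
      seed = c_$seed
    )
    list(expr = expr, cohort = cohort, truth = truth)
  })
}
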
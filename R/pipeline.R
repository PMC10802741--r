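#' Configuration for an end-to-end pipeline run
#'
#' Flat key-value configuration: stage toggles, simulation configs and stage
#' parameters with the package defaults. Stages consume each other's outputs
#' (labels need the cohort, signatures need the DE results, and so on);
#' dependencies are validated before anything runs.
#'
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "label", "de", "signatures", "compare", "ratio",
#'   "deconvolve", "stratify", "sc", "druggability", "cv")`.
#' @param seed master seed; each stage derives its own sub-seed from it.
#' @param bulk,sc [bulk_sim_config()] / [sc_sim_config()] for the simulate
#'   stages.
#' @param alpha Bonferroni significance level for signatures.
#' @param basis_types,basis_genes,basis_mixtures signature-basis simulation
#'   sizes.
#' @param n_circuits,nodes_per_circuit circuit simulation sizes.
#' @param inhibition_factor in-silico inhibition factor.
#' @param cv_models model names for the nested-CV stage.
#' @param cv_top_n number of top DEGs (by adjusted p) used as features.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(stages = c("simulate", "label", "de",
                                       "signatures", "compare", "ratio",
                                       "deconvolve", "stratify", "sc",
                                       "druggability", "cv"),
                            seed = 1L,
                            bulk = bulk_sim_config(seed = seed),
                            sc = sc_sim_config(seed = seed + 1L),
                            alpha = 0.05,
                            basis_types = 5, basis_genes = 100,
                            basis_mixtures = 20,
                            n_circuits = 3, nodes_per_circuit = 5,
                            inhibition_factor = 0.1,
                            cv_models = c("glm", "lda", "random_forest"),
                            cv_top_n = 10) {
  all_stages <- c("simulate", "label", "de", "signatures", "compare",
                  "ratio", "deconvolve", "stratify", "sc", "druggability",
                  "cv")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stages: %s", paste(bad, collapse = ", "))
  deps <- list(label = "simulate", de = "simulate", signatures = "de",
               compare = "signatures", ratio = "signatures",
               deconvolve = "simulate", stratify = "deconvolve",
               sc = character(0), druggability = c("simulate", "signatures"),
               cv = c("simulate", "de"))
  for (s in stages) {
    missing_dep <- setdiff(deps[[s]] %||% character(0), stages)
    if (length(missing_dep))
      stopf("stage '%s' requires stage(s): %s", s,
            paste(missing_dep, collapse = ", "))
  }
  structure(list(stages = stages, seed = as.integer(seed), bulk = bulk,
                 sc = sc, alpha = alpha, basis_types = basis_types,
                 basis_genes = basis_genes, basis_mixtures = basis_mixtures,
                 n_circuits = n_circuits,
                 nodes_per_circuit = nodes_per_circuit,
                 inhibition_factor = inhibition_factor,
                 cv_models = cv_models, cv_top_n = cv_top_n),
            class = "pipeline_config")
}

#' Run the non-response analysis pipeline end to end
#'
#' Executes the enabled stages in order -- simulate, clinical labelling,
#' moderated DE, Bonferroni signatures, cross-drug GSEA comparison, ratio
#' scores, deconvolution and rich/poor stratification with response-rate
#' tests, single-cell QC/normalization/module scoring, in-silico
#' druggability, and nested-CV response prediction -- writing each stage's
#' tables under `outdir` plus a reproducibility manifest
#' (`manifest.json`: config hash, seeds, package version, per-stage row
#' counts). Identical config + seed gives byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  on <- function(s) s %in% config$stages
  res <- list()
  manifest <- list(
    package_version = as.character(utils::packageVersion("lupusnr")),
    seed = config$seed,
    stages = config$stages,
    config_hash = unname(config_hash(config)),
    counts = list())
  note <- function(stage, n) manifest$counts[[stage]] <<- n
  log_stage <- function(s) message(sprintf("[lupusnr] stage %s", s))

  if (on("simulate")) {
    log_stage("simulate")
    res$bulk <- generate_bulk_cohort(config$bulk)
    write_expression_tsv(res$bulk$expr, file.path(outdir, "expression.tsv"))
    readr::write_csv(res$bulk$cohort, file.path(outdir, "cohort.csv"))
    res$basis <- generate_signature_basis(config$basis_types,
                                          config$basis_genes,
                                          config$basis_mixtures,
                                          seed = config$seed + 2L)
    res$circuits <- generate_circuits(config$n_circuits,
                                      config$nodes_per_circuit,
                                      seed = config$seed + 3L)
    note("simulate", ncol(res$bulk$expr))
  }
  if (on("label")) {
    log_stage("label")
    res$labels_sri4 <- derive_sri4_response(res$bulk$cohort)
    readr::write_csv(res$labels_sri4, file.path(outdir, "labels_sri4.csv"))
    note("label", nrow(res$labels_sri4))
  }
  drugs <- if (on("de")) unique(res$bulk$cohort$drug) else character(0)
  if (on("de")) {
    log_stage("de")
    res$de <- lapply(stats::setNames(drugs, drugs), function(d) {
      idx <- res$bulk$cohort$drug == d
      design <- response_design(res$bulk$cohort[idx, ])
      moderated_de(res$bulk$expr[, idx], design,
                   blocks = res$bulk$cohort$patient_id[idx])
    })
    for (d in drugs)
      readr::write_tsv(tibble::as_tibble(res$de[[d]]),
                       file.path(outdir, sprintf("de_%s.tsv", d)))
    note("de", sum(vapply(res$de, nrow, 0)))
  }
  if (on("signatures")) {
    log_stage("signatures")
    res$signatures <- lapply(stats::setNames(drugs, drugs), function(d)
      bonferroni_signatures(res$de[[d]], alpha = config$alpha, drug = d))
    sets <- list()
    for (d in drugs) {
      sets[[paste0(d, "_up")]] <- res$signatures[[d]]$up
      sets[[paste0(d, "_down")]] <- res$signatures[[d]]$down
    }
    write_gmt(sets, file.path(outdir, "signatures.gmt"))
    note("signatures", length(sets))
  }
  if (on("compare") && length(drugs) > 1) {
    log_stage("compare")
    rows <- list()
    for (d1 in drugs) for (d2 in setdiff(drugs, d1)) {
      ranked <- stats::setNames(res$de[[d2]]$logFC, res$de[[d2]]$gene)
      for (dir in c("up", "down")) {
        set <- res$signatures[[d1]][[dir]]
        if (!length(set) || length(set) >= length(ranked)) next
        g <- gsea_compare(ranked, set, n_perm = 500,
                          seed = config$seed + 4L)
        rows[[length(rows) + 1]] <- dplyr::mutate(
          tibble::as_tibble(g), signature = d1, direction = dir,
          ranking = d2, .before = 1)
      }
    }
    res$gsea <- purrr::list_rbind(rows)
    readr::write_tsv(res$gsea, file.path(outdir, "gsea_compare.tsv"))
    note("compare", nrow(res$gsea))
  }
  if (on("ratio")) {
    log_stage("ratio")
    rows <- list()
    for (d in drugs) {
      sg <- res$signatures[[d]]
      if (!length(sg$up) || !length(sg$down)) next
      idx <- res$bulk$cohort$drug == d
      sc_ <- ratio_score(res$bulk$expr[, idx], sg)
      sc_$drug <- d
      sc_$response <- res$bulk$cohort$response[idx]
      rows[[d]] <- sc_
    }
    res$ratio <- purrr::list_rbind(rows)
    if (nrow(res$ratio))
      readr::write_tsv(res$ratio, file.path(outdir, "ratio_scores.tsv"))
    note("ratio", nrow(res$ratio))
  }
  if (on("deconvolve")) {
    log_stage("deconvolve")
    res$fractions <- deconvolve(res$basis$mixtures, res$basis$basis)
    readr::write_tsv(res$fractions, file.path(outdir, "fractions.tsv"))
    note("deconvolve", nrow(res$fractions))
  }
  if (on("stratify")) {
    log_stage("stratify")
    res$strata <- stratify_rich_poor(res$fractions,
                                     patients = res$fractions$sample_id)
    readr::write_tsv(res$strata, file.path(outdir, "rich_poor.tsv"))
    note("stratify", nrow(res$strata))
  }
  if (on("sc")) {
    log_stage("sc")
    sim <- generate_single_cell(config$sc)
    qc <- qc_filter(sim$counts)
    norm <- sc_normalize(qc$counts)
    keep <- sim$cells$barcode %in% qc$kept
    score <- module_score(norm,
                          intersect(sim$truth$program_genes, rownames(norm)),
                          seed = config$seed + 5L)
    res$sc <- list(qc = qc$report, score = score,
                   clusters = sim$cells$cluster[keep])
    readr::write_csv(qc$report, file.path(outdir, "sc_qc_report.csv"))
    readr::write_csv(score, file.path(outdir, "sc_module_scores.csv"))
    note("sc", nrow(score))
  }
  if (on("druggability")) {
    log_stage("druggability")
    lin <- 2^res$bulk$expr
    targets <- unique(unlist(res$circuits[[1]]$nodes$genes))
    # annotate circuit genes onto measured genes: circuits generated with
    # synthetic symbols are mapped onto the first matrix genes
    res$circuits_mapped <- map_circuit_genes(res$circuits, rownames(lin))
    targets <- res$circuits_mapped$targets
    sc_ <- response_score(lin, res$circuits_mapped$circuits, targets,
                          factor = config$inhibition_factor)
    sc_$patient_id <- res$bulk$cohort$patient_id
    sc_$response <- res$bulk$cohort$response
    per_patient <- sc_ |>
      dplyr::group_by(.data$patient_id, .data$response) |>
      dplyr::summarise(score = mean(.data$score), .groups = "drop")
    fav <- favorable_rate(per_patient$score,
                          per_patient$response == "non-responder")
    res$druggability <- list(scores = per_patient, favorable = fav)
    readr::write_tsv(per_patient, file.path(outdir, "response_scores.tsv"))
    note("druggability", nrow(per_patient))
  }
  if (on("cv")) {
    log_stage("cv")
    d <- drugs[1]
    idx <- res$bulk$cohort$drug == d
    top <- res$de[[d]] |>
      dplyr::filter(!is.na(.data$p_bonferroni)) |>
      dplyr::arrange(.data$p_bonferroni) |>
      dplyr::slice_head(n = config$cv_top_n)
    feats <- t(res$bulk$expr[top$gene, idx, drop = FALSE])
    res$cv <- nested_cv(feats, res$bulk$cohort$response[idx],
                        res$bulk$cohort$patient_id[idx],
                        models = model_zoo(config$cv_models),
                        seed = config$seed + 6L)
    readr::write_tsv(res$cv$report[, c("model", "mean_mcc")],
                     file.path(outdir, "cv_report.tsv"))
    note("cv", nrow(res$cv$report))
  }

  res$manifest <- manifest
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

# Deterministic hash of the config: canonical JSON -> md5.
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

# Relabel each circuit's synthetic node genes with genes actually present in
# the expression matrix so inhibition targets exist in the data. Nodes take
# consecutive measured genes; the first circuit's receptor genes become the
# default targets.
map_circuit_genes <- function(circuits, measured_genes) {
  gi <- 0
  mapped <- lapply(circuits, function(cc) {
    cc$nodes$genes <- lapply(cc$nodes$genes, function(g) {
      out <- measured_genes[gi + seq_along(g)]
      gi <<- gi + length(g)
      out
    })
    cc
  })
  rec <- mapped[[1]]$nodes$role == "receptor"
  list(circuits = mapped, targets = unlist(mapped[[1]]$nodes$genes[rec]))
}
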
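#' Configuration for the synthetic single-cell count matrix
#'
#' @param n_cells,n_genes matrix dimensions (genes include the mito/ribo
#'   blocks).
#' @param n_clusters ground-truth cell clusters.
#' @param program_gene_count genes of the planted program, over-expressed in
#'   cluster 1.
#' @param mito_gene_count,ribo_gene_count genes named with the "MT-" / "RPS"
#'   prefixes so QC can identify them.
#' @param fraction_low_quality fraction of cells planted as low quality
#'   (mitochondrial fraction driven far above the 25% QC threshold).
#' @param mean_counts mean library size of a good cell.
#' @param seed integer seed.
#' @return A `sc_sim_config` list.
#' @export
sc_sim_config <- function(n_cells = 500,
                          n_genes = 300,
                          n_clusters = 3,
                          program_gene_count = 30,
                          mito_gene_count = 20,
                          ribo_gene_count = 40,
                          fraction_low_quality = 0.1,
                          mean_counts = 15000,
                          seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_clusters = as.integer(n_clusters),
              program_gene_count = as.integer(program_gene_count),
              mito_gene_count = as.integer(mito_gene_count),
              ribo_gene_count = as.integer(ribo_gene_count),
              fraction_low_quality = fraction_low_quality,
              mean_counts = mean_counts, seed = as.integer(seed))
  if (cfg$fraction_low_quality < 0 || cfg$fraction_low_quality > 1)
    stopf("fraction_low_quality must be in [0, 1]")
  if (cfg$n_clusters < 1) stopf("n_clusters must be >= 1")
  if (cfg$program_gene_count + cfg$mito_gene_count + cfg$ribo_gene_count >
        cfg$n_genes)
    stopf("program/mito/ribo genes exceed n_genes")
  structure(cfg, class = "sc_sim_config")
}

#' Simulate a single-cell count matrix with planted structure
#'
#' Cells belong to ground-truth clusters; a planted gene program is
#' over-expressed (2x) in cluster 1; mitochondrial ("MT-") and ribosomal
#' ("RPS") gene blocks carry realistic count shares (~8% / ~15%); a configured
#' fraction of cells is planted low quality with ~45% mitochondrial counts so
#' they fail the 25% QC rule. Counts are Poisson draws given per-cluster gene
#' proportions and log-normal library sizes.
#'
#' @param config an [sc_sim_config()].
#' @return list with `counts` (genes x cells integer matrix), `cells`
#'   (per-cell tibble: barcode, cluster, low_quality), and `truth` (program
#'   genes, low-quality barcodes, cluster labels).
#' @export
generate_single_cell <- function(config = sc_sim_config()) {
  stopifnot(inherits(config, "sc_sim_config"))
  c_ <- config
  with_seed(c_$seed, {
    n_body <- c_$n_genes - c_$mito_gene_count - c_$ribo_gene_count
    genes <- c(sprintf("GENE%04d", seq_len(n_body)),
               sprintf("MT-%02d", seq_len(c_$mito_gene_count)),
               sprintf("RPS%02d", seq_len(c_$ribo_gene_count)))
    mito <- grepl("^MT-", genes); ribo <- grepl("^RPS", genes)
    program <- genes[seq_len(c_$program_gene_count)]

    barcodes <- sprintf("CELL%05d", seq_len(c_$n_cells))
    cluster <- sort(rep_len(seq_len(c_$n_clusters), c_$n_cells))
    n_low <- round(c_$fraction_low_quality * c_$n_cells)
    low <- rep(FALSE, c_$n_cells)
    if (n_low > 0) low[sample(c_$n_cells, n_low)] <- TRUE

    # near-flat profiles with moderate planted structure keep good cells
    # above the 0.8 diversity cut (strong skew would fail every cell)
    base <- rgamma(c_$n_genes, shape = 100, rate = 1) + 0.05
    profiles <- sapply(seq_len(c_$n_clusters), function(k) {
      p <- base
      # mild cluster identity on a random gene block
      idm <- sample(which(!mito & !ribo), max(10, n_body %/% 10))
      p[idm] <- p[idm] * runif(length(idm), 1.2, 1.4)
      if (k == 1) p[genes %in% program] <- p[genes %in% program] * 2
      p
    })
    counts <- matrix(0L, c_$n_genes, c_$n_cells,
                     dimnames = list(genes, barcodes))
    lib <- round(stats::rlnorm(c_$n_cells, log(c_$mean_counts), 0.15))
    lib[low] <- pmax(500, round(lib[low] * 0.4))
    for (j in seq_len(c_$n_cells)) {
      p <- profiles[, cluster[j]]
      mshare <- if (low[j]) 0.45 else 0.08
      rshare <- 0.15
      p[mito] <- p[mito] / sum(p[mito]) * mshare
      p[ribo] <- p[ribo] / sum(p[ribo]) * rshare
      p[!mito & !ribo] <- p[!mito & !ribo] / sum(p[!mito & !ribo]) *
        (1 - mshare - rshare)
      counts[, j] <- rpois(c_$n_genes, lib[j] * p)
    }
    cells <- tibble::tibble(barcode = barcodes,
                            cluster = paste0("cl", cluster),
                            low_quality = low)
    truth <- list(program_genes = program,
                  low_quality = barcodes[low],
                  cluster = stats::setNames(cells$cluster, barcodes),
                  seed = c_$seed)
    list(counts = counts, cells = cells, truth = truth)
  })
}

#' Simulate a cell-type signature basis and mixtures with known fractions
#'
#' Builds a non-negative gene x cell-type basis with distinct marker blocks
#' (markers at high expression in their own type only) and mixes its columns
#' with Dirichlet-distributed fractions plus optional Gaussian noise, the
#' linear mixture model that reference-based deconvolution assumes.
#'
#' @param n_cell_types number of cell types (>= 2).
#' @param n_marker_genes total genes in the basis (>= n_cell_types).
#' @param n_mixtures number of mixture samples.
#' @param noise_sd Gaussian noise SD added to mixtures, as a fraction of the
#'   mean signal (0 = noiseless).
#' @param seed integer seed.
#' @return list with `basis` (genes x types), `mixtures` (genes x samples),
#'   and `truth$fractions` (samples x types, rows sum to 1).
#' @export
generate_signature_basis <- function(n_cell_types = 5,
                                     n_marker_genes = 100,
                                     n_mixtures = 20,
                                     noise_sd = 0,
                                     seed = 1L) {
  if (n_cell_types < 2) stopf("n_cell_types must be >= 2")
  if (n_marker_genes < n_cell_types)
    stopf("n_marker_genes must be >= n_cell_types")
  with_seed(seed, {
    genes <- sprintf("MK%04d", seq_len(n_marker_genes))
    types <- sprintf("CT%d", seq_len(n_cell_types))
    basis <- matrix(runif(n_marker_genes * n_cell_types, 0, 1),
                    n_marker_genes, n_cell_types,
                    dimnames = list(genes, types))
    block <- split(seq_len(n_marker_genes),
                   rep_len(seq_len(n_cell_types), n_marker_genes))
    for (k in seq_len(n_cell_types))
      basis[block[[k]], k] <- basis[block[[k]], k] + runif(length(block[[k]]), 8, 12)
    g <- matrix(rgamma(n_mixtures * n_cell_types, shape = 1), n_mixtures)
    fractions <- g / rowSums(g)
    dimnames(fractions) <- list(sprintf("MIX%03d", seq_len(n_mixtures)), types)
    mixtures <- basis %*% t(fractions)
    if (noise_sd > 0)
      mixtures <- mixtures + rnorm(length(mixtures), 0, noise_sd * mean(mixtures))
    mixtures[mixtures < 0] <- 0
    list(basis = basis, mixtures = mixtures,
         truth = list(fractions = fractions, seed = seed))
  })
}

#' Simulate signed acyclic receptor-to-effector signalling circuits
#'
#' Each circuit is a signed directed acyclic graph over nodes ordered so all
#' edges point forward: node 1 never receives an edge (so >= 1 receptor
#' exists) and the last node emits none (the unique effector); every other
#' node gets one guaranteed forward edge plus random extras. Edge signs are
#' -1 (inhibition) with probability `inhibitor_fraction`, +1 otherwise. Every
#' node is annotated with 1-2 synthetic gene symbols.
#'
#' @param n_circuits number of circuits.
#' @param nodes_per_circuit nodes per circuit (>= 2).
#' @param inhibitor_fraction probability that an edge is inhibitory.
#' @param seed integer seed.
#' @return list of `lnr_circuit` objects (`nodes` tibble with node/role/genes
#'   list-column; `edges` tibble with from/to/sign).
#' @export
generate_circuits <- function(n_circuits = 3,
                              nodes_per_circuit = 5,
                              inhibitor_fraction = 0.25,
                              seed = 1L) {
  if (nodes_per_circuit < 2) stopf("nodes_per_circuit must be >= 2")
  with_seed(seed, {
    lapply(seq_len(n_circuits), function(ci) {
      n <- nodes_per_circuit
      ids <- sprintf("C%d_N%d", ci, seq_len(n))
      from <- integer(0); to <- integer(0)
      for (i in seq_len(n - 1)) {          # guaranteed path to the effector
        j <- if (i == n - 1) n else sample((i + 1):n, 1)
        from <- c(from, i); to <- c(to, j)
      }
      for (i in seq_len(n - 2)) {          # optional extra forward edges
        for (j in (i + 1):n) {
          if (runif(1) < 0.25 && !any(from == i & to == j)) {
            from <- c(from, i); to <- c(to, j)
          }
        }
      }
      sign <- ifelse(runif(length(from)) < inhibitor_fraction, -1L, 1L)
      # edges into the effector keep at least one activation so the circuit
      # can carry signal
      eff_in <- which(to == n)
      if (all(sign[eff_in] == -1L)) sign[eff_in[1]] <- 1L
      indeg <- tabulate(to, n)
      role <- dplyr::case_when(indeg == 0 ~ "receptor",
                               seq_len(n) == n ~ "effector",
                               TRUE ~ "intermediate")
      genes <- lapply(seq_len(n), function(i)
        sprintf("%s_g%d", ids[i], seq_len(sample(1:2, 1))))
      new_circuit(
        nodes = tibble::tibble(node = ids, role = role, genes = genes),
        edges = tibble::tibble(from = ids[from], to = ids[to], sign = sign),
        id = sprintf("circuit%d", ci)
      )
    })
  })
}

new_circuit <- function(nodes, edges, id = "circuit") {
  x <- structure(list(nodes = nodes, edges = edges, id = id),
                 class = "lnr_circuit")
  validate_circuit(x)
}

validate_circuit <- function(x) {
  stopifnot(all(c("node", "role", "genes") %in% names(x$nodes)),
            all(c("from", "to", "sign") %in% names(x$edges)))
  if (!all(x$edges$sign %in% c(-1L, 1L)))
    stopf("edge signs must be +1 or -1")
  topo_sort_circuit(x)  # errors on cycles
  outdeg <- table(factor(x$edges$from, levels = x$nodes$node))
  indeg <- table(factor(x$edges$to, levels = x$nodes$node))
  if (sum(outdeg == 0) != 1) stopf("circuit must have exactly one effector")
  if (sum(indeg == 0) < 1) stopf("circuit must have at least one receptor")
  x
}

#' @export
print.lnr_circuit <- function(x, ...) {
  cat(sprintf("<lnr_circuit %s: %d nodes, %d edges (%d inhibitory)>\n",
              x$id, nrow(x$nodes), nrow(x$edges), sum(x$edges$sign == -1L)))
  invisible(x)
}

# Kahn topological sort; errors naming a cycle if one exists.
topo_sort_circuit <- function(circuit) {
  nodes <- circuit$nodes$node
  indeg <- stats::setNames(tabulate(match(circuit$edges$to, nodes),
                                    length(nodes)), nodes)
  order <- character(0)
  ready <- nodes[indeg == 0]
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    order <- c(order, v)
    outs <- circuit$edges$to[circuit$edges$from == v]
    for (w in outs) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- c(ready, w)
    }
  }
  if (length(order) < length(nodes))
    stopf("circuit contains a cycle involving: %s",
          paste(setdiff(nodes, order), collapse = ", "))
  order
}
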
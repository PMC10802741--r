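#' Read and write GMT gene-set files
#'
#' GMT: one set per line, tab-separated `name`, `description`, genes.
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a genes x samples expression matrix as TSV
#'
#' Genes as rows, first column `gene`, remaining columns the sample ids.
#'
#' @param expr genes x samples matrix.
#' @param path file path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- tibble::as_tibble(expr, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$gene
  m
}

#' Write / read a circuit as a node + edge CSV pair
#'
#' Nodes: `node_id, gene_list` (semicolon-separated), `role`; edges:
#' `source, target, sign`.
#'
#' @param circuit an `lnr_circuit`.
#' @param node_path,edge_path CSV paths.
#' @export
write_circuit_csv <- function(circuit, node_path, edge_path) {
  nodes <- tibble::tibble(
    node_id = circuit$nodes$node,
    gene_list = vapply(circuit$nodes$genes, paste, "", collapse = ";"),
    role = circuit$nodes$role)
  readr::write_csv(nodes, node_path)
  readr::write_csv(tibble::tibble(source = circuit$edges$from,
                                  target = circuit$edges$to,
                                  sign = circuit$edges$sign), edge_path)
  invisible(node_path)
}

#' @rdname write_circuit_csv
#' @param id circuit id for the rebuilt object.
#' @export
read_circuit_csv <- function(node_path, edge_path, id = "circuit") {
  nodes <- readr::read_csv(node_path, show_col_types = FALSE)
  edges <- readr::read_csv(edge_path, show_col_types = FALSE)
  new_circuit(
    nodes = tibble::tibble(node = nodes$node_id,
                           role = nodes$role,
                           genes = strsplit(nodes$gene_list, ";")),
    edges = tibble::tibble(from = edges$source, to = edges$target,
                           sign = as.integer(edges$sign)),
    id = id)
}

#' Read a single-cell matrix from an MTX triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` (gene per row) and `barcodes.tsv`
#' in `dir`.
#'
#' @param dir directory containing the triplet.
#' @return genes x cells sparse matrix.
#' @export
read_mtx_dir <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- readLines(file.path(dir, "features.tsv"))
  bcs <- readLines(file.path(dir, "barcodes.tsv"))
  feats <- vapply(strsplit(feats, "\t"), `[[`, "", 1)
  dimnames(m) <- list(feats, bcs)
  m
}

#' @rdname read_mtx_dir
#' @param counts genes x cells matrix.
#' @export
write_mtx_dir <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(counts * 1.0, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
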
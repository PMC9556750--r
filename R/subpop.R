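#' Binarize raw counts
#'
#' A gene is "on" in a cell when its raw UMI count is at or above
#' `threshold` (default 2). Binarization always uses raw counts, never
#' normalized values.
#'
#' @param matrix a [count_matrix()]
#' @param genes gene symbols to include (rows of the result)
#' @param threshold on/off count threshold (default 2)
#' @return logical genes x cells matrix
#' @export
binarize <- function(matrix, genes, threshold = 2) {
  stopifnot(inherits(matrix, "count_matrix"))
  missing <- setdiff(genes, matrix$genes$symbol)
  if (length(missing) > 0) {
    abort(paste0("gene(s) not in matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  as.matrix(matrix$counts[genes, , drop = FALSE] >= threshold)
}

# pairwise binary (asymmetric/Jaccard) distance between the rows of a
# logical matrix: discordant / (discordant + both-on); joint absences
# excluded. All-off pairs are defined as distance 0 (with a warning
# upstream).
binary_dist <- function(B) {
  B <- B * 1
  both_on <- tcrossprod(B)
  on <- rowSums(B)
  denom <- outer(on, on, "+") - both_on
  disc <- denom - both_on
  d <- ifelse(denom > 0, disc / denom, 0)
  as.dist(d)
}

#' Bicluster a binarized expression matrix
#'
#' Complete-linkage hierarchical clustering of genes (rows) and cells
#' (columns) under the binary distance `discordant / (discordant +
#' both-on)` (joint absences excluded; two all-off profiles have distance
#' 0). Merge order on ties follows `stats::hclust`, which is
#' deterministic given input order.
#'
#' @param binary logical genes x cells matrix from [binarize()]
#' @return list of class `bicluster_result`: `gene_tree` and `cell_tree`
#'   (`hclust` objects), plus the input matrix
#' @export
bicluster <- function(binary) {
  if (nrow(binary) < 2 || ncol(binary) < 2) {
    abort("need at least 2 rows and 2 columns to bicluster")
  }
  if (any(rowSums(binary) == 0) || any(colSums(binary) == 0)) {
    warn("all-off row(s)/column(s) present; their pairwise distances are 0")
  }
  structure(list(gene_tree = hclust(binary_dist(binary), method = "complete"),
                 cell_tree = hclust(binary_dist(base::t(binary)),
                                    method = "complete"),
                 binary = binary),
            class = "bicluster_result")
}

#' @export
print.bicluster_result <- function(x, ...) {
  cat(sprintf("<bicluster_result> %d genes x %d cells\n",
              nrow(x$binary), ncol(x$binary)))
  invisible(x)
}

#' Define subpopulations by nested dendrogram cuts
#'
#' Cuts the cell dendrogram at each requested `k`; each cell receives the
#' label of the finest cut, and the nesting property holds by
#' construction (every finer cluster is contained in exactly one coarser
#' cluster).
#'
#' @param bic a `bicluster_result` from [bicluster()] (or a bare `hclust`)
#' @param k integer vector of cut sizes (e.g. `c(3, 7)`)
#' @return tibble with one row per cell: `cell`, one column `k<value>`
#'   per cut, and `subpopulation` (the finest cut)
#' @export
cut_subpopulations <- function(bic, k) {
  tree <- if (inherits(bic, "bicluster_result")) bic$cell_tree else bic
  stopifnot(inherits(tree, "hclust"))
  n_leaves <- length(tree$order)
  if (any(k > n_leaves)) {
    abort(sprintf("k = %d exceeds the %d leaves",
                  max(k), n_leaves))
  }
  k <- sort(unique(as.integer(k)))
  cuts <- cutree(tree, k = k)
  cuts <- matrix(cuts, nrow = n_leaves,
                 dimnames = list(tree$labels, paste0("k", k)))
  out <- as_tibble(cuts, rownames = "cell")
  out$subpopulation <- unname(cuts[, ncol(cuts)])
  out
}

#' AC fraction per subpopulation
#'
#' @param subpops tibble from [cut_subpopulations()] (needs `cell`,
#'   `subpopulation`)
#' @param cells cell annotation tibble with `region` (e.g.
#'   `matrix$cells`), matched by cell key or barcode order
#' @return tibble `subpopulation`, `n_cells`, `n_ac`, `ac_fraction`
#' @export
ac_fraction <- function(subpops, cells) {
  key <- if ("barcode" %in% names(cells)) cell_key(cells) else NULL
  region <- if (!is.null(key) && all(subpops$cell %in% key)) {
    cells$region[match(subpops$cell, key)]
  } else if (nrow(cells) == nrow(subpops)) {
    cells$region
  } else {
    abort("cannot match subpopulation cells to region labels")
  }
  tibble(subpopulation = subpops$subpopulation, region = region) |>
    group_by(.data$subpopulation) |>
    summarise(n_cells = n(), n_ac = sum(.data$region == "AC"),
              .groups = "drop") |>
    mutate(ac_fraction = .data$n_ac / .data$n_cells)
}

#' Continuous expression model on subpopulation AC fraction
#'
#' Regresses every gene's normalized expression on the AC fraction of
#' the cell's subpopulation — a continuous axis from all-PA to all-AC
#' states — and returns the per-gene coefficient, which ranks genes for
#' ontology enrichment via [preranked_gsea()].
#'
#' @param matrix a [count_matrix()]
#' @param subpops tibble from [cut_subpopulations()] covering the
#'   matrix's cells
#' @param fractions optional precomputed [ac_fraction()] table; computed
#'   from the matrix's region labels when absent
#' @param min_frac minimum expressing fraction for a gene to be fitted
#'   (default 0.01)
#' @return tibble `symbol`, `coefficient`, `p_value`, ranked by
#'   decreasing coefficient
#' @export
continuous_expression_model <- function(matrix, subpops, fractions = NULL,
                                        min_frac = 0.01) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (is.null(fractions)) fractions <- ac_fraction(subpops, matrix$cells)
  if (nrow(fractions) < 2) {
    abort("need at least 2 subpopulations (no variance in the predictor)")
  }
  idx <- match(subpops$cell, cell_key(matrix$cells))
  if (anyNA(idx)) abort("subpopulations name cells absent from the matrix")
  frac <- fractions$ac_fraction[match(subpops$subpopulation,
                                      fractions$subpopulation)]
  if (stats::var(frac) == 0) {
    abort("all subpopulations have the same AC fraction")
  }
  sub <- matrix[, idx]
  norm <- normalize_expression(sub)
  zv <- attr(norm, "zero_variance")
  expressed <- Matrix::rowSums(sub$counts >= 1) / ncol(sub$counts) >= min_frac
  fitted <- expressed & !zv
  X <- cbind(`(Intercept)` = 1, ac_fraction = frac)
  res <- lm_per_gene(base::t(norm[fitted, , drop = FALSE]), X, "ac_fraction")
  res |>
    dplyr::rename(coefficient = "estimate") |>
    arrange(desc(.data$coefficient))
}
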
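#' Partition cells by community detection on a nearest-neighbor graph
#'
#' Library-size-normalized, log1p-transformed counts are reduced to their
#' top principal components; a k-nearest-neighbor graph is built in PC
#' space and partitioned by Louvain modularity optimization. Graph
#' partitioning is used instead of embedding-space clustering because it
#' is deterministic under a seed and directly testable.
#'
#' @param matrix a [count_matrix()]
#' @param n_pcs number of principal components (default 20; must be
#'   smaller than both dimensions)
#' @param k_neighbors neighbors per cell (default 20)
#' @param seed integer RNG seed for the community detection
#' @return tibble with one row per cell: `cell`, `barcode`, `sample_id`,
#'   `patient_id`, `region`, `partition` (integer id).
#' @export
partition_cells <- function(matrix, n_pcs = 20, k_neighbors = 20, seed = 1L) {
  stopifnot(inherits(matrix, "count_matrix"))
  n <- ncol(matrix$counts)
  if (n < 2) abort("need at least 2 cells to partition")
  n_pcs <- min(n_pcs, nrow(matrix$counts) - 1L, n - 1L)
  if (n_pcs < 1) abort("n_pcs must be at least 1 after clipping to dimensions")

  expr <- log_normalize(matrix)            # cells x genes
  keep <- which(apply(expr, 2, stats::var) > 0)
  pcs <- if (length(keep) == 0) {
    matrix(0, n, 1)                        # all cells identical
  } else {
    stats::prcomp(expr[, keep, drop = FALSE], center = TRUE,
                  scale. = FALSE, rank. = n_pcs)$x
  }
  nn <- knn_pairs(pcs, k = min(k_neighbors, n - 1L))
  g <- igraph::graph_from_edgelist(nn, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  g <- igraph::simplify(g)
  set.seed(as.integer(seed))
  memb <- igraph::membership(igraph::cluster_louvain(g))
  tibble(cell = cell_key(matrix$cells),
         barcode = matrix$cells$barcode,
         sample_id = matrix$cells$sample_id,
         patient_id = matrix$cells$patient_id,
         region = matrix$cells$region,
         partition = as.integer(memb))
}

# cells x genes log1p(depth-normalized) matrix (dense)
log_normalize <- function(matrix) {
  counts <- matrix$counts
  libsize <- Matrix::colSums(counts)
  if (any(libsize == 0)) {
    warn(sprintf("%d cell(s) with zero library size", sum(libsize == 0)))
    libsize[libsize == 0] <- 1
  }
  sf <- median(libsize) / libsize
  log1p(base::t(as.matrix(counts)) * sf)
}

# symmetric kNN edge list (union of directed neighborhoods), blockwise
knn_pairs <- function(x, k, block = 1024L) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  out <- vector("list", ceiling(n / block))
  for (b in seq_along(out)) {
    idx <- (((b - 1L) * block + 1L):min(b * block, n))
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(x[idx, , drop = FALSE], x)
    d2[cbind(seq_along(idx), idx)] <- Inf
    nb <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
    out[[b]] <- cbind(rep(idx, each = k), as.vector(t(nb)))
  }
  do.call(rbind, out)
}

#' Drop partitions too small for downstream analysis
#'
#' @param partitioning tibble from [partition_cells()]
#' @param min_cells minimum partition size (default 50)
#' @return the partitioning tibble restricted to retained partitions
#' @export
drop_small_partitions <- function(partitioning, min_cells = 50) {
  sizes <- partitioning |> dplyr::count(.data$partition)
  small <- sizes$partition[sizes$n < min_cells]
  if (length(small) > 0) {
    inform(sprintf("dropping %d partition(s) with fewer than %d cells",
                   length(small), min_cells))
  }
  partitioning |> filter(!.data$partition %in% small)
}

# fraction of cells expressing (UMI >= 1) and mean raw count, per
# partition -- shared by the marker operations
partition_profiles <- function(matrix, partitioning) {
  idx <- match(partitioning$cell, cell_key(matrix$cells))
  if (anyNA(idx)) abort("partitioning names cells absent from the matrix")
  parts <- sort(unique(partitioning$partition))
  frac <- matrix(0, nrow(matrix$counts), length(parts),
                 dimnames = list(matrix$genes$symbol, parts))
  mn <- frac
  for (j in seq_along(parts)) {
    cols <- idx[partitioning$partition == parts[j]]
    if (length(cols) == 0) { warn(sprintf("partition %s is empty", parts[j])); next }
    sub <- matrix$counts[, cols, drop = FALSE]
    frac[, j] <- Matrix::rowSums(sub >= 1) / length(cols)
    mn[, j] <- Matrix::rowSums(sub) / length(cols)
  }
  list(partitions = parts, fraction = frac, mean = mn)
}

#' Partition marker genes by ubiquity criteria
#'
#' Reports genes expressed in more than `min_fraction` of a partition's
#' cells (UMI >= 1) at a mean raw count above `min_mean` — the criteria
#' used to pick the handful of marker genes that define each cell type.
#' Both thresholds are strict inequalities.
#'
#' @param matrix a [count_matrix()]
#' @param partitioning tibble from [partition_cells()]
#' @param min_fraction minimum expressing fraction (default 0.8)
#' @param min_mean minimum mean raw count (default 2.0)
#' @return tibble `partition`, `symbol`, `fraction_expressing`,
#'   `mean_count`, ranked by fraction then mean within partition.
#' @export
find_partition_markers <- function(matrix, partitioning,
                                   min_fraction = 0.8, min_mean = 2.0) {
  pp <- partition_profiles(matrix, partitioning)
  purrr::map(seq_along(pp$partitions), function(j) {
    hit <- which(pp$fraction[, j] > min_fraction & pp$mean[, j] > min_mean)
    tibble(partition = pp$partitions[j],
           symbol = rownames(pp$fraction)[hit],
           fraction_expressing = pp$fraction[hit, j],
           mean_count = pp$mean[hit, j])
  }) |>
    bind_rows() |>
    arrange(.data$partition, desc(.data$fraction_expressing),
            desc(.data$mean_count))
}

#' Assign cell-type labels to partitions from a reference marker table
#'
#' Each partition is labeled with the cell type whose reference markers
#' dominate its marker list (simple majority of marker hits); partitions
#' with no reference hit, or with a tie, are labeled `"unassigned"`.
#'
#' @param markers tibble from [find_partition_markers()]
#' @param reference data frame with columns `symbol`, `cell_type` mapping
#'   known marker genes to cell types
#' @return tibble `partition`, `label`
#' @export
assign_cell_types <- function(markers, reference) {
  reference <- as_tibble(reference)
  if (nrow(reference) == 0) {
    warn("empty reference: all partitions unassigned")
    return(tibble(partition = unique(markers$partition),
                  label = "unassigned"))
  }
  stopifnot(all(c("symbol", "cell_type") %in% names(reference)))
  hits <- markers |>
    left_join(reference, by = "symbol") |>
    filter(!is.na(.data$cell_type)) |>
    dplyr::count(.data$partition, .data$cell_type)
  labels <- hits |>
    group_by(.data$partition) |>
    summarise(label = if (sum(.data$n == max(.data$n)) > 1) "unassigned"
              else .data$cell_type[which.max(.data$n)],
              .groups = "drop")
  tibble(partition = sort(unique(markers$partition))) |>
    left_join(labels, by = "partition") |>
    mutate(label = dplyr::coalesce(.data$label, "unassigned"))
}

#' Discover partition-exclusive marker genes for doublet detection
#'
#' A gene enters a partition's exclusion set when it is ubiquitously
#' expressed (fraction strictly above `ubiquity`) in that partition and
#' rarely expressed (fraction strictly below `rarity`) in every other
#' partition. Because `rarity < ubiquity`, a gene can belong to at most
#' one partition's set.
#'
#' @param matrix a [count_matrix()]
#' @param partitioning tibble from [partition_cells()]
#' @param ubiquity expressing-fraction floor in the owning partition
#'   (default 0.9)
#' @param rarity expressing-fraction ceiling elsewhere (default 0.1)
#' @return tibble `partition`, `symbol`
#' @export
discover_exclusion_markers <- function(matrix, partitioning,
                                       ubiquity = 0.9, rarity = 0.1) {
  pp <- partition_profiles(matrix, partitioning)
  if (length(pp$partitions) < 2) abort("need at least 2 partitions")
  purrr::map(seq_along(pp$partitions), function(j) {
    others <- pp$fraction[, -j, drop = FALSE]
    hit <- which(pp$fraction[, j] > ubiquity &
                   apply(others, 1, max) < rarity)
    tibble(partition = pp$partitions[j],
           symbol = rownames(pp$fraction)[hit])
  }) |> bind_rows()
}

#' Flag putative doublets by inappropriate marker expression
#'
#' A cell's inappropriate markers are the exclusion-set genes of
#' partitions other than its own that it expresses (UMI >= 1). Cells with
#' at least `min_markers` inappropriate markers are flagged for removal.
#'
#' @param matrix a [count_matrix()]
#' @param partitioning tibble from [partition_cells()]
#' @param exclusion_sets tibble from [discover_exclusion_markers()]
#' @param min_markers flagging threshold (default 2)
#' @return tibble per cell: `cell`, `barcode`, `partition`,
#'   `n_inappropriate`, `inappropriate_markers` (list column),
#'   `total_umi`, `flagged`
#' @export
flag_doublets <- function(matrix, partitioning, exclusion_sets,
                          min_markers = 2) {
  idx <- match(partitioning$cell, cell_key(matrix$cells))
  genes <- unique(exclusion_sets$symbol)
  n <- nrow(partitioning)
  total_umi <- as.integer(Matrix::colSums(matrix$counts))[idx]
  if (length(genes) == 0) {
    return(tibble(cell = partitioning$cell, barcode = partitioning$barcode,
                  partition = partitioning$partition,
                  n_inappropriate = 0L,
                  inappropriate_markers = rep(list(character()), n),
                  total_umi = total_umi, flagged = FALSE))
  }
  expressed <- base::t(as.matrix(matrix$counts[genes, idx, drop = FALSE] >= 1))
  parts <- sort(unique(exclusion_sets$partition))
  member <- sapply(parts, function(p) {
    genes %in% exclusion_sets$symbol[exclusion_sets$partition == p]
  })
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(genes, parts))
  per_part <- expressed %*% member                 # cells x owning partition
  own_col <- match(partitioning$partition, parts)
  own <- ifelse(is.na(own_col), 0,
                per_part[cbind(seq_len(n), own_col)])
  n_inapp <- as.integer(rowSums(per_part) - own)
  foreign_gene <- function(i) {
    g <- genes[expressed[i, ]]
    setdiff(g, exclusion_sets$symbol[exclusion_sets$partition ==
                                       partitioning$partition[i]])
  }
  markers_list <- rep(list(character()), n)
  nz <- which(n_inapp > 0)
  markers_list[nz] <- purrr::map(nz, foreign_gene)
  tibble(cell = partitioning$cell, barcode = partitioning$barcode,
         partition = partitioning$partition,
         n_inappropriate = n_inapp,
         inappropriate_markers = markers_list,
         total_umi = total_umi,
         flagged = n_inapp >= min_markers)
}

#' Validate doublet flags by the read-count shift
#'
#' True doublets carry the summed transcriptome of two cells, so flagged
#' cells should show elevated total UMI relative to the rest of the
#' population. Reports the mean and median shift and a one-sided
#' rank-sum p-value; validation passes when the flagged mean exceeds the
#' unflagged mean.
#'
#' @param flags tibble from [flag_doublets()]
#' @return one-row tibble: counts, means, medians, `p_value`, `passes`
#' @export
validate_doublets_readcount <- function(flags) {
  n_flag <- sum(flags$flagged)
  if (n_flag == 0) {
    inform("no doublets flagged")
    return(tibble(n_flagged = 0L, n_unflagged = nrow(flags),
                  mean_flagged = NA_real_, mean_unflagged = NA_real_,
                  median_flagged = NA_real_, median_unflagged = NA_real_,
                  p_value = NA_real_, passes = NA))
  }
  a <- flags$total_umi[flags$flagged]
  b <- flags$total_umi[!flags$flagged]
  p <- if (length(b) == 0) NA_real_ else {
    suppressWarnings(wilcox.test(a, b, alternative = "greater")$p.value)
  }
  tibble(n_flagged = n_flag, n_unflagged = length(b),
         mean_flagged = mean(a),
         mean_unflagged = if (length(b)) mean(b) else NA_real_,
         median_flagged = median(a),
         median_unflagged = if (length(b)) median(b) else NA_real_,
         p_value = p,
         passes = isTRUE(mean(a) > mean(b)))
}
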
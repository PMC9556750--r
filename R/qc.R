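#' Quality-control filtering of cells
#'
#' Removes cells with a mitochondrial UMI fraction strictly above
#' `mito_max`, strictly fewer than `min_genes` detected genes, or strictly
#' more than `max_genes` detected genes (a gene is detected at UMI >= 1).
#' Boundary cells (exactly 10% mitochondrial, exactly 200 or 4000 genes)
#' are retained: the removal rules are strict inequalities. Fractions are
#' computed on raw UMIs. Each removed cell is counted once, under the
#' first rule it fails in the priority order mito, low-genes, high-genes.
#'
#' @param matrix a [count_matrix()] with mitochondrial flags
#' @param mito_max maximum mitochondrial fraction (default 0.10)
#' @param min_genes minimum detected genes (default 200)
#' @param max_genes maximum detected genes (default 4000)
#' @return list with `matrix` (filtered [count_matrix()]) and `report`, a
#'   tibble with overall and per-sample removal counts (`sample_id = "all"`
#'   for the total row).
#' @export
qc_filter <- function(matrix, mito_max = 0.10, min_genes = 200,
                      max_genes = 4000) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (!any(matrix$genes$is_mito)) {
    warn("no mitochondrial genes flagged; mito filter removes nothing")
  }
  total <- Matrix::colSums(matrix$counts)
  mito <- Matrix::colSums(matrix$counts[matrix$genes$is_mito, , drop = FALSE])
  if (any(total == 0)) {
    warn(sprintf("%d cell(s) with zero total UMI removed under the low-genes rule",
                 sum(total == 0)))
  }
  mito_frac <- ifelse(total > 0, mito / total, 0)
  detected <- Matrix::colSums(matrix$counts >= 1)

  fail_mito <- mito_frac > mito_max
  fail_low <- !fail_mito & detected < min_genes
  fail_high <- !fail_mito & !fail_low & detected > max_genes
  keep <- !(fail_mito | fail_low | fail_high)

  per_sample <- tibble(sample_id = matrix$cells$sample_id,
                       fail_mito = fail_mito, fail_low = fail_low,
                       fail_high = fail_high, keep = keep) |>
    group_by(.data$sample_id) |>
    summarise(cells_in = n(),
              removed_mito = sum(.data$fail_mito),
              removed_low_genes = sum(.data$fail_low),
              removed_high_genes = sum(.data$fail_high),
              cells_out = sum(.data$keep), .groups = "drop")
  report <- bind_rows(
    per_sample |>
      summarise(sample_id = "all",
                across(c("cells_in", "removed_mito", "removed_low_genes",
                         "removed_high_genes", "cells_out"), sum)),
    per_sample)
  list(matrix = matrix[, which(keep)], report = report)
}

#' Equalizing per-sample downsampling
#'
#' Draws `total_cells / n_samples` cells uniformly without replacement
#' from each sample, equalizing the contribution of every sample (and
#' thus region) to downstream unsupervised steps. A sample smaller than
#' its quota keeps all of its cells with a warning; the achieved total is
#' then reported rather than silently re-allocated to other samples.
#'
#' @param matrix a [count_matrix()]
#' @param total_cells target total (must be divisible by the number of
#'   samples, e.g. 17100 over 6 samples = 2850 each)
#' @param seed integer RNG seed; selection is seed-deterministic
#' @return the downsampled [count_matrix()]
#' @export
downsample_equal <- function(matrix, total_cells, seed = 1L) {
  stopifnot(inherits(matrix, "count_matrix"))
  samples <- sort(unique(matrix$cells$sample_id))
  n_samp <- length(samples)
  if (total_cells %% n_samp != 0) {
    abort(sprintf("total_cells (%d) is not divisible by the %d samples",
                  total_cells, n_samp))
  }
  quota <- total_cells %/% n_samp
  set.seed(as.integer(seed))
  keep <- integer(0)
  for (s in samples) {
    idx <- which(matrix$cells$sample_id == s)
    if (length(idx) < quota) {
      warn(sprintf("sample %s has %d cells (< quota %d); keeping all",
                   s, length(idx), quota))
      keep <- c(keep, idx)
    } else {
      keep <- c(keep, sort(sample(idx, quota)))
    }
  }
  achieved <- length(keep)
  if (achieved != total_cells) {
    inform(sprintf("achieved total %d cells (requested %d)",
                   achieved, total_cells))
  }
  matrix[, keep]
}

#' Region-balanced downsampling within cell groups
#'
#' Draws exactly `per_group` cells from every (group, region) combination,
#' the balance used before heatmap biclustering (e.g. 448 cells from each
#' cell type and anatomic location).
#'
#' @param matrix a [count_matrix()]
#' @param groups character/factor of group labels per cell (e.g. cell type)
#' @param per_group cells to draw per (group, region)
#' @param seed integer RNG seed
#' @return the downsampled [count_matrix()]
#' @export
downsample_balanced <- function(matrix, groups, per_group, seed = 1L) {
  stopifnot(inherits(matrix, "count_matrix"),
            length(groups) == ncol(matrix$counts))
  set.seed(as.integer(seed))
  key <- paste(groups, matrix$cells$region)
  keep <- integer(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < per_group) {
      abort(sprintf("group '%s' has only %d cells (< %d requested)",
                    k, length(idx), per_group))
    }
    keep <- c(keep, sort(sample(idx, per_group)))
  }
  matrix[, sort(keep)]
}
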
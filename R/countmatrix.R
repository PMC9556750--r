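#' Construct a single-cell count matrix with cell and gene annotations
#'
#' The central container of the pipeline: a sparse genes x cells matrix of
#' UMI counts together with a tibble of per-cell annotations (barcode,
#' sample, patient, anatomic region) and a tibble of per-gene annotations
#' (symbol, mitochondrial flag). All downstream stages (QC, partitioning,
#' differential expression, networks) consume and return this object or
#' plain tibbles derived from it.
#'
#' @param counts genes x cells matrix of non-negative integer UMI counts
#'   (dense or sparse; stored as `dgCMatrix`). Row names are gene symbols,
#'   column names are cell barcodes.
#' @param cells data frame with one row per cell, columns `barcode`,
#'   `sample_id`, `patient_id`, `region` (values `"AC"` or `"PA"`). Extra
#'   columns are preserved.
#' @param genes data frame with one row per gene, columns `symbol` and
#'   optionally `is_mito`. When `is_mito` is absent it is derived from
#'   `mito_prefix`.
#' @param mito_prefix prefix identifying mitochondrial gene symbols
#'   (default `"MT-"`).
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `cells`, `genes`.
#' @export
count_matrix <- function(counts, cells, genes = NULL, mito_prefix = "MT-") {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) abort("counts must be non-negative")
  if (any(counts@x != floor(counts@x))) abort("counts must be integral")
  cells <- as_tibble(cells)
  required <- c("barcode", "sample_id", "patient_id", "region")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    abort(paste0("cell annotations lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(cells) != ncol(counts)) {
    abort(sprintf("cell table has %d rows but matrix has %d columns",
                  nrow(cells), ncol(counts)))
  }
  if (anyNA(cells$region) || anyNA(cells$patient_id)) {
    abort("every cell needs a patient and region annotation")
  }
  bad <- setdiff(unique(cells$region), c("AC", "PA"))
  if (length(bad) > 0) {
    abort(paste0("region must be 'AC' or 'PA'; found: ",
                 paste(bad, collapse = ", ")))
  }
  dup <- cells |> dplyr::count(.data$sample_id, .data$barcode) |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate barcode(s) within a sample, e.g. %s / %s",
                  dup$sample_id[1], dup$barcode[1]))
  }
  if (is.null(genes)) {
    sym <- rownames(counts)
    if (is.null(sym)) sym <- sprintf("G%05d", seq_len(nrow(counts)))
    genes <- tibble(symbol = sym)
  }
  genes <- as_tibble(genes)
  if (!"symbol" %in% names(genes)) abort("gene annotations need a 'symbol' column")
  if (nrow(genes) != nrow(counts)) {
    abort(sprintf("gene table has %d rows but matrix has %d rows",
                  nrow(genes), nrow(counts)))
  }
  if (!"is_mito" %in% names(genes)) {
    genes$is_mito <- startsWith(genes$symbol, mito_prefix)
  }
  rownames(counts) <- genes$symbol
  colnames(counts) <- cell_key(cells)
  structure(list(counts = counts, cells = cells, genes = genes),
            class = "count_matrix")
}

# Globally unique cell identifier (barcodes are only unique within a sample)
cell_key <- function(cells) paste(cells$sample_id, cells$barcode, sep = "_")

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- x$cells |> dplyr::count(.data$sample_id, .data$patient_id, .data$region)
  cat(sprintf("  %d sample(s), %d patient(s); regions: %s\n",
              dplyr::n_distinct(x$cells$sample_id),
              dplyr::n_distinct(x$cells$patient_id),
              paste(sort(unique(x$cells$region)), collapse = ", ")))
  cat(sprintf("  %d mitochondrial gene(s)\n", sum(x$genes$is_mito)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by gene and/or cell index
#'
#' @param x a [count_matrix()]
#' @param i,j gene and cell indices (integer, logical, or gene symbols /
#'   cell keys)
#' @param ... ignored
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, x$genes$symbol)
  if (is.character(j)) j <- match(j, cell_key(x$cells))
  structure(list(counts = x$counts[i, j, drop = FALSE],
                 cells = x$cells[j, , drop = FALSE],
                 genes = x$genes[i, , drop = FALSE]),
            class = "count_matrix")
}

#' Write a count matrix as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate format), `features.tsv`,
#' `barcodes.tsv` and a `metadata.tsv` carrying the per-cell sample,
#' patient and region annotations, into `path`.
#'
#' @param x a [count_matrix()]
#' @param path output directory (created if needed)
#' @return `path`, invisibly.
#' @export
write_matrix_10x <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
  readr::write_tsv(x$genes, file.path(path, "features.tsv"),
                   col_names = FALSE)
  readr::write_tsv(tibble(barcode = x$cells$barcode),
                   file.path(path, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(x$cells, file.path(path, "metadata.tsv"))
  invisible(path)
}

#' Read a 10x-style MTX triplet with cell metadata
#'
#' Expects `matrix.mtx`, `features.tsv` (symbol, optional mito flag),
#' `barcodes.tsv`, and `metadata.tsv` with columns barcode, sample_id,
#' patient_id, region. Dimensions are cross-checked and mitochondrial
#' genes are flagged by symbol prefix when the features file carries no
#' flag column.
#'
#' @param path directory containing the triplet
#' @inheritParams count_matrix
#' @return a [count_matrix()]
#' @export
read_matrix_10x <- function(path, mito_prefix = "MT-") {
  need <- c("matrix.mtx", "features.tsv", "barcodes.tsv", "metadata.tsv")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      abort(sprintf("missing required file '%s' in %s", f, path))
    }
  }
  m <- Matrix::readMM(file.path(path, "matrix.mtx"))
  feats <- readr::read_tsv(file.path(path, "features.tsv"),
                           col_names = FALSE, show_col_types = FALSE)
  bcs <- readr::read_tsv(file.path(path, "barcodes.tsv"),
                         col_names = FALSE, show_col_types = FALSE)
  meta <- readr::read_tsv(file.path(path, "metadata.tsv"),
                          show_col_types = FALSE)
  if (nrow(feats) != nrow(m)) {
    abort(sprintf("features.tsv has %d rows but matrix.mtx has %d rows",
                  nrow(feats), nrow(m)))
  }
  if (nrow(bcs) != ncol(m)) {
    abort(sprintf("barcodes.tsv has %d rows but matrix.mtx has %d columns",
                  nrow(bcs), ncol(m)))
  }
  if (nrow(meta) != ncol(m)) {
    abort(sprintf("metadata.tsv has %d rows but matrix.mtx has %d columns",
                  nrow(meta), ncol(m)))
  }
  if (!all(meta$barcode == bcs[[1]])) {
    abort("metadata.tsv barcodes do not match barcodes.tsv order")
  }
  genes <- tibble(symbol = feats[[1]])
  if (ncol(feats) >= 2 && is.logical(type.convert(feats[[ncol(feats)]],
                                                  as.is = TRUE))) {
    genes$is_mito <- type.convert(feats[[ncol(feats)]], as.is = TRUE)
  }
  count_matrix(m, meta, genes, mito_prefix = mito_prefix)
}

#' Convert raw counts to a long tibble
#'
#' One row per non-zero (gene, cell) entry, joined with cell annotations.
#' Convenience for downstream dplyr/ggplot work on small matrices.
#'
#' @param x a [count_matrix()]
#' @param ... ignored
#' @return tibble with columns symbol, barcode, sample_id, patient_id,
#'   region, count
#' @export
tidy.count_matrix <- function(x, ...) {
  tm <- methods::as(x$counts, "TsparseMatrix")
  tibble(symbol = x$genes$symbol[tm@i + 1L],
         cell = cell_key(x$cells)[tm@j + 1L],
         count = tm@x) |>
    left_join(x$cells |> mutate(cell = cell_key(x$cells)), by = "cell")
}

#' One-row summary of a count matrix
#'
#' @param x a [count_matrix()]
#' @param ... ignored
#' @export
glance.count_matrix <- function(x, ...) {
  tibble(n_genes = nrow(x$counts), n_cells = ncol(x$counts),
         n_samples = dplyr::n_distinct(x$cells$sample_id),
         n_patients = dplyr::n_distinct(x$cells$patient_id),
         median_umi = median(Matrix::colSums(x$counts)),
         median_genes_detected = median(Matrix::colSums(x$counts > 0)))
}
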
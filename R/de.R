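#' Normalize expression for effect-size modeling
#'
#' Counts are scaled by cell library size to the median depth,
#' log1p-transformed, and then each gene is standardized to zero mean and
#' unit variance across cells. On this scale a model coefficient is
#' directly interpretable as the gene's effect size (normalized effect).
#' Zero-variance genes are left at all zero and flagged in the
#' `"zero_variance"` attribute.
#'
#' @param matrix a [count_matrix()]
#' @return genes x cells numeric matrix with attribute `zero_variance`
#'   (logical per gene)
#' @export
normalize_expression <- function(matrix) {
  stopifnot(inherits(matrix, "count_matrix"))
  expr <- log_normalize(matrix)                      # cells x genes
  mu <- colMeans(expr)
  sdv <- apply(expr, 2, sd)
  zv <- sdv == 0 | !is.finite(sdv)
  sdv[zv] <- 1
  out <- base::t((expr - rep(mu, each = nrow(expr))) /
                   rep(sdv, each = nrow(expr)))
  out[zv, ] <- 0
  attr(out, "zero_variance") <- setNames(zv, rownames(out))
  out
}

# per-gene least squares of Y (cells x genes) on design X, returning the
# coefficient of column `term` with its two-sided t-test
lm_per_gene <- function(Y, X, term) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    abort(paste("design is rank deficient (confounded): the contrast is",
                "collinear with the covariates (e.g. every patient observed",
                "in a single region)"))
  }
  coefs <- qr.coef(qrx, Y)
  res <- Y - X %*% coefs
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrx))
  j <- match(term, colnames(X))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  est <- coefs[j, ]
  tstat <- ifelse(se > 0, est / se, 0)
  p <- 2 * pt(-abs(tstat), df)
  tibble(symbol = colnames(Y), estimate = unname(est),
         p_value = unname(p))
}

#' Normalized-effect differential expression
#'
#' Fits, for every tested gene, a linear model of the standardized
#' log-normalized expression on the region contrast with patient identity
#' (and any further cell-level covariates) as corrective terms. The
#' contrast coefficient is the gene's normalized effect (NE); by
#' convention PA is coded 1, so NE > 0 means higher expression in PA and
#' NE < 0 higher in AC. P-values are two-sided t-tests on the contrast
#' coefficient, corrected across tested genes by Benjamini-Hochberg.
#'
#' Genes expressed in fewer than `min_frac` of the contrasted cells are
#' not tested; zero-variance genes are reported with NE = 0, p = 1,
#' q = 1.
#'
#' @param matrix a [count_matrix()]
#' @param contrast cell annotation column to contrast (default
#'   `"region"`, levels AC/PA)
#' @param covariates cell annotation columns to adjust for (default
#'   `"patient_id"`)
#' @param min_frac minimum expressing fraction for a gene to be tested
#'   (default 0.01)
#' @return an object of class `ne_fit`; use [tidy()] for the per-gene
#'   table (`symbol`, `ne`, `p_value`, `q_value`) and [glance()] for a
#'   one-row summary.
#' @export
fit_de <- function(matrix, contrast = "region", covariates = "patient_id",
                   min_frac = 0.01) {
  stopifnot(inherits(matrix, "count_matrix"))
  cells <- matrix$cells
  if (!contrast %in% names(cells)) {
    abort(sprintf("contrast column '%s' not in cell annotations", contrast))
  }
  lv <- sort(unique(as.character(cells[[contrast]])))
  if (length(lv) != 2) {
    abort(sprintf("contrast '%s' must have exactly 2 levels, found %d",
                  contrast, length(lv)))
  }
  if (any(table(cells[[contrast]]) < 2)) {
    abort("each contrast level needs at least 2 cells")
  }
  # PA (or the alphabetically later level) coded 1
  pos_level <- if ("PA" %in% lv) "PA" else lv[2]
  x <- as.numeric(cells[[contrast]] == pos_level)
  covs <- as.data.frame(lapply(cells[covariates], factor))
  covs <- covs[, vapply(covs, nlevels, 0L) >= 2, drop = FALSE]
  X <- if (ncol(covs) > 0) {
    stats::model.matrix(~ x + ., data = covs)
  } else {
    stats::model.matrix(~ x)
  }
  colnames(X)[colnames(X) == "x"] <- "contrast"

  norm <- normalize_expression(matrix)
  zv <- attr(norm, "zero_variance")
  frac <- Matrix::rowSums(matrix$counts >= 1) / ncol(matrix$counts)
  tested <- frac >= min_frac
  fitted <- tested & !zv

  res <- lm_per_gene(base::t(norm[fitted, , drop = FALSE]), X, "contrast")
  tab <- tibble(symbol = matrix$genes$symbol[tested]) |>
    left_join(res, by = "symbol") |>
    mutate(ne = dplyr::coalesce(.data$estimate, 0),
           p_value = dplyr::coalesce(.data$p_value, 1)) |>
    select("symbol", "ne", "p_value")
  tab$q_value <- bh_adjust(tab$p_value)
  structure(list(table = tab, contrast = contrast,
                 positive_level = pos_level,
                 reference_level = setdiff(lv, pos_level),
                 covariates = covariates,
                 n_cells = ncol(matrix$counts),
                 n_genes_tested = sum(tested)),
            class = "ne_fit")
}

#' @export
print.ne_fit <- function(x, ...) {
  cat(sprintf("<ne_fit> %s: %s (positive) vs %s, %d cells, %d genes tested\n",
              x$contrast, x$positive_level, x$reference_level,
              x$n_cells, x$n_genes_tested))
  cat(sprintf("  %d gene(s) at q < 0.05\n", sum(x$table$q_value < 0.05)))
  invisible(x)
}

#' @rdname fit_de
#' @param x an `ne_fit`
#' @param ... ignored
#' @export
tidy.ne_fit <- function(x, ...) x$table

#' @rdname fit_de
#' @export
glance.ne_fit <- function(x, ...) {
  tibble(n_cells = x$n_cells, n_genes_tested = x$n_genes_tested,
         n_sig_q05 = sum(x$table$q_value < 0.05),
         n_sig_selected = nrow(de_genes(x)))
}

#' Significant DE genes under the selection rule
#'
#' The downstream selection rule: q-value below `q_cut` and normalized
#' effect above `ne_cut` or below `-ne_cut`.
#'
#' @param fit an `ne_fit` (or its [tidy()] table)
#' @param q_cut q-value threshold (default 0.05)
#' @param ne_cut absolute NE threshold (default 0.5)
#' @return the filtered DE tibble
#' @export
de_genes <- function(fit, q_cut = 0.05, ne_cut = 0.5) {
  tab <- if (inherits(fit, "ne_fit")) fit$table else as_tibble(fit)
  tab |> filter(.data$q_value < q_cut,
                .data$ne > ne_cut | .data$ne < -ne_cut)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up BH with monotonicity enforcement. `NaN`/`NA` inputs
#' propagate and are excluded from the ranking.
#'
#' @param p_values numeric vector of p-values in [0, 1] (NA allowed)
#' @return q-values, same length and order
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  m <- length(p)
  q <- rep(NA_real_, length(p_values))
  if (m > 0) {
    o <- order(p)
    qs <- p[o] * m / seq_len(m)
    qs <- rev(cummin(rev(qs)))
    qs <- pmin(qs, 1)
    qo <- numeric(m); qo[o] <- qs
    q[ok] <- qo
  }
  q
}
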
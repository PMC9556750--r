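#' Shrinkage partial-correlation matrix
#'
#' Estimates all pairwise gene-gene partial correlations adjusted for the
#' rest of the genome: the sample correlation matrix is shrunk toward the
#' identity, `R* = (1 - lambda) R + lambda I`, with the analytic
#' variance-minimizing shrinkage intensity (Schafer-Strimmer estimator,
#' clamped to [0, 1]); the precision matrix is obtained by Moore-Penrose
#' pseudo-inversion of `R*` and standardized to partial correlations
#' `pcor_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)` with unit diagonal.
#'
#' @param expr normalized genes x cells matrix (e.g. from
#'   [normalize_expression()])
#' @param lambda optional fixed shrinkage intensity in [0, 1]; by default
#'   the analytic estimator is used. `lambda = 0` gives the plain
#'   pseudo-inverse partial correlations.
#' @return an object of class `pcor_matrix`: list with `values`
#'   (symmetric matrix, unit diagonal), `lambda`, `genes`, `n_cells`
#' @export
shrinkage_pcor <- function(expr, lambda = NULL) {
  expr <- as.matrix(expr)
  p <- nrow(expr); n <- ncol(expr)
  if (n < 3) abort("need at least 3 cells")
  if (p < 2) abort("need at least 2 genes")
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("V%d", seq_len(p))
  sds <- apply(expr, 1, sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warn(sprintf("excluding %d constant gene(s) before partial correlations",
                 sum(const)))
    expr <- expr[!const, , drop = FALSE]
    p <- nrow(expr)
    if (p < 2) abort("fewer than 2 non-constant genes")
  }
  X <- base::t(expr)                                  # cells x genes
  R <- cor(X)
  if (is.null(lambda)) {
    S <- scale(X)                                     # sd denominator n-1
    W2 <- crossprod(S^2)                              # sum_k s_ki^2 s_kj^2
    SW <- crossprod(S)                                # (n-1) r_ij
    var_r <- n / (n - 1)^3 * (W2 - SW^2 / n)
    ut <- upper.tri(R)
    denom <- sum(R[ut]^2)
    lambda <- if (denom == 0) 1 else sum(var_r[ut]) / denom
    lambda <- min(1, max(0, lambda))
  } else {
    stopifnot(lambda >= 0, lambda <= 1)
  }
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  omega <- MASS::ginv(Rs)
  d <- sqrt(abs(diag(omega)))
  pc <- -omega / tcrossprod(d)
  pc <- (pc + base::t(pc)) / 2
  diag(pc) <- 1
  dimnames(pc) <- list(rownames(expr), rownames(expr))
  structure(list(values = pc, lambda = lambda,
                 genes = rownames(expr), n_cells = n),
            class = "pcor_matrix")
}

#' @export
print.pcor_matrix <- function(x, ...) {
  cat(sprintf("<pcor_matrix> %d genes, %d cells, lambda = %.4f\n",
              length(x$genes), x$n_cells, x$lambda))
  invisible(x)
}

#' Edge significance and top-k retention
#'
#' The upper triangle of the partial-correlation matrix is linearized to
#' an edge list; each partial correlation is converted to a z-statistic
#' via the inverse hyperbolic tangent with effective sample size
#' `n - (p - 2) - 3` (floored at 3). Because shrinkage deflates the null
#' spread, the null standard deviation is fitted empirically to the
#' central 90% of the z distribution and a tail-area FDR is computed per
#' edge (`method = "empirical"`); `method = "bh"` applies plain BH to
#' standard-normal p-values instead — the ranking is identical whenever
#' both use the same z ordering. Edges are ranked by FDR, then by
#' absolute partial correlation, ties broken lexicographically by gene
#' pair; the `top_k` highest-ranked edges are retained even where their
#' FDR exceeds 0.05 (the relaxed regime used when clustering weighted
#' edges).
#'
#' @param pcor a `pcor_matrix` from [shrinkage_pcor()]
#' @param top_k edges to retain (default 20000; all edges are kept with a
#'   note when fewer pairs exist)
#' @param method `"empirical"` (empirical-null tail-area FDR, default) or
#'   `"bh"`
#' @return tibble with one row per unordered pair `gene_i < gene_j`:
#'   `pcor`, `z`, `fdr`, `rank`, `retained`
#' @export
edge_fdr <- function(pcor, top_k = 20000, method = c("empirical", "bh")) {
  stopifnot(inherits(pcor, "pcor_matrix"))
  method <- match.arg(method)
  p <- length(pcor$genes)
  if (p < 2) abort("need at least 2 genes")
  n <- pcor$n_cells
  ut <- which(upper.tri(pcor$values), arr.ind = TRUE)
  # order pairs lexicographically by gene symbol for a stable tie-break
  gi <- pcor$genes[ut[, 1]]; gj <- pcor$genes[ut[, 2]]
  swap <- gi > gj
  tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
  val <- pcor$values[ut]

  kappa <- max(n - (p - 2) - 3, 3)
  z <- atanh(pmin(pmax(val, -1 + 1e-12), 1 - 1e-12)) * sqrt(kappa)
  if (method == "empirical") {
    qs <- quantile(z, c(0.05, 0.95), names = FALSE)
    central <- z[z >= qs[1] & z <= qs[2]]
    # sd of a normal truncated to its central 90%
    a <- stats::qnorm(0.95)
    trunc_factor <- sqrt(1 - 2 * a * dnorm(a) / 0.9)
    sd0 <- max(sd(central) / trunc_factor, .Machine$double.eps)
    pv <- 2 * pnorm(-abs(z) / sd0)
  } else {
    pv <- 2 * pnorm(-abs(z))
  }
  fdr <- bh_adjust(pv)

  ord <- order(fdr, -abs(val), gi, gj)
  rank <- integer(length(ord)); rank[ord] <- seq_along(ord)
  if (length(val) < top_k) {
    inform(sprintf("only %d pairs available (top_k = %d); retaining all",
                   length(val), top_k))
  }
  tibble(gene_i = gi, gene_j = gj, pcor = val, z = z, fdr = fdr,
         rank = rank, retained = rank <= top_k) |>
    arrange(.data$rank)
}

#' Louvain co-expression modules from retained edges
#'
#' Builds the graph on retained edges and detects modules by Louvain
#' modularity optimization. By default edge weights are the absolute
#' partial correlations (`"affinity"`: modularity treats weights as
#' connection strength); `"reciprocal"` uses `1 / |pcor|` instead,
#' preserving the distance-flavored weighting described alongside the
#' method (see the methods vignette for why affinity is the default).
#'
#' @param edges tibble from [edge_fdr()] (only `retained` rows are used)
#' @param weight_mode `"affinity"` (default) or `"reciprocal"`
#' @param seed integer RNG seed for the community detection
#' @return an object of class `network_modules`: `membership` tibble
#'   (`symbol`, `module`), `strength` tibble (`symbol`, `strength`),
#'   `edges` (the retained edges), `weight_mode`
#' @export
build_modules <- function(edges, weight_mode = c("affinity", "reciprocal"),
                          seed = 1L) {
  weight_mode <- match.arg(weight_mode)
  ed <- edges |> filter(.data$retained)
  if (nrow(ed) == 0) {
    return(structure(list(membership = tibble(symbol = character(),
                                              module = integer()),
                          strength = tibble(symbol = character(),
                                            strength = double()),
                          edges = ed, weight_mode = weight_mode),
                     class = "network_modules"))
  }
  w <- if (weight_mode == "affinity") abs(ed$pcor) else 1 / abs(ed$pcor)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$gene_i, to = ed$gene_j, weight = w),
    directed = FALSE)
  set.seed(as.integer(seed))
  memb <- igraph::membership(igraph::cluster_louvain(g))
  membership <- tibble(symbol = names(memb), module = as.integer(memb)) |>
    arrange(.data$module, .data$symbol)
  structure(list(membership = membership,
                 strength = node_strength(ed),
                 edges = ed, weight_mode = weight_mode),
            class = "network_modules")
}

#' @export
print.network_modules <- function(x, ...) {
  cat(sprintf("<network_modules> %d module(s) over %d gene(s), %d edge(s) [%s weights]\n",
              dplyr::n_distinct(x$membership$module),
              nrow(x$membership), nrow(x$edges), x$weight_mode))
  invisible(x)
}

#' @rdname build_modules
#' @param x a `network_modules`
#' @param ... ignored
#' @export
tidy.network_modules <- function(x, ...) {
  x$membership |> left_join(x$strength, by = "symbol")
}

#' @rdname build_modules
#' @export
glance.network_modules <- function(x, ...) {
  tibble(n_modules = dplyr::n_distinct(x$membership$module),
         n_genes = nrow(x$membership),
         n_edges = nrow(x$edges),
         median_module_size = median(table(x$membership$module)))
}

#' Node strength
#'
#' Strength of a gene is the sum of absolute partial correlations over
#' its retained incident edges — the connectivity measure used to rank
#' candidate driver genes. Isolated nodes have strength 0.
#'
#' @param edges tibble from [edge_fdr()] (only `retained` rows are used;
#'   a plain edge tibble with `gene_i`, `gene_j`, `pcor` also works)
#' @return tibble `symbol`, `strength`
#' @export
node_strength <- function(edges) {
  ed <- if ("retained" %in% names(edges)) {
    edges |> filter(.data$retained)
  } else edges
  bind_rows(ed |> select(symbol = "gene_i", "pcor"),
            ed |> select(symbol = "gene_j", "pcor")) |>
    group_by(.data$symbol) |>
    summarise(strength = sum(abs(.data$pcor)), .groups = "drop") |>
    arrange(desc(.data$strength))
}

#' Export retained edges as a weighted edge list or GraphML
#'
#' @param modules a `network_modules` from [build_modules()]
#' @param path output file; format chosen by extension (`.graphml` or
#'   anything else for a TSV edge list)
#' @return `path`, invisibly
#' @export
write_network <- function(modules, path) {
  stopifnot(inherits(modules, "network_modules"))
  ed <- modules$edges
  if (grepl("\\.graphml$", path)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = ed$gene_i, to = ed$gene_j,
                 weight = abs(ed$pcor), pcor = ed$pcor, fdr = ed$fdr),
      directed = FALSE,
      vertices = tidy(modules) |> dplyr::rename(name = "symbol"))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    readr::write_tsv(ed, path)
  }
  invisible(path)
}
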
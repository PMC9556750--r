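#' Configuration for the synthetic single-cell generator
#'
#' Describes a patient-matched two-region (AC vs PA) single-cell study:
#' how many patients, how many cells per (patient, region) sample, the gene
#' roster, the cell types with their exclusive marker genes, negative
#' binomial noise, patient batch effects, planted differential-expression
#' effects and planted partial-correlation modules.
#'
#' The default study design mirrors a 3-patient paired AC/PA carotid
#' experiment with more core than adjacent cells, scaled to desk size
#' (see the methods vignette for the scaling rationale).
#'
#' @param n_patients number of patients; each contributes one AC and one
#'   PA sample.
#' @param cells_per_sample cells per (patient, region) sample: a single
#'   integer, or a named vector `c(AC = ..., PA = ...)` to reproduce the
#'   core/adjacent imbalance.
#' @param n_genes total number of genes including mitochondrial genes.
#' @param n_cell_types number of planted cell types.
#' @param n_markers exclusive marker genes per cell type (expressed at
#'   high mean in the owning type, near zero elsewhere).
#' @param n_program additional genes per cell type with a moderately
#'   elevated mean in the owning type (gives partitions structure beyond
#'   the markers).
#' @param mito_gene_fraction fraction of the roster that is mitochondrial
#'   (symbols prefixed `MT-`).
#' @param nb_dispersion negative binomial size parameter `theta` shared by
#'   all genes.
#' @param patient_effect_sd standard deviation of the gene-wise log-normal
#'   multiplicative patient factor (shared by both regions of a patient).
#' @param cell_size_sd standard deviation of the per-cell log-normal
#'   library-size factor.
#' @param de_spec data frame of planted differential effects with columns
#'   `symbol`, `effect` (normalized-effect scale, positive = higher in PA)
#'   and optionally `cell_type` (`NA` = all types) and `mean` (baseline
#'   negative binomial mean for the gene, overriding the random draw;
#'   planted effects on near-zero-count genes are attenuated by count
#'   quantization, so recovery studies plant them at a moderate
#'   expression level). `abs(effect)` must be `< 2`: under per-gene
#'   unit-variance normalization a two-group mean difference cannot
#'   exceed 2.
#' @param ggm_spec list of planted partial-correlation modules, each a list
#'   with `n_genes` (or explicit `genes` symbols), `pcor = c(lo, hi)`
#'   magnitude range, and `topology` `"ring_chords"` (default) or `"hub"`.
#' @param doublet_rate fraction of cross-type doublets to spike in
#'   [`spike_doublets()`]; stored for reference, not applied by
#'   [`generate_cells()`].
#' @param seed integer RNG seed; identical configurations give
#'   bit-identical output.
#'
#' @return a list of class `sim_config`.
#' @seealso [generate_cells()], [spike_doublets()]
#' @export
sim_config <- function(n_patients = 3,
                       cells_per_sample = c(AC = 1300, PA = 500),
                       n_genes = 300,
                       n_cell_types = 6,
                       n_markers = 3,
                       n_program = 10,
                       mito_gene_fraction = 0.03,
                       nb_dispersion = 2,
                       patient_effect_sd = 0.15,
                       cell_size_sd = 0.3,
                       de_spec = NULL,
                       ggm_spec = list(),
                       doublet_rate = 0,
                       seed = 1L) {
  if (length(cells_per_sample) == 1 && is.null(names(cells_per_sample))) {
    cells_per_sample <- c(AC = unname(cells_per_sample),
                          PA = unname(cells_per_sample))
  }
  stopifnot(all(c("AC", "PA") %in% names(cells_per_sample)),
            all(cells_per_sample >= 1), n_patients >= 1,
            n_cell_types >= 1, nb_dispersion > 0, patient_effect_sd >= 0)
  if (doublet_rate < 0 || doublet_rate >= 0.5) {
    abort("doublet_rate must lie in [0, 0.5)")
  }

  n_mito <- round(mito_gene_fraction * n_genes)
  symbols <- c(sprintf("MT-G%04d", seq_len(n_mito)),
               sprintf("G%04d", seq_len(n_genes - n_mito)))
  genes <- tibble(symbol = symbols,
                  is_mito = startsWith(symbols, "MT-"),
                  role = "background", owner_type = NA_integer_)
  genes$role[genes$is_mito] <- "mito"

  free <- which(!genes$is_mito)
  take <- function(k) {
    if (k == 0) return(integer(0))
    if (k > length(free)) abort("gene roster too small for requested layout")
    out <- free[seq_len(k)]
    free <<- free[-seq_len(k)]
    out
  }
  for (t in seq_len(n_cell_types)) {
    idx <- take(n_markers)
    genes$role[idx] <- "marker"; genes$owner_type[idx] <- t
  }
  for (t in seq_len(n_cell_types)) {
    idx <- take(n_program)
    genes$role[idx] <- "program"; genes$owner_type[idx] <- t
  }

  # resolve module gene assignments
  modules <- list()
  if (length(ggm_spec) > 0) {
    for (m in seq_along(ggm_spec)) {
      sp <- ggm_spec[[m]]
      topo <- sp$topology %||% "ring_chords"
      if (!is.null(sp$genes)) {
        idx <- match(sp$genes, genes$symbol)
        if (anyNA(idx)) abort("ggm_spec names genes outside the roster")
      } else {
        nm <- sp$n_genes %||% abort("ggm_spec module needs n_genes or genes")
        idx <- take(nm)
      }
      if (any(genes$role[idx] == "module")) {
        abort("ggm_spec module gene lists must be disjoint")
      }
      genes$role[idx] <- "module"
      pr <- sp$pcor %||% c(0.25, 0.4)
      if (length(pr) == 1) pr <- c(pr, pr)
      modules[[m]] <- list(genes = genes$symbol[idx], pcor = pr,
                           topology = topo)
    }
  }
  de_spec <- if (is.null(de_spec)) {
    tibble(symbol = character(), cell_type = integer(), effect = double())
  } else {
    de_spec <- as_tibble(de_spec)
    if (!"cell_type" %in% names(de_spec)) de_spec$cell_type <- NA_integer_
    if (!"mean" %in% names(de_spec)) de_spec$mean <- NA_real_
    if (anyNA(match(de_spec$symbol, genes$symbol))) {
      abort("de_spec names genes outside the roster")
    }
    if (any(!is.finite(de_spec$effect))) abort("de_spec effects must be finite")
    if (any(abs(de_spec$effect) >= 2)) {
      abort("planted |effect| must be < 2 on the normalized scale")
    }
    de_spec
  }
  structure(list(n_patients = n_patients,
                 cells_per_sample = cells_per_sample,
                 n_genes = n_genes, n_cell_types = n_cell_types,
                 n_markers = n_markers, n_program = n_program,
                 nb_dispersion = nb_dispersion,
                 patient_effect_sd = patient_effect_sd,
                 cell_size_sd = cell_size_sd,
                 genes = genes, modules = modules, de_spec = de_spec,
                 doublet_rate = doublet_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# Assemble the planted precision matrix (unit diagonal) for the full
# roster, with module blocks wired per spec. Returns the matrix plus the
# realized planted edges (magnitudes can shrink slightly if a ridge was
# needed for positive definiteness).
build_precision <- function(config) {
  p <- config$n_genes
  omega <- diag(p)
  edges <- NULL
  for (mod in config$modules) {
    gi <- match(mod$genes, config$genes$symbol)
    m <- length(gi)
    if (mod$topology == "hub") {
      if (m < 2) abort("hub module needs at least 2 genes")
      ee <- cbind(gi[1], gi[-1])
    } else {
      ee <- cbind(gi, c(gi[-1], gi[1]))            # ring
      n_chord <- max(0L, floor(m / 4))
      if (n_chord > 0 && m >= 4) {
        ch <- t(replicate(n_chord, sample(gi, 2)))
        ee <- rbind(ee, ch)
      }
    }
    # drop duplicate pairs (chords may coincide with ring edges)
    key <- paste(pmin(ee[, 1], ee[, 2]), pmax(ee[, 1], ee[, 2]))
    ee <- ee[!duplicated(key), , drop = FALSE]
    vals <- runif(nrow(ee), mod$pcor[1], mod$pcor[2]) *
      sample(c(-1, 1), nrow(ee), replace = TRUE)
    if (mod$topology == "hub") {
      # positive definiteness of a star requires sum of squared spoke
      # pcors < 1; rescale if the draw violates it
      ss <- sum(vals^2)
      if (ss >= 0.95) vals <- vals * sqrt(0.95 / ss)
    }
    for (k in seq_len(nrow(ee))) {
      omega[ee[k, 1], ee[k, 2]] <- -vals[k]
      omega[ee[k, 2], ee[k, 1]] <- -vals[k]
    }
    edges <- rbind(edges, ee)
  }
  if (!is.null(edges)) {
    ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0.05) {
      omega <- omega + (0.05 - ev) * diag(p)
      omega <- stats::cov2cor(omega)
    }
  }
  planted <- if (is.null(edges)) {
    tibble(gene_i = character(), gene_j = character(), pcor = double())
  } else {
    i <- pmin(edges[, 1], edges[, 2]); j <- pmax(edges[, 1], edges[, 2])
    tibble(gene_i = config$genes$symbol[i],
           gene_j = config$genes$symbol[j],
           pcor = -omega[cbind(i, j)] / sqrt(omega[cbind(i, i)] *
                                               omega[cbind(j, j)]))
  }
  list(omega = omega, planted_edges = planted)
}

#' Generate a synthetic count matrix with planted ground truth
#'
#' Draws UMI counts for a patient-matched AC/PA study via a Gaussian
#' copula: within each cell, a multivariate normal latent vector with the
#' planted precision matrix is transformed through its normal CDF to
#' uniforms and then to negative binomial quantiles, preserving the
#' partial-correlation structure the network stage must recover while
#' producing integer counts. Planted differential effects shift the latent
#' mean of the specified genes between regions (with the variance
#' compensation that makes the normalized-effect coefficient recover the
#' planted value; see the methods vignette), patient batch factors
#' multiply the negative binomial means gene-wise, and mitochondrial genes
#' are flagged.
#'
#' @param config a [sim_config()]
#' @return a list with elements `matrix` (a [count_matrix()]) and `truth`,
#'   a list holding per-cell true types, the planted DE table, the planted
#'   precision matrix and realized planted edges, module membership,
#'   patient factors, and an (initially empty) doublet table.
#' @export
generate_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$n_genes
  prec <- build_precision(config)
  sigma <- stats::cov2cor(solve(prec$omega))
  ch <- tryCatch(chol(sigma), error = function(e) {
    abort("planted precision matrix is not positive definite")
  })

  # cell roster: patients x regions, uniform type mixture
  cells <- tidyr::expand_grid(patient_id = sprintf("P%d", seq_len(config$n_patients)),
                              region = c("AC", "PA")) |>
    mutate(sample_id = paste0(.data$patient_id, "_", .data$region),
           n = unname(config$cells_per_sample[.data$region])) |>
    tidyr::uncount(.data$n)
  n_cells <- nrow(cells)
  cells$barcode <- sprintf("BC%06d", seq_len(n_cells))
  cells <- cells |> select("barcode", "sample_id", "patient_id", "region")
  cell_type <- sample.int(config$n_cell_types, n_cells, replace = TRUE)

  # per-(gene, type) negative binomial means
  base_mean <- exp(rnorm(p, log(1.5), 0.8))
  base_mean[config$genes$role == "mito"] <- 3
  if (nrow(config$de_spec) > 0 && any(!is.na(config$de_spec$mean))) {
    pinned <- config$de_spec[!is.na(config$de_spec$mean), ]
    base_mean[match(pinned$symbol, config$genes$symbol)] <- pinned$mean
  }
  mu_type <- matrix(rep(base_mean, config$n_cell_types), nrow = p)
  for (t in seq_len(config$n_cell_types)) {
    mk <- which(config$genes$role == "marker")
    own <- mk[config$genes$owner_type[mk] == t]
    mu_type[own, ] <- 0.02
    mu_type[own, t] <- 8
    pg <- which(config$genes$role == "program" &
                  config$genes$owner_type == t)
    mu_type[pg, t] <- mu_type[pg, t] * 3
  }

  # gene-wise log-normal patient factors, shared by both regions
  pf <- matrix(exp(rnorm(p * config$n_patients, 0,
                         config$patient_effect_sd)),
               nrow = p,
               dimnames = list(config$genes$symbol,
                               sprintf("P%d", seq_len(config$n_patients))))
  size_factor <- exp(rnorm(n_cells, 0, config$cell_size_sd))

  # latent MVN with planted correlation; DE as a centered latent shift
  z <- matrix(rnorm(n_cells * p), n_cells, p) %*% ch
  if (nrow(config$de_spec) > 0) {
    for (k in seq_len(nrow(config$de_spec))) {
      g <- match(config$de_spec$symbol[k], config$genes$symbol)
      delta <- config$de_spec$effect[k]
      s <- delta / sqrt(1 - delta^2 / 4)
      tt <- config$de_spec$cell_type[k]
      affected <- if (is.na(tt)) rep(TRUE, n_cells) else cell_type == tt
      shift <- ifelse(cells$region == "PA", s / 2, -s / 2)
      z[affected, g] <- z[affected, g] + shift[affected]
    }
  }

  pat_idx <- match(cells$patient_id, colnames(pf))
  mu <- t(mu_type[, cell_type, drop = FALSE]) * t(pf[, pat_idx, drop = FALSE]) *
    size_factor
  counts <- matrix(qnbinom(pnorm(z), size = config$nb_dispersion, mu = mu),
                   n_cells, p)
  dimnames(counts) <- list(NULL, config$genes$symbol)

  mat <- count_matrix(Matrix::t(Matrix::Matrix(counts, sparse = TRUE)),
                      cells, config$genes[, c("symbol", "is_mito")])
  truth <- list(
    cell_types = tibble(barcode = cells$barcode,
                        sample_id = cells$sample_id,
                        cell_type = cell_type),
    de = config$de_spec,
    omega = prec$omega,
    planted_edges = prec$planted_edges,
    modules = purrr::imap(config$modules,
                          \(m, i) tibble(symbol = m$genes, module = i)) |>
      bind_rows(),
    patient_factors = pf,
    doublets = tibble(barcode = character(), parent1 = character(),
                      parent2 = character())
  )
  list(matrix = mat, truth = truth)
}

#' Spike cross-type doublets into a count matrix
#'
#' Appends `round(rate * n_cells)` synthetic barcodes, each the
#' element-wise sum of two cells of differing true cell type drawn from
#' the same sample (doublets arise within a droplet run, never across
#' samples). Parent identities are recorded in the truth object so doublet
#' recall and singlet false-positive rate can be computed downstream.
#'
#' @param matrix a [count_matrix()]
#' @param truth truth list from [generate_cells()]
#' @param rate doublet fraction in [0, 0.5)
#' @param seed integer RNG seed
#' @return list with updated `matrix` and `truth`
#' @export
spike_doublets <- function(matrix, truth, rate, seed = 1L) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (rate < 0 || rate >= 0.5) abort("doublet rate must lie in [0, 0.5)")
  n <- ncol(matrix$counts)
  n_dbl <- round(rate * n)
  if (n_dbl == 0) return(list(matrix = matrix, truth = truth))
  types <- truth$cell_types$cell_type[match(matrix$cells$barcode,
                                            truth$cell_types$barcode)]
  if (dplyr::n_distinct(types, na.rm = TRUE) < 2) {
    abort("need at least 2 cell types to form cross-type doublets")
  }
  set.seed(as.integer(seed))
  eligible <- which(!is.na(types))
  pairs <- matrix(NA_integer_, n_dbl, 2)
  samp <- matrix$cells$sample_id
  for (k in seq_len(n_dbl)) {
    repeat {
      a <- sample(eligible, 1)
      cand <- eligible[samp[eligible] == samp[a] &
                         types[eligible] != types[a]]
      if (length(cand) > 0) { pairs[k, ] <- c(a, sample(cand, 1)); break }
    }
  }
  dbl_counts <- matrix$counts[, pairs[, 1], drop = FALSE] +
    matrix$counts[, pairs[, 2], drop = FALSE]
  dbl_cells <- matrix$cells[pairs[, 1], ]
  dbl_cells$barcode <- sprintf("DBL%05d", seq_len(n_dbl))
  new_cells <- bind_rows(matrix$cells, dbl_cells)
  out <- count_matrix(cbind(matrix$counts, dbl_counts), new_cells,
                      matrix$genes)
  truth$doublets <- bind_rows(
    truth$doublets,
    tibble(barcode = dbl_cells$barcode,
           parent1 = matrix$cells$barcode[pairs[, 1]],
           parent2 = matrix$cells$barcode[pairs[, 2]]))
  truth$cell_types <- bind_rows(
    truth$cell_types,
    tibble(barcode = dbl_cells$barcode, sample_id = dbl_cells$sample_id,
           cell_type = NA_integer_))
  list(matrix = out, truth = truth)
}

#' Write the synthetic truth tables beside a 10x triplet
#'
#' @param truth truth list from [generate_cells()]
#' @param path output directory
#' @return `path`, invisibly
#' @export
write_truth <- function(truth, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(truth$cell_types, file.path(path, "truth_cell_types.tsv"))
  readr::write_tsv(truth$de, file.path(path, "truth_de.tsv"))
  readr::write_tsv(truth$planted_edges, file.path(path, "truth_edges.tsv"))
  readr::write_tsv(truth$doublets, file.path(path, "truth_doublets.tsv"))
  if (nrow(truth$modules) > 0) {
    readr::write_tsv(truth$modules, file.path(path, "truth_modules.tsv"))
  }
  invisible(path)
}
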
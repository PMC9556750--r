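#' Read a GMT gene-set collection
#'
#' Tab-separated: set name, description, then member genes. Empty lines
#' are skipped.
#'
#' @param path path to a `.gmt` file
#' @return named list of character vectors (set name -> genes)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields (name, description, genes...)",
                  bad[1]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(names(sets))) warn("duplicate set names in GMT; keeping all")
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# weighted Kolmogorov-Smirnov running-sum enrichment score for one set.
# scores must be sorted decreasing. Returns ES and the index of the
# extremum (for the leading edge).
ks_es <- function(in_set, scores, weight = 1) {
  w <- abs(scores)^weight
  hit <- ifelse(in_set, w, 0)
  sum_hit <- sum(hit)
  n_miss <- sum(!in_set)
  if (sum_hit == 0 || n_miss == 0) return(list(es = NA_real_, at = NA_integer_))
  running <- cumsum(hit / sum_hit - (!in_set) / n_miss)
  i_max <- which.max(running); i_min <- which.min(running)
  if (running[i_max] >= -running[i_min]) {
    list(es = running[i_max], at = i_max)
  } else {
    list(es = running[i_min], at = i_min)
  }
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov enrichment on a ranked gene list
#' (genes ranked by normalized effect): hits increment the running sum
#' proportionally to `|score|^weight`, misses decrement uniformly; the
#' enrichment score (ES) is the running-sum extremum. The null is built
#' from `n_perm` random gene-label permutations; NES divides ES by the
#' mean absolute null ES of matching sign, the nominal p is the
#' sign-matched null tail frequency, and FDR q follows the sign-matched
#' pooled-null rule. The leading edge contains the set members at or
#' before the extremum (at or after it for negative ES).
#'
#' @param ranked named numeric vector, gene -> score (e.g. normalized
#'   effect); names must be unique
#' @param sets named list of gene sets (see [read_gmt()])
#' @param n_perm number of gene-label permutations (default 1000; below
#'   100 a warning is issued)
#' @param weight running-sum weight exponent (default 1)
#' @param min_size minimum set overlap with the ranked list (default 5)
#' @param seed integer RNG seed for the permutations
#' @return an object of class `gsea_result`; [tidy()] gives one row per
#'   set (`set`, `size`, `es`, `nes`, `p_value`, `q_value`,
#'   `leading_edge` list column)
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000, weight = 1,
                           min_size = 5, seed = 1L) {
  if (anyDuplicated(names(ranked))) abort("ranked list has duplicate genes")
  if (n_perm < 100) warn("n_perm < 100: null and FDR estimates will be coarse")
  ord <- order(ranked, decreasing = TRUE)
  genes <- names(ranked)[ord]
  scores <- unname(ranked[ord])
  n <- length(genes)

  keep <- vapply(sets, function(s) sum(s %in% genes) >= min_size, TRUE)
  skipped <- names(sets)[!keep]
  if (length(skipped) > 0) {
    inform(sprintf("skipping %d set(s) with overlap below %d",
                   length(skipped), min_size))
  }
  sets <- sets[keep]
  if (length(sets) == 0) abort("no gene set overlaps the ranked list")

  obs <- purrr::map(sets, function(s) {
    in_set <- genes %in% s
    r <- ks_es(in_set, scores, weight)
    le <- if (is.na(r$es)) character() else if (r$es >= 0) {
      genes[seq_len(r$at)][in_set[seq_len(r$at)]]
    } else {
      genes[r$at:n][in_set[r$at:n]]
    }
    list(es = r$es, size = sum(in_set), leading_edge = le)
  })

  set.seed(as.integer(seed))
  sizes <- sort(unique(vapply(obs, `[[`, 0L, "size")))
  # permutation null per set size: permute gene labels, i.e. random
  # positions of the set in the ranked list
  null_by_size <- lapply(sizes, function(k) {
    vapply(seq_len(n_perm), function(i) {
      in_set <- logical(n)
      in_set[sample.int(n, k)] <- TRUE
      ks_es(in_set, scores, weight)$es
    }, 0)
  })
  names(null_by_size) <- as.character(sizes)

  rows <- purrr::imap(obs, function(o, nm) {
    nulls <- null_by_size[[as.character(o$size)]]
    same <- nulls[sign(nulls) == sign(o$es)]
    p <- if (length(same) == 0) 1 / (n_perm + 1) else {
      (sum(abs(same) >= abs(o$es)) + 1) / (length(same) + 1)
    }
    denom <- if (length(same) > 0) mean(abs(same)) else mean(abs(nulls))
    tibble(set = nm, size = o$size, es = o$es,
           nes = o$es / denom, p_value = p,
           leading_edge = list(o$leading_edge))
  })
  tab <- bind_rows(rows)

  # sign-matched pooled-null FDR: for each set, compare the fraction of
  # pooled null NES at least as extreme (same sign) with the fraction of
  # observed NES at least as extreme
  null_nes <- unlist(purrr::imap(obs, function(o, nm) {
    nulls <- null_by_size[[as.character(o$size)]]
    pos <- nulls[nulls >= 0]; neg <- nulls[nulls < 0]
    c(if (length(pos)) pos / mean(pos),
      if (length(neg)) -neg / mean(-neg) * -1)
  }), use.names = FALSE)
  tab$q_value <- vapply(seq_len(nrow(tab)), function(i) {
    s <- sign(tab$nes[i])
    pool <- null_nes[sign(null_nes) == s]
    obs_same <- tab$nes[sign(tab$nes) == s]
    num <- if (length(pool) == 0) 1 else mean(abs(pool) >= abs(tab$nes[i]))
    den <- mean(abs(obs_same) >= abs(tab$nes[i]))
    min(1, num / max(den, .Machine$double.eps))
  }, 0)
  tab <- tab |> arrange(desc(.data$nes)) |>
    select("set", "size", "es", "nes", "p_value", "q_value", "leading_edge")
  structure(list(table = tab, n_perm = n_perm, weight = weight,
                 n_genes = n, skipped = skipped),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> %d set(s) on %d ranked genes, %d permutations\n",
              nrow(x$table), x$n_genes, x$n_perm))
  print(x$table |> select(-"leading_edge"), n = 10)
  invisible(x)
}

#' @rdname preranked_gsea
#' @param x a `gsea_result`
#' @param ... ignored
#' @export
tidy.gsea_result <- function(x, ...) x$table

#' @rdname preranked_gsea
#' @export
glance.gsea_result <- function(x, ...) {
  tibble(n_sets = nrow(x$table), n_genes = x$n_genes,
         n_perm = x$n_perm, n_sig_q05 = sum(x$table$q_value < 0.05),
         n_skipped = length(x$skipped))
}

#' One-tailed Fisher exact test for overlap enrichment
#'
#' Upper-tail hypergeometric probability `P(X >= observed overlap)` for a
#' 2x2 contingency table of set membership against a selection (e.g. DE
#' genes against module genes over the network universe).
#'
#' @param overlap_table 2x2 matrix of non-negative integer counts with
#'   the observed overlap in `[1, 1]`: rows = in selection yes/no,
#'   columns = in set yes/no
#' @return the one-tailed p-value
#' @export
fisher_one_tailed <- function(overlap_table) {
  m <- as.matrix(overlap_table)
  if (!all(dim(m) == c(2, 2))) abort("overlap_table must be 2x2")
  if (any(m < 0)) abort("overlap_table cells must be non-negative")
  if (any(m != floor(m))) abort("overlap_table cells must be integers")
  k <- m[1, 1]                     # overlap
  K <- m[1, 1] + m[1, 2]           # selection size
  s <- m[1, 1] + m[2, 1]           # set size
  N <- sum(m)
  # P(X >= k) for X ~ Hypergeometric(N, K, s)
  phyper(k - 1, K, N - K, s, lower.tail = FALSE)
}

# 2x2 table for a gene subset against a selection over a universe:
# rows = in selection yes/no, columns = in subset yes/no
overlap_table <- function(universe, selection, subset) {
  selection <- intersect(selection, universe)
  subset <- intersect(subset, universe)
  a <- length(intersect(subset, selection))
  matrix(c(a, length(subset) - a,
           length(selection) - a,
           length(universe) - length(selection) - length(subset) + a),
         2, 2, byrow = TRUE)
}
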
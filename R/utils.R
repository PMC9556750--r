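#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for random
#' agreement. Used to score recovery of planted cell types and network
#' modules.
#'
#' @param a,b label vectors of equal length
#' @return the adjusted Rand index
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  sum_ab <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n_pairs <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n_pairs
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ab - expected) / (max_idx - expected)
}
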
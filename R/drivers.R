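#' Select modules enriched with differentially expressed genes
#'
#' For every module, a 2x2 contingency table of significant DE genes
#' against module membership over the network universe (genes present in
#' the network) is tested by the one-tailed Fisher exact test; modules
#' with `p < alpha` are selected. Modules never overlap (Louvain yields a
#' partition), so the tests tile the universe.
#'
#' @param modules a `network_modules` from [build_modules()]
#' @param de an `ne_fit` (or its [tidy()] table)
#' @param alpha selection threshold (default 0.05)
#' @param q_cut,ne_cut DE significance rule passed to [de_genes()]
#' @return tibble per module: `module`, `n_genes`, `n_de`, `p_value`,
#'   `selected`
#' @export
select_enriched_modules <- function(modules, de, alpha = 0.05,
                                    q_cut = 0.05, ne_cut = 0.5) {
  stopifnot(inherits(modules, "network_modules"))
  universe <- modules$membership$symbol
  sig <- intersect(de_genes(de, q_cut, ne_cut)$symbol, universe)
  modules$membership |>
    group_by(.data$module) |>
    summarise(n_genes = n(),
              n_de = sum(.data$symbol %in% sig),
              p_value = fisher_one_tailed(
                overlap_table(universe, sig, .data$symbol)),
              .groups = "drop") |>
    mutate(selected = .data$p_value < alpha) |>
    arrange(.data$p_value)
}

#' Overlap of hallmark leading edges with network modules
#'
#' Tests every (hallmark leading edge, module) pair by the one-tailed
#' Fisher exact test over the network universe, restricted to
#' differentially expressed leading-edge genes. A hallmark is flagged
#' `specific` when exactly one module passes `p < alpha` — the pattern of
#' a process concentrating in a single module.
#'
#' @param modules a `network_modules`
#' @param leading_edges named list: hallmark -> leading-edge genes (e.g.
#'   from [tidy()] of a `gsea_result`)
#' @param de optional `ne_fit` or DE table; when supplied, leading edges
#'   are restricted to significant DE genes ([de_genes()] rule)
#' @param alpha significance threshold (default 0.05)
#' @param q_cut,ne_cut DE significance rule
#' @return tibble per (hallmark, module): `hallmark`, `module`,
#'   `n_overlap`, `p_value`, `passes`, `specific`
#' @export
hallmark_module_overlap <- function(modules, leading_edges, de = NULL,
                                    alpha = 0.05, q_cut = 0.05,
                                    ne_cut = 0.5) {
  stopifnot(inherits(modules, "network_modules"))
  universe <- modules$membership$symbol
  if (!is.null(de)) {
    sig <- de_genes(de, q_cut, ne_cut)$symbol
    leading_edges <- purrr::map(leading_edges, intersect, sig)
  }
  keep <- lengths(leading_edges) > 0
  if (any(!keep)) {
    inform(sprintf("skipping %d hallmark(s) with empty leading edge",
                   sum(!keep)))
  }
  leading_edges <- leading_edges[keep]
  if (length(leading_edges) == 0) {
    return(tibble(hallmark = character(), module = integer(),
                  n_overlap = integer(), p_value = double(),
                  passes = logical(), specific = logical()))
  }
  mods <- split(modules$membership$symbol, modules$membership$module)
  rows <- purrr::imap(leading_edges, function(le, hm) {
    purrr::imap(mods, function(mg, mid) {
      tibble(hallmark = hm, module = as.integer(mid),
             n_overlap = length(intersect(le, mg)),
             p_value = fisher_one_tailed(overlap_table(universe, le, mg)))
    }) |> bind_rows()
  }) |> bind_rows()
  rows |>
    mutate(passes = .data$p_value < alpha) |>
    group_by(.data$hallmark) |>
    mutate(specific = .data$passes & sum(.data$passes) == 1) |>
    ungroup() |>
    arrange(.data$hallmark, .data$p_value)
}

#' Extract a key-driver subnetwork from a module
#'
#' The subnetwork keeps the module genes in the top `top_frac` by node
#' strength (strength computed on the module's induced subgraph by
#' default) together with all of the module's significant DE genes. A
#' node is a key driver when it passes all three cutoffs: `q < q_cut`,
#' `strength > strength_cut` (strict), and `NE > ne_cut` or
#' `NE < -ne_cut` (strict). Nodes are annotated with the DE direction
#' (`"AC"` for negative NE, `"PA"` for positive) for export or plotting.
#'
#' @param module integer module id
#' @param modules a `network_modules` from [build_modules()]
#' @param de an `ne_fit` or DE table
#' @param top_frac strength quantile kept (default 0.15; `ceiling` of
#'   `top_frac * module size` genes)
#' @param strength_cut node-strength cutoff (default 0.3)
#' @param ne_cut absolute NE cutoff (default 0.5)
#' @param q_cut q-value cutoff (default 0.05)
#' @param strength_scope `"module"` (default: strength on the induced
#'   subgraph) or `"global"` (strength over all retained edges)
#' @return an object of class `driver_subnetwork`: `nodes` tibble
#'   (`symbol`, `strength`, `ne`, `q_value`, `direction`, `is_driver`),
#'   `edges` (induced retained edges), `module`
#' @export
extract_driver_subnetwork <- function(module, modules, de,
                                      top_frac = 0.15, strength_cut = 0.3,
                                      ne_cut = 0.5, q_cut = 0.05,
                                      strength_scope = c("module", "global")) {
  stopifnot(inherits(modules, "network_modules"))
  strength_scope <- match.arg(strength_scope)
  mg <- modules$membership$symbol[modules$membership$module == module]
  if (length(mg) < 3) abort(sprintf("module %s has fewer than 3 genes", module))
  ed <- modules$edges |>
    filter(.data$gene_i %in% mg & .data$gene_j %in% mg)
  strengths <- if (strength_scope == "module") {
    node_strength(ed)
  } else {
    modules$strength
  }
  strengths <- tibble(symbol = mg) |>
    left_join(strengths, by = "symbol") |>
    mutate(strength = dplyr::coalesce(.data$strength, 0))

  tab <- if (inherits(de, "ne_fit")) de$table else as_tibble(de)
  n_top <- ceiling(top_frac * length(mg))
  top_genes <- strengths |> arrange(desc(.data$strength)) |>
    head(n_top) |> dplyr::pull("symbol")
  de_in_module <- intersect(de_genes(tab, q_cut, ne_cut)$symbol, mg)
  node_set <- union(top_genes, de_in_module)

  nodes <- tibble(symbol = node_set) |>
    left_join(strengths, by = "symbol") |>
    left_join(tab |> select("symbol", "ne", "q_value"), by = "symbol") |>
    mutate(direction = dplyr::case_when(
             is.na(.data$ne) ~ NA_character_,
             .data$ne < 0 ~ "AC",
             TRUE ~ "PA"),
           significant = !is.na(.data$q_value) & .data$q_value < q_cut,
           is_driver = .data$significant &
             .data$strength > strength_cut &
             (dplyr::coalesce(.data$ne, 0) > ne_cut |
                dplyr::coalesce(.data$ne, 0) < -ne_cut)) |>
    arrange(desc(.data$strength))
  structure(list(module = module,
                 nodes = nodes,
                 edges = ed |> filter(.data$gene_i %in% node_set &
                                        .data$gene_j %in% node_set)),
            class = "driver_subnetwork")
}

#' @export
print.driver_subnetwork <- function(x, ...) {
  cat(sprintf("<driver_subnetwork> module %s: %d node(s), %d edge(s), %d driver(s)\n",
              x$module, nrow(x$nodes), nrow(x$edges),
              sum(x$nodes$is_driver)))
  invisible(x)
}

#' @rdname extract_driver_subnetwork
#' @param x a `driver_subnetwork`
#' @param ... ignored
#' @export
tidy.driver_subnetwork <- function(x, ...) x$nodes

#' @rdname extract_driver_subnetwork
#' @export
glance.driver_subnetwork <- function(x, ...) {
  tibble(module = x$module, n_nodes = nrow(x$nodes),
         n_edges = nrow(x$edges), n_drivers = sum(x$nodes$is_driver))
}
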
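#' Volcano plot of normalized effects
#'
#' Normalized effect against -log10 q-value, with the selection rule
#' (`q < q_cut`, `|NE| > ne_cut`) drawn as dashed guides. Positive NE
#' (PA-enriched) plots right, negative (AC-enriched) left.
#'
#' @param fit an `ne_fit` from [fit_de()] (or its [tidy()] table)
#' @param q_cut,ne_cut selection thresholds to draw (defaults 0.05, 0.5)
#' @return a ggplot
#' @export
plot_volcano <- function(fit, q_cut = 0.05, ne_cut = 0.5) {
  tab <- if (inherits(fit, "ne_fit")) fit$table else as_tibble(fit)
  tab <- tab |>
    mutate(status = dplyr::case_when(
      .data$q_value < q_cut & .data$ne > ne_cut ~ "PA-enriched",
      .data$q_value < q_cut & .data$ne < -ne_cut ~ "AC-enriched",
      TRUE ~ "not selected"))
  ggplot(tab, aes(x = .data$ne, y = -log10(pmax(.data$q_value, 1e-300)),
                  colour = .data$status)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_vline(xintercept = c(-ne_cut, ne_cut), linetype = "dashed") +
    geom_hline(yintercept = -log10(q_cut), linetype = "dashed") +
    scale_colour_manual(values = c("AC-enriched" = "#c0392b",
                                   "PA-enriched" = "#16a085",
                                   "not selected" = "grey70")) +
    labs(x = "normalized effect (positive = higher in PA)",
         y = expression(-log[10] ~ "q-value"), colour = NULL) +
    theme_minimal()
}

#' Ranked NES bars for a GSEA result
#'
#' @param object a `gsea_result` from [preranked_gsea()]
#' @param q_cut highlight sets at FDR q below this (default 0.05)
#' @param ... ignored
#' @return a ggplot
#' @export
autoplot.gsea_result <- function(object, q_cut = 0.05, ...) {
  tab <- object$table |>
    mutate(set = stats::reorder(.data$set, .data$nes),
           significant = .data$q_value < q_cut)
  ggplot(tab, aes(x = .data$nes, y = .data$set, fill = .data$significant)) +
    geom_col() +
    scale_fill_manual(values = c(`TRUE` = "#2c3e50", `FALSE` = "grey75"),
                      labels = c(`TRUE` = paste0("q < ", q_cut),
                                 `FALSE` = "ns")) +
    labs(x = "normalized enrichment score", y = NULL, fill = NULL) +
    theme_minimal()
}

#' Plot a key-driver subnetwork
#'
#' Fruchterman-Reingold layout of the subnetwork; node colour encodes DE
#' direction (AC vs PA), shape marks key drivers, edge colour the sign of
#' the partial correlation and width its magnitude.
#'
#' @param object a `driver_subnetwork` from [extract_driver_subnetwork()]
#' @param seed layout seed
#' @param ... ignored
#' @return a ggplot
#' @export
autoplot.driver_subnetwork <- function(object, seed = 1L, ...) {
  nodes <- object$nodes
  g <- igraph::graph_from_data_frame(
    object$edges |> select("gene_i", "gene_j", "pcor"),
    directed = FALSE,
    vertices = nodes |> select("symbol"))
  set.seed(as.integer(seed))
  xy <- igraph::layout_with_fr(g)
  pos <- tibble(symbol = igraph::V(g)$name, x = xy[, 1], y = xy[, 2]) |>
    left_join(nodes, by = "symbol")
  seg <- object$edges |>
    left_join(pos |> select("symbol", "x", "y"),
              by = c(gene_i = "symbol")) |>
    left_join(pos |> select("symbol", xend = "x", yend = "y"),
              by = c(gene_j = "symbol"))
  ggplot() +
    geom_segment(data = seg,
                 aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, linewidth = abs(.data$pcor),
                     colour = .data$pcor > 0), alpha = 0.6) +
    geom_point(data = pos,
               aes(x = .data$x, y = .data$y, fill = .data$direction,
                   shape = .data$is_driver), size = 4) +
    geom_text(data = pos, aes(x = .data$x, y = .data$y,
                              label = .data$symbol),
              vjust = -1.2, size = 3) +
    scale_colour_manual(values = c(`TRUE` = "#27ae60", `FALSE` = "#e67e22"),
                        labels = c(`TRUE` = "positive", `FALSE` = "negative"),
                        name = "partial correlation") +
    scale_fill_manual(values = c(AC = "#c0392b", PA = "#16a085"),
                      na.value = "grey70", name = "higher in") +
    scale_shape_manual(values = c(`TRUE` = 22, `FALSE` = 21),
                       labels = c(`TRUE` = "key driver", `FALSE` = "member"),
                       name = NULL) +
    scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    theme_void()
}

#' Binary on/off heatmap in dendrogram order
#'
#' @param object a `bicluster_result` from [bicluster()]
#' @param regions optional region label per cell (colours the column strip)
#' @param ... ignored
#' @return a ggplot
#' @export
autoplot.bicluster_result <- function(object, regions = NULL, ...) {
  B <- object$binary[object$gene_tree$order, object$cell_tree$order,
                     drop = FALSE]
  long <- as_tibble(as.table(B * 1), .name_repair = \(x) c("gene", "cell", "on"))
  long$gene <- factor(long$gene, levels = rownames(B))
  long$cell <- factor(long$cell, levels = colnames(B))
  p <- ggplot(long, aes(x = .data$cell, y = .data$gene,
                        fill = .data$on > 0)) +
    geom_tile() +
    scale_fill_manual(values = c(`TRUE` = "#2c3e50", `FALSE` = "grey92"),
                      labels = c(`TRUE` = "on (count >= 2)", `FALSE` = "off"),
                      name = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_blank(), panel.grid = element_blank()) +
    labs(x = sprintf("%d cells", ncol(B)), y = NULL)
  p
}

#' QC removal summary plot
#'
#' @param report the QC report tibble from [qc_filter()]
#' @return a ggplot
#' @export
plot_qc <- function(report) {
  long <- report |>
    filter(.data$sample_id != "all") |>
    tidyr::pivot_longer(c("removed_mito", "removed_low_genes",
                          "removed_high_genes", "cells_out"),
                        names_to = "fate", values_to = "n")
  ggplot(long, aes(x = .data$sample_id, y = .data$n, fill = .data$fate)) +
    geom_col(position = "stack") +
    scale_fill_brewer(palette = "Set2") +
    labs(x = NULL, y = "cells", fill = NULL) +
    theme_minimal()
}
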
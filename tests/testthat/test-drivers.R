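# shared toy networks: k clique modules of 10 genes each, prefixes
# "a".."j", with controlled membership
toy_modules <- function(k = 3) {
  mk_clique <- function(genes, pcor) {
    pairs <- t(combn(genes, 2))
    tibble::tibble(gene_i = pairs[, 1], gene_j = pairs[, 2], pcor = pcor,
                   fdr = 0.01)
  }
  prefixes <- letters[seq_len(k)]
  ed <- dplyr::bind_rows(lapply(prefixes, function(p) {
    mk_clique(sprintf("%s%02d", p, 1:10), 0.3)
  }))
  ed$rank <- seq_len(nrow(ed)); ed$retained <- TRUE
  membership <- tibble::tibble(
    symbol = unlist(lapply(prefixes, function(p) sprintf("%s%02d", p, 1:10))),
    module = rep(seq_len(k), each = 10))
  modules_from_edges(ed, membership)
}

de_table <- function(sig_genes, ne = 1, universe) {
  tibble::tibble(symbol = universe,
                 ne = ifelse(universe %in% sig_genes, ne, 0.01),
                 p_value = ifelse(universe %in% sig_genes, 1e-6, 0.9),
                 q_value = ifelse(universe %in% sig_genes, 1e-5, 0.95))
}

test_that("a module holding all DE genes is maximally enriched, background-rate modules are not", {
  nm <- toy_modules()
  universe <- nm$membership$symbol
  de <- de_table(sprintf("a%02d", 1:8), universe = universe)
  enr <- select_enriched_modules(nm, de)
  expect_true(enr$selected[enr$module == 1])
  expect_equal(enr$p_value[enr$module == 1],
               fisher_one_tailed(matrix(c(8, 2, 0, 20), 2, 2, byrow = TRUE)),
               tolerance = 1e-12)
  expect_false(any(enr$selected[enr$module != 1]))
  # background-rate module: spread DE uniformly (roughly one per module)
  de_bg <- de_table(c("a01", "b01", "c01"), universe = universe)
  enr_bg <- select_enriched_modules(nm, de_bg)
  expect_false(any(enr_bg$selected))
  expect_true(all(enr_bg$p_value > 0.2))
})

test_that("module enrichment p-values match the hypergeometric oracle", {
  nm <- toy_modules()
  universe <- nm$membership$symbol
  de <- de_table(c(sprintf("a%02d", 1:5), "b01", "c07"), universe = universe)
  enr <- select_enriched_modules(nm, de)
  # oracle: P(X >= k) summing the hypergeometric pmf; 7 DE genes total,
  # module size 10, universe 30
  for (m in 1:3) {
    k <- enr$n_de[enr$module == m]
    oracle <- sum(stats::dhyper(k:7, 7, 23, 10))
    expect_equal(enr$p_value[enr$module == m], oracle, tolerance = 1e-12)
  }
})

test_that("planted DE concentrated in two of ten modules selects exactly those two", {
  nm <- toy_modules(k = 10)
  universe <- nm$membership$symbol
  hits <- 0
  for (r in 1:25) {
    set.seed(100 + r)
    sig <- c(sample(sprintf("a%02d", 1:10), 7),
             sample(sprintf("b%02d", 1:10), 7))
    enr <- select_enriched_modules(nm, de_table(sig, universe = universe))
    if (setequal(enr$module[enr$selected], c(1, 2))) hits <- hits + 1
  }
  expect_gte(hits / 25, 0.95)
})

test_that("hallmark overlap is specific only when a single module passes", {
  nm <- toy_modules(k = 10)
  universe <- nm$membership$symbol
  de <- de_table(universe, universe = universe)  # everything DE

  concentrated <- list(HM1 = sprintf("a%02d", 1:8))
  ov <- hallmark_module_overlap(nm, concentrated, de)
  expect_true(ov$specific[ov$module == 1])
  expect_equal(sum(ov$passes), 1)

  # one leading-edge gene per module: no module passes
  spread <- list(HM2 = sprintf("%s01", letters[1:10]))
  ov2 <- hallmark_module_overlap(nm, spread, de)
  expect_false(any(ov2$passes))
  expect_false(any(ov2$specific))

  # two modules each holding half: both pass, neither is specific
  halves <- list(HM3 = c(sprintf("a%02d", 1:7), sprintf("b%02d", 1:7)))
  ov3 <- hallmark_module_overlap(nm, halves, de)
  expect_gte(sum(ov3$passes), 2)
  expect_false(any(ov3$specific))

  expect_message(hallmark_module_overlap(nm, list(EMPTY = "zz"), de),
                 "empty leading edge")
})

test_that("driver subnetworks take the strength top-15% union of DE genes", {
  genes <- sprintf("m%03d", 1:100)
  # star-ish topology: first 20 genes highly connected
  ed <- dplyr::bind_rows(lapply(1:20, function(i) {
    tibble::tibble(gene_i = pmin(genes[i], genes[20 + (1:4) + 4 * (i - 1)]),
                   gene_j = pmax(genes[i], genes[20 + (1:4) + 4 * (i - 1)]),
                   pcor = 0.35, fdr = 0.01)
  }))
  ed$rank <- seq_len(nrow(ed)); ed$retained <- TRUE
  nm <- modules_from_edges(ed, tibble::tibble(symbol = genes, module = 1L))
  de <- de_table(c("m050", "m099"), ne = -1, universe = genes)
  sub <- extract_driver_subnetwork(1, nm, de)
  expect_equal(nrow(sub$nodes), length(union(
    dplyr::arrange(nm$strength, dplyr::desc(strength))$symbol[1:15],
    c("m050", "m099"))))
  expect_true(all(c("m050", "m099") %in% sub$nodes$symbol))
  # ceil(0.15 * 100) = 15 top-strength genes
  expect_equal(sum(!sub$nodes$symbol %in% c("m050", "m099")), 15)
})

test_that("driver flags respect strict threshold boundaries", {
  genes <- c("hub", paste0("s", 1:9))
  mk_star <- function(w_hub) {
    ed <- tibble::tibble(gene_i = pmin("hub", paste0("s", 1:9)),
                         gene_j = pmax("hub", paste0("s", 1:9)),
                         pcor = w_hub, fdr = 0.01)
    ed$rank <- seq_len(nrow(ed)); ed$retained <- TRUE
    modules_from_edges(ed, tibble::tibble(symbol = genes, module = 1L))
  }
  de <- tibble::tibble(symbol = genes, ne = -0.6, p_value = 1e-4,
                       q_value = 0.04)
  # spokes have a single edge; set its weight so spoke strength brackets 0.3
  above <- tidy(extract_driver_subnetwork(1, mk_star(0.31), de))
  below <- tidy(extract_driver_subnetwork(1, mk_star(0.29), de))
  expect_true(all(above$is_driver[above$symbol != "hub"]))
  expect_false(any(below$is_driver[below$symbol != "hub"]))
  # hub strength 9 * 0.29 passes regardless
  expect_true(below$is_driver[below$symbol == "hub"])

  # q at the boundary fails; |NE| at the boundary fails
  de_q <- dplyr::mutate(de, q_value = 0.05)
  expect_false(any(tidy(extract_driver_subnetwork(1, mk_star(0.31),
                                                  de_q))$is_driver))
  de_ne <- dplyr::mutate(de, ne = -0.5)
  sub_ne <- extract_driver_subnetwork(1, mk_star(0.31), de_ne)
  expect_false(any(tidy(sub_ne)$is_driver))
  expect_true(all(tidy(sub_ne)$direction == "AC"))
})

test_that("driver flags are invariant to edge-order permutation", {
  nm <- toy_modules()
  de <- de_table(sprintf("a%02d", 1:6), ne = 0.9,
                 universe = nm$membership$symbol)
  sub1 <- extract_driver_subnetwork(1, nm, de)
  set.seed(41)
  nm_perm <- nm
  nm_perm$edges <- nm$edges[sample(nrow(nm$edges)), ]
  sub2 <- extract_driver_subnetwork(1, nm_perm, de)
  j1 <- dplyr::arrange(tidy(sub1), symbol)
  j2 <- dplyr::arrange(tidy(sub2), symbol)
  expect_equal(j1$is_driver, j2$is_driver)
  expect_equal(j1$strength, j2$strength)
})

test_that("tiny modules are rejected", {
  ed <- tibble::tibble(gene_i = "a", gene_j = "b", pcor = 0.4, fdr = 0.01,
                       rank = 1L, retained = TRUE)
  nm <- modules_from_edges(ed, tibble::tibble(symbol = c("a", "b"),
                                              module = 1L))
  de <- de_table("a", universe = c("a", "b"))
  expect_error(extract_driver_subnetwork(1, nm, de), "fewer than 3")
})

test_that("planted hub drivers are consistently flagged across replicates", {
  flagged <- logical(20)
  for (r in seq_len(20)) {
    cfg <- sim_config(n_patients = 2, cells_per_sample = 150, n_genes = 60,
                      n_cell_types = 1, n_markers = 0, n_program = 0,
                      seed = 500 + r,
                      de_spec = data.frame(symbol = "G0030", effect = 1,
                                           mean = 5),
                      ggm_spec = list(list(
                        genes = sprintf("G%04d", 30:40), pcor = c(0.29, 0.29),
                        topology = "hub")))
    sim <- generate_cells(cfg)
    fit <- fit_de(sim$matrix)
    norm <- normalize_expression(sim$matrix)
    pc <- shrinkage_pcor(norm[!attr(norm, "zero_variance"), ])
    ed <- edge_fdr(pc, top_k = 120)
    nm <- build_modules(ed, seed = 1)
    hub_mod <- nm$membership$module[nm$membership$symbol == "G0030"]
    sub <- extract_driver_subnetwork(hub_mod, nm, fit)
    flagged[r] <- isTRUE(tidy(sub)$is_driver[tidy(sub)$symbol == "G0030"])
  }
  expect_gte(mean(flagged), 0.9)
})
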
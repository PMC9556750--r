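test_that("fully separated cell types are recovered exactly", {
  sim <- toy_sim(seed = 3, n_cell_types = 2)
  part <- partition_cells(sim$matrix, n_pcs = 10, seed = 1)
  truth <- sim$truth$cell_types$cell_type[match(part$barcode,
                                                sim$truth$cell_types$barcode)]
  expect_equal(dplyr::n_distinct(part$partition), 2)
  expect_equal(adjusted_rand_index(part$partition, truth), 1)
})

test_that("six planted types are recovered with high ARI and every cluster spans all samples", {
  sim <- generate_cells(sim_config(n_patients = 3,
                                   cells_per_sample = c(AC = 150, PA = 100),
                                   n_genes = 200, n_cell_types = 6,
                                   seed = 17))
  part <- partition_cells(sim$matrix, n_pcs = 20, k_neighbors = 15, seed = 2)
  truth <- sim$truth$cell_types$cell_type[match(part$barcode,
                                                sim$truth$cell_types$barcode)]
  expect_gte(adjusted_rand_index(part$partition, truth), 0.9)
  # reproducibility check: each cluster contains cells from all samples
  spread <- table(part$partition, part$sample_id)
  expect_true(all(spread > 0))
})

test_that("identical cells collapse to a single partition", {
  counts <- matrix(3L, 20, 30)
  cm <- make_cm(counts)
  part <- partition_cells(cm, n_pcs = 5, k_neighbors = 5, seed = 1)
  expect_equal(dplyr::n_distinct(part$partition), 1)
})

test_that("partition_cells validates dimensions", {
  cm <- make_cm(matrix(1:4, 2, 2))
  expect_error(partition_cells(cm[, 1], seed = 1), "at least 2 cells")
})

test_that("marker discovery applies strict ubiquity boundaries", {
  # partition 1 = cells 1..10, partition 2 = cells 11..20
  counts <- matrix(0L, 4, 20)
  counts[1, 1:9] <- 3L            # 90% of partition 1, mean 2.7
  counts[2, 1:8] <- 3L            # exactly 80% -> excluded
  counts[3, 1:9] <- 2L            # mean exactly 2*0.9 = 1.8 -> fails mean
  counts[4, 1:10] <- 5L           # 100%, mean 5 -> reported
  cm <- make_cm(counts, region = rep(c("AC", "PA"), each = 10))
  part <- tibble::tibble(cell = paste(cm$cells$sample_id, cm$cells$barcode,
                                      sep = "_"),
                         barcode = cm$cells$barcode,
                         sample_id = cm$cells$sample_id,
                         partition = rep(1:2, each = 10))
  mk <- find_partition_markers(cm, part, min_fraction = 0.8, min_mean = 2)
  p1 <- mk$symbol[mk$partition == 1]
  expect_setequal(p1, c("G001", "G004"))
  # ranked by fraction then mean
  expect_equal(p1, c("G004", "G001"))
})

test_that("marker discovery equals a brute-force scan on synthetic data", {
  sim <- toy_sim(seed = 23)
  part <- partition_cells(sim$matrix, n_pcs = 10, seed = 1)
  mk <- find_partition_markers(sim$matrix, part)
  counts <- as.matrix(sim$matrix$counts)
  key <- paste(sim$matrix$cells$sample_id, sim$matrix$cells$barcode, sep = "_")
  for (p in unique(part$partition)) {
    cols <- match(part$cell[part$partition == p], key)
    frac <- rowMeans(counts[, cols] >= 1)
    mn <- rowMeans(counts[, cols])
    oracle <- rownames(counts)[frac > 0.8 & mn > 2]
    expect_setequal(mk$symbol[mk$partition == p], oracle)
  }
})

test_that("cell types are assigned by reference-marker majority with ties unassigned", {
  mk <- tibble::tibble(
    partition = c(1, 1, 1, 2, 3, 3),
    symbol = c("CD2", "CD3E", "MYH11", "PECAM1", "AAA", "BBB"),
    fraction_expressing = 0.95, mean_count = 5)
  ref <- tibble::tibble(symbol = c("CD2", "CD3E", "MYH11", "PECAM1"),
                        cell_type = c("T/NKT", "T/NKT", "VSMC", "EC"))
  lab <- assign_cell_types(mk, ref)
  expect_equal(lab$label[lab$partition == 1], "T/NKT")  # 2 vs 1 majority
  expect_equal(lab$label[lab$partition == 2], "EC")
  expect_equal(lab$label[lab$partition == 3], "unassigned")

  tie <- assign_cell_types(
    tibble::tibble(partition = 1, symbol = c("CD2", "MYH11"),
                   fraction_expressing = 0.9, mean_count = 3), ref)
  expect_equal(tie$label, "unassigned")
  expect_warning(out <- assign_cell_types(mk, ref[0, ]), "empty")
  expect_true(all(out$label == "unassigned"))
})

test_that("planted types get fully correct labels from a configured reference", {
  sim <- toy_sim(seed = 29, n_cell_types = 3)
  part <- partition_cells(sim$matrix, n_pcs = 10, seed = 1)
  mk <- find_partition_markers(sim$matrix, part)
  cfg_genes <- sim_config(n_patients = 2, cells_per_sample = 100,
                          n_genes = 80, n_cell_types = 3, seed = 29)$genes
  ref <- dplyr::filter(cfg_genes, role == "marker") |>
    dplyr::transmute(symbol, cell_type = paste0("type", owner_type))
  lab <- assign_cell_types(mk, ref)
  truth <- sim$truth$cell_types$cell_type[match(part$barcode,
                                                sim$truth$cell_types$barcode)]
  major <- tapply(truth, part$partition, function(x)
    paste0("type", names(sort(table(x), decreasing = TRUE))[1]))
  expect_equal(lab$label, as.character(major[as.character(lab$partition)]))
})

test_that("exclusion sets enforce strict ubiquity and rarity boundaries", {
  counts <- matrix(0L, 4, 40)
  counts[1, 1:19] <- 1L           # 95% of partition 1, 0% elsewhere
  counts[2, 1:18] <- 1L           # exactly 90% -> excluded
  counts[3, c(1:19, 21:23)] <- 1L # 95% own but 15% foreign -> excluded
  counts[4, c(1:19, 21:22)] <- 1L # 95% own, 10% foreign exactly -> excluded
  cm <- make_cm(counts, region = rep(c("AC", "PA"), each = 20))
  part <- tibble::tibble(cell = paste(cm$cells$sample_id, cm$cells$barcode,
                                      sep = "_"),
                         barcode = cm$cells$barcode,
                         sample_id = cm$cells$sample_id,
                         partition = rep(1:2, each = 20))
  ex <- discover_exclusion_markers(cm, part, ubiquity = 0.9, rarity = 0.1)
  expect_equal(ex$symbol[ex$partition == 1], "G001")
  expect_equal(nrow(ex[ex$partition == 2, ]), 0)
  expect_error(discover_exclusion_markers(cm, part[part$partition == 1, ]),
               "2 partitions")
})

test_that("exclusion sets are partition-disjoint on synthetic data", {
  sim <- toy_sim(seed = 31, n_cell_types = 3)
  part <- partition_cells(sim$matrix, n_pcs = 10, seed = 1)
  ex <- discover_exclusion_markers(sim$matrix, part)
  expect_false(any(duplicated(ex$symbol)))
  expect_gt(nrow(ex), 0)
})

test_that("doublet flagging needs at least two inappropriate markers and is monotone", {
  # two partitions with known exclusion genes; craft cells expressing
  # 0, 1, 2 foreign markers
  counts <- matrix(0L, 6, 30)
  counts[1, 1:15] <- 2L; counts[2, 1:15] <- 2L    # partition 1 markers
  counts[3, 16:30] <- 2L; counts[4, 16:30] <- 2L  # partition 2 markers
  counts[5, 16:30] <- 2L
  # each foreign marker is expressed by at most 1/15 of partition 1 so
  # rarity (< 10%) still holds
  counts[3, 1] <- 1L                              # cell 1: one foreign marker
  counts[4, 2] <- 1L; counts[5, 2] <- 1L          # cell 2: two foreign markers
  cm <- make_cm(counts, region = rep(c("AC", "PA"), each = 15))
  part <- tibble::tibble(cell = paste(cm$cells$sample_id, cm$cells$barcode,
                                      sep = "_"),
                         barcode = cm$cells$barcode,
                         sample_id = cm$cells$sample_id,
                         partition = rep(1:2, each = 15))
  ex <- discover_exclusion_markers(cm, part)
  expect_setequal(ex$symbol[ex$partition == 1], c("G001", "G002"))
  expect_setequal(ex$symbol[ex$partition == 2], c("G003", "G004", "G005"))
  fl <- flag_doublets(cm, part, ex, min_markers = 2)
  expect_false(fl$flagged[1])
  expect_true(fl$flagged[2])
  expect_equal(fl$n_inappropriate[1], 1L)
  expect_setequal(fl$inappropriate_markers[[2]], c("G004", "G005"))

  # monotonicity: expressing one more foreign marker never unflags
  counts2 <- counts; counts2[3, 2] <- 1L
  cm2 <- make_cm(counts2, region = rep(c("AC", "PA"), each = 15))
  fl2 <- flag_doublets(cm2, part, ex, min_markers = 2)
  expect_true(all(fl2$flagged[fl$flagged]))
})

test_that("spiked doublets are recovered with elevated read counts", {
  sim <- generate_cells(sim_config(n_patients = 2, cells_per_sample = 250,
                                   n_genes = 120, n_cell_types = 3,
                                   seed = 37))
  sp <- spike_doublets(sim$matrix, sim$truth, 0.05, seed = 5)
  part <- partition_cells(sp$matrix, n_pcs = 15, seed = 1)
  # exclusion markers come from the major partitions; cells falling into
  # small (putative doublet) partitions are still screened
  ex <- discover_exclusion_markers(sp$matrix,
                                   drop_small_partitions(part, 50))
  fl <- flag_doublets(sp$matrix, part, ex)
  is_dbl <- fl$barcode %in% sp$truth$doublets$barcode
  expect_gte(mean(fl$flagged[is_dbl]), 0.7)
  expect_lte(mean(fl$flagged[!is_dbl]), 0.05)
  val <- validate_doublets_readcount(fl)
  expect_true(val$passes)
  expect_lt(val$p_value, 0.05)
})

test_that("randomly drawn flags show no systematic read-count shift", {
  set.seed(101)
  totals <- rpois(400, 500)
  n_sig <- 0
  for (i in 1:100) {
    flags <- tibble::tibble(total_umi = totals,
                            flagged = seq_along(totals) %in% sample(400, 20))
    v <- validate_doublets_readcount(flags)
    if (!is.na(v$p_value) && v$p_value < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 10)  # no shift at alpha = 0.05 in >= 90% of draws
})

test_that("a single flagged cell still yields a complete report", {
  flags <- tibble::tibble(total_umi = c(900, rep(400, 9)),
                          flagged = c(TRUE, rep(FALSE, 9)))
  v <- validate_doublets_readcount(flags)
  expect_equal(v$n_flagged, 1L)
  expect_false(is.na(v$p_value))
  expect_true(v$passes)
  empty <- validate_doublets_readcount(dplyr::mutate(flags, flagged = FALSE))
  expect_equal(empty$n_flagged, 0L)
  expect_true(is.na(empty$p_value))
})

test_that("small partitions can be dropped before downstream analysis", {
  part <- tibble::tibble(cell = sprintf("c%03d", 1:120),
                         barcode = sprintf("c%03d", 1:120),
                         sample_id = "S1",
                         partition = rep(c(1, 2, 3), c(60, 55, 5)))
  kept <- drop_small_partitions(part, min_cells = 50)
  expect_setequal(unique(kept$partition), c(1, 2))
})
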
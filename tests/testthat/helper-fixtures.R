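# Small fixture builders shared across test files. Everything is built
# in code; no binary fixtures.

# hand-built count matrix: counts is genes x cells, cells get one sample
# per region unless a sample vector is given
make_cm <- function(counts, region = NULL, sample_id = NULL,
                    patient_id = NULL, symbols = NULL, mito = NULL) {
  n <- ncol(counts)
  region <- region %||% rep(c("AC", "PA"), length.out = n)
  sample_id <- sample_id %||% paste0("S_", region)
  patient_id <- patient_id %||% rep("P1", n)
  symbols <- symbols %||% sprintf("G%03d", seq_len(nrow(counts)))
  genes <- tibble::tibble(symbol = symbols)
  if (!is.null(mito)) genes$is_mito <- mito
  count_matrix(counts,
               tibble::tibble(barcode = sprintf("BC%04d", seq_len(n)),
                              sample_id = sample_id,
                              patient_id = patient_id,
                              region = region),
               genes)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# two-type toy study with exclusive high markers; small and fast
toy_sim <- function(seed = 1, ..., n_cell_types = 2) {
  generate_cells(sim_config(n_patients = 2, cells_per_sample = 100,
                            n_genes = 80, n_cell_types = n_cell_types,
                            seed = seed, ...))
}

# network_modules object built directly from an edge tibble (retained
# edges only), for driver tests that need full control of the topology
modules_from_edges <- function(edges, membership) {
  structure(list(membership = membership,
                 strength = node_strength(edges),
                 edges = dplyr::mutate(edges, retained = TRUE),
                 weight_mode = "affinity"),
            class = "network_modules")
}
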
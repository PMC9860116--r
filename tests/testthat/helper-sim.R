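# Shared fixtures and oracles, all built in code.

# small lognorm expression matrix + annotation from a dense matrix and a
# vector of per-cell types
tiny_lognorm <- function(values, types, dataset = "d1", batch = "b1",
                         source = "tissue_mature", age_dpc = NA_real_) {
  genes <- rownames(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  cells <- paste0(batch, "_c", seq_len(ncol(values)))
  m <- expression_matrix(Matrix::Matrix(values, sparse = TRUE),
                         genes = genes, cells = cells, layer = "lognorm")
  ann <- cell_annotation(data.frame(
    cell_id = cells, cell_type = types, dataset = dataset, batch = batch,
    source = source, protocol = NA_character_, age_dpc = age_dpc,
    stringsAsFactors = FALSE))
  list(matrix = m, annotation = ann)
}

# the worked example: g1 on only in type A, g2 only in B, g3 constant
worked_example <- function() {
  vals <- rbind(g1 = c(2, 2, 0, 0), g2 = c(0, 0, 2, 2), g3 = c(1, 1, 1, 1))
  tiny_lognorm(vals, c("A", "A", "B", "B"))
}

# brute-force identity scores: materializes every pairwise rank difference
brute_identity_scores <- function(s) {
  G <- nrow(s$nz); K <- ncol(s$nz)
  r1 <- apply(s$nz, 2, function(x) rank(x, ties.method = "average") / G)
  r2 <- apply(-s$cv, 2, function(x) rank(x, ties.method = "average") / G)
  out <- matrix(0, G, K, dimnames = dimnames(s$nz))
  for (g in seq_len(G)) for (k in seq_len(K)) {
    acc <- 0
    for (kp in seq_len(K)) {
      if (kp == k) next
      acc <- acc + ((r1[g, k] - r1[g, kp]) + (r2[g, k] - r2[g, kp])) / 2
    }
    out[g, k] <- acc / (K - 1)
  }
  out
}

# random stability statistics with occasional silent genes (cv = Inf)
random_stability <- function(G, K) {
  nz <- matrix(runif(G * K), G, K,
               dimnames = list(paste0("g", seq_len(G)), LETTERS[seq_len(K)]))
  cv <- matrix(rexp(G * K), G, K, dimnames = dimnames(nz))
  silent <- matrix(runif(G * K) < 0.1, G, K)
  nz[silent] <- 0
  cv[silent] <- Inf
  structure(list(nz = nz, cv = cv,
                 n_cells = stats::setNames(rep(50L, K), colnames(nz))),
            class = "stability_stats")
}

# split a simulate_tissue() result into per-batch (matrix, annotation) pairs
split_batches <- function(tis) {
  lapply(split(seq_len(nrow(tis$annotation)), tis$annotation$batch),
         function(i) {
           idx <- tis$annotation$cell_id[i]
           list(matrix = expression_matrix(
             tis$matrix$values[, idx, drop = FALSE],
             genes = tis$matrix$genes, cells = idx, layer = "counts"),
             annotation = tis$annotation[i, , drop = FALSE])
         })
}

# per-batch identity scores from a simulate_tissue() result
batch_identity_scores <- function(tis, min_cells = 20) {
  lapply(split_batches(tis), function(b) {
    m <- log_normalize(b$matrix)
    identity_scores(stability_stats(m, b$annotation, min_cells = min_cells),
                    dataset = b$annotation$dataset[1],
                    batch = b$annotation$batch[1])
  })
}

# age grid for the fetal+mature maturation fixture (dpc)
maturation_ages <- function(n = 16) round(seq(55, 280, length.out = n))

# cached heavy fixtures (default study conditions), shared across test files
.fixture_cache <- new.env(parent = emptyenv())

default_tissue <- function() {
  if (is.null(.fixture_cache$tissue))
    .fixture_cache$tissue <- simulate_tissue(sim_config(seed = 101))
  .fixture_cache$tissue
}

default_fetal_tissue <- function() {
  if (is.null(.fixture_cache$fetal_tissue))
    .fixture_cache$fetal_tissue <- simulate_tissue(
      sim_config(ages = maturation_ages(8), seed = 102))
  .fixture_cache$fetal_tissue
}

default_fetal_reference <- function() {
  if (is.null(.fixture_cache$fetal_reference))
    .fixture_cache$fetal_reference <-
      build_reference(split_batches(default_fetal_tissue()), group = "fetal")
  .fixture_cache$fetal_reference
}

default_reference <- function() {
  if (is.null(.fixture_cache$reference))
    .fixture_cache$reference <- build_reference(split_batches(default_tissue()),
                                                group = "mature")
  .fixture_cache$reference
}

# small multi-type simulation for module tests
small_tissue <- function(seed = 5, n_genes = 300, n_batches = 4,
                         cells_per_batch = 350, ...) {
  simulate_tissue(sim_config(n_genes = n_genes, n_markers = 10,
                             n_batches = n_batches,
                             cells_per_batch = cells_per_batch,
                             seed = seed, ...))
}
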
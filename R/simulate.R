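#' Simulation configuration for synthetic retinal tissue
#'
#' Defaults describe a multi-batch retinal tissue atlas at desk scale:
#' 2,000 genes, the 7 major retinal cell types in equal proportions (200
#' cells per type per batch), 50 planted marker genes per type with a 2
#' natural-log-fold effect, 8 batches with log-normal multiplicative batch
#' effects (sd 0.15 on the log scale), log-normal library sizes around 2,000
#' counts, and negative-binomial counts with dispersion 0.3. When `ages` is supplied (one dpc per batch),
#' each type additionally gets `n_ramp_genes` whose mean expression in that
#' type scales with age as `exp(ramp_slope * age_scaled)`, i.e. `ramp_slope`
#' natural-log folds over the full age range — the same effect-size units as
#' `marker_effect`.
#'
#' @param n_genes number of genes.
#' @param cell_types cell-type names.
#' @param proportions per-type proportions (sum to 1).
#' @param n_markers planted markers per type.
#' @param marker_effect natural-log fold change of markers in their type.
#' @param n_batches number of batches.
#' @param batch_sd sd of per-batch log-normal gene factors (0 = no batch
#'   effect).
#' @param cells_per_batch cells per batch.
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param ages optional dpc per batch (length `n_batches`); NULL for mature
#'   tissue.
#' @param n_ramp_genes age-ramp genes per type (used when ages given).
#' @param ramp_slope natural-log fold change of ramp genes over the full age
#'   range: the mean is multiplied by `exp(ramp_slope * age_scaled)`.
#' @param seed integer seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       cell_types = cell_type_vocabulary()$canonical,
                       proportions = NULL,
                       n_markers = 50, marker_effect = 2,
                       n_batches = 8, batch_sd = 0.15,
                       cells_per_batch = 1400,
                       libsize_meanlog = log(2000), libsize_sdlog = 0.3,
                       dispersion = 0.3,
                       ages = NULL, n_ramp_genes = 50, ramp_slope = 2,
                       seed = 1L) {
  if (is.null(proportions))
    proportions <- rep(1 / length(cell_types), length(cell_types))
  if (abs(sum(proportions) - 1) > 1e-8 || any(proportions < 0))
    stop("proportions must be a simplex")
  if (length(proportions) != length(cell_types))
    stop("one proportion per cell type required")
  if (!is.null(ages) && length(ages) != n_batches)
    stop("ages must have one entry per batch")
  if (is.null(seed)) stop("seed is mandatory")
  structure(list(n_genes = n_genes, cell_types = cell_types,
                 proportions = proportions, n_markers = n_markers,
                 marker_effect = marker_effect, n_batches = n_batches,
                 batch_sd = batch_sd, cells_per_batch = cells_per_batch,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog, dispersion = dispersion,
                 ages = ages, n_ramp_genes = n_ramp_genes,
                 ramp_slope = ramp_slope, seed = as.integer(seed)),
            class = "sim_config")
}

#' Load a simulation configuration from YAML
#'
#' @param path YAML file with `sim_config` fields.
#' @return A [sim_config()].
#' @export
sim_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(sim_config, raw)
}

.type_counts <- function(proportions, n, types) {
  cnt <- floor(proportions * n)
  left <- n - sum(cnt)
  if (left > 0) {
    extra <- order(proportions * n - cnt, decreasing = TRUE)[seq_len(left)]
    cnt[extra] <- cnt[extra] + 1
  }
  stats::setNames(as.integer(cnt), types)
}

.sim_counts_block <- function(w, libsizes, dispersion) {
  # w: relative expression weights per gene; one column of counts per cell
  p <- w / sum(w)
  mu <- outer(p, libsizes)
  matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
         nrow = length(p))
}

#' Simulate multi-batch retinal tissue counts with known ground truth
#'
#' Counts are negative binomial around per-cell means built from log-normal
#' relative gene abundances, multiplied in each type by the planted marker
#' effect, per batch by log-normal batch factors, per cell by a log-normal
#' library size, and (for aged batches) by the age ramp of that type's ramp
#' genes. The returned truth tables record the marker and ramp assignments
#' and the generative parameters, so downstream recovery can be checked
#' exactly.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (counts [expression_matrix()]), `annotation`
#'   (a [cell_annotation()]) and `truth` (markers, ramps, base abundances,
#'   config).
#' @export
simulate_tissue <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes
  K <- length(cfg$cell_types)
  genes <- sprintf("gene%04d", seq_len(G))
  base_rel <- stats::setNames(stats::rlnorm(G, 0, 1), genes)
  marker_pool <- sample(genes, K * cfg$n_markers)
  markers <- data.frame(
    gene = marker_pool,
    cell_type = rep(cfg$cell_types, each = cfg$n_markers),
    effect = cfg$marker_effect, stringsAsFactors = FALSE)
  ramps <- NULL
  if (!is.null(cfg$ages) && cfg$n_ramp_genes > 0) {
    ramp_pool <- sample(setdiff(genes, marker_pool), K * cfg$n_ramp_genes)
    # half the ramps per type gain expression with age, half lose it
    sgn <- rep(rep(c(1, -1), length.out = cfg$n_ramp_genes), K)
    ramps <- data.frame(
      gene = ramp_pool,
      cell_type = rep(cfg$cell_types, each = cfg$n_ramp_genes),
      slope = cfg$ramp_slope * sgn, stringsAsFactors = FALSE)
  }
  # per-type relative abundance: markers up-shifted in their own type
  type_w <- sapply(cfg$cell_types, function(k) {
    w <- base_rel
    mk <- markers$gene[markers$cell_type == k]
    w[mk] <- w[mk] * exp(cfg$marker_effect)
    w
  })
  age_rng <- if (!is.null(cfg$ages)) range(cfg$ages) else c(0, 0)
  blocks <- list(); ann <- list()
  for (b in seq_len(cfg$n_batches)) {
    bf <- if (cfg$batch_sd > 0) stats::rlnorm(G, 0, cfg$batch_sd) else rep(1, G)
    age <- if (!is.null(cfg$ages)) cfg$ages[b] else NA_real_
    age_s <- if (!is.na(age) && diff(age_rng) > 0)
      (age - age_rng[1]) / diff(age_rng) else 0
    cnt <- .type_counts(cfg$proportions, cfg$cells_per_batch, cfg$cell_types)
    for (k in cfg$cell_types) {
      nk <- cnt[[k]]
      if (nk == 0) next
      w <- type_w[, k] * bf
      if (!is.null(ramps)) {
        sel <- ramps$cell_type == k
        w[ramps$gene[sel]] <- w[ramps$gene[sel]] * exp(ramps$slope[sel] * age_s)
      }
      libs <- stats::rlnorm(nk, cfg$libsize_meanlog, cfg$libsize_sdlog)
      blocks[[length(blocks) + 1L]] <-
        .sim_counts_block(w, libs, cfg$dispersion)
      ann[[length(ann) + 1L]] <- data.frame(
        cell_type = rep(k, nk), batch = sprintf("batch%02d", b),
        age_dpc = age, stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, blocks)
  anno <- do.call(rbind, ann)
  anno$cell_id <- sprintf("cell%06d", seq_len(nrow(anno)))
  anno$dataset <- "sim_tissue"
  anno$source <- if (is.null(cfg$ages)) "tissue_mature" else "tissue_fetal"
  anno$protocol <- NA_character_
  anno <- cell_annotation(anno[, c("cell_id", "cell_type", "dataset", "batch",
                                   "source", "protocol", "age_dpc")])
  m <- expression_matrix(methods::as(counts, "CsparseMatrix"),
                         genes = genes, cells = anno$cell_id,
                         layer = "counts")
  list(matrix = m, annotation = anno,
       truth = list(markers = markers, ramps = ramps, base_rel = base_rel,
                    type_w = type_w, config = cfg))
}

#' Organoid degradation configuration
#'
#' Knobs emulate the failure axes the fidelity benchmark scores: noise on the
#' per-gene identity program (`identity_noise_sd`), missing cell types
#' (`dropped_types`), skewed cell-type proportions (`proportion_skew`, a
#' Dirichlet concentration; `Inf` keeps the tissue proportions exactly),
#' off-target cells drawn from an unrelated expression program
#' (`offtarget_fraction`), and the developmental position of the age ramps
#' (`age_position` in \[0, 1\], 0 = youngest fetal, 1 = oldest).
#'
#' @param identity_noise_sd sd of log-normal per-gene mean jitter.
#' @param dropped_types cell types absent from the organoid.
#' @param proportion_skew Dirichlet concentration around tissue proportions.
#' @param offtarget_fraction fraction of off-target cells in \[0, 1\].
#' @param age_position position along the age ramp in \[0, 1\].
#' @param n_cells organoid cells simulated.
#' @param protocol protocol label recorded in the annotation.
#' @param batch batch label.
#' @param seed integer seed (mandatory).
#' @return An `organoid_sim_config` list.
#' @export
organoid_sim_config <- function(identity_noise_sd = 0,
                                dropped_types = character(),
                                proportion_skew = Inf,
                                offtarget_fraction = 0,
                                age_position = 1,
                                n_cells = 5600,
                                protocol = "sim_protocol",
                                batch = "org01",
                                seed = 1L) {
  if (offtarget_fraction < 0 || offtarget_fraction > 1)
    stop("offtarget_fraction must be in [0, 1]")
  if (age_position < 0 || age_position > 1)
    stop("age_position must be in [0, 1]")
  if (is.null(seed)) stop("seed is mandatory")
  structure(list(identity_noise_sd = identity_noise_sd,
                 dropped_types = dropped_types,
                 proportion_skew = proportion_skew,
                 offtarget_fraction = offtarget_fraction,
                 age_position = age_position, n_cells = n_cells,
                 protocol = protocol, batch = batch,
                 seed = as.integer(seed)),
            class = "organoid_sim_config")
}

.rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x <- alpha
  x / sum(x)
}

#' Simulate an organoid dataset from a tissue ground truth
#'
#' Draws cells from the tissue generative model with per-gene mean jitter,
#' drops the configured cell types, perturbs the cell-type proportions by a
#' Dirichlet draw, positions the age-ramp genes at `age_position`, and
#' appends off-target cells from an independent log-normal expression
#' program (annotated as `"other"` and flagged in the truth table).
#'
#' @param tissue_truth the `truth` element returned by [simulate_tissue()].
#' @param ocfg an [organoid_sim_config()].
#' @return list with `matrix`, `annotation` and `truth` (per-cell off-target
#'   flags and the drawn proportions).
#' @export
simulate_organoid <- function(tissue_truth, ocfg) {
  stopifnot(inherits(ocfg, "organoid_sim_config"))
  cfg <- tissue_truth$config
  set.seed(ocfg$seed)
  keep <- setdiff(cfg$cell_types, ocfg$dropped_types)
  if (!length(keep)) stop("all cell types dropped")
  G <- cfg$n_genes
  genes <- names(tissue_truth$base_rel)
  p0 <- cfg$proportions[match(keep, cfg$cell_types)]
  p0 <- p0 / sum(p0)
  props <- if (is.finite(ocfg$proportion_skew))
    .rdirichlet1(ocfg$proportion_skew * p0) else p0
  names(props) <- keep
  n_off <- floor(ocfg$offtarget_fraction * ocfg$n_cells)
  n_on <- ocfg$n_cells - n_off
  cnt <- .type_counts(props, n_on, keep)
  jitter <- if (ocfg$identity_noise_sd > 0)
    stats::rlnorm(G, 0, ocfg$identity_noise_sd) else rep(1, G)
  names(jitter) <- genes
  blocks <- list(); ann <- list()
  for (k in keep) {
    nk <- cnt[[k]]
    if (nk == 0) next
    w <- tissue_truth$type_w[, k] * jitter
    if (!is.null(tissue_truth$ramps)) {
      sel <- tissue_truth$ramps$cell_type == k
      rg <- tissue_truth$ramps$gene[sel]
      w[rg] <- w[rg] * exp(tissue_truth$ramps$slope[sel] * ocfg$age_position)
    }
    libs <- stats::rlnorm(nk, cfg$libsize_meanlog, cfg$libsize_sdlog)
    blocks[[length(blocks) + 1L]] <- .sim_counts_block(w, libs,
                                                       cfg$dispersion)
    ann[[length(ann) + 1L]] <- data.frame(cell_type = rep(k, nk),
                                          offtarget = FALSE,
                                          stringsAsFactors = FALSE)
  }
  if (n_off > 0) {
    w_off <- stats::rlnorm(G, 0, 1)
    libs <- stats::rlnorm(n_off, cfg$libsize_meanlog, cfg$libsize_sdlog)
    blocks[[length(blocks) + 1L]] <- .sim_counts_block(w_off, libs,
                                                       cfg$dispersion)
    ann[[length(ann) + 1L]] <- data.frame(cell_type = rep("other", n_off),
                                          offtarget = TRUE,
                                          stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, blocks)
  anno <- do.call(rbind, ann)
  anno$cell_id <- sprintf("org%06d", seq_len(nrow(anno)))
  anno$dataset <- "sim_organoid"
  anno$batch <- ocfg$batch
  anno$source <- "organoid"
  anno$protocol <- ocfg$protocol
  anno$age_dpc <- NA_real_
  offtarget <- anno$offtarget
  anno <- cell_annotation(anno[, c("cell_id", "cell_type", "dataset", "batch",
                                   "source", "protocol", "age_dpc")])
  m <- expression_matrix(methods::as(counts, "CsparseMatrix"),
                         genes = genes, cells = anno$cell_id,
                         layer = "counts")
  list(matrix = m, annotation = anno,
       truth = list(offtarget = stats::setNames(offtarget, anno$cell_id),
                    proportions = props, config = ocfg))
}
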
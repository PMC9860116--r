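#' Per-cell-type expression stability statistics
#'
#' For one (dataset, batch), computes for every gene and retained cell type
#' the fraction of cells with nonzero expression (`nz`) and the coefficient
#' of variation (`cv`, population standard deviation divided by mean) of the
#' log-normalized values, zeros included. Genes with mean zero in a type get
#' `cv = Inf` so that silent genes receive the worst stability rank. Cell
#' types with fewer than `min_cells` cells are dropped from the batch.
#'
#' @param m an [expression_matrix()] with `layer = "lognorm"` restricted to
#'   one (dataset, batch).
#' @param ann a [cell_annotation()] covering `m`'s cells (harmonized labels).
#' @param min_cells minimum cells per type (default 20).
#' @return A `stability_stats` object: list with gene-by-type matrices `nz`
#'   and `cv` and the per-type cell counts `n_cells`.
#' @export
stability_stats <- function(m, ann, min_cells = 20) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$layer != "lognorm")
    stop("stability_stats expects log-normalized values")
  idx <- match(m$cells, ann$cell_id)
  if (anyNA(idx)) stop("annotation does not cover all cells in the matrix")
  type <- as.character(ann$cell_type[idx])
  counts <- table(type)
  keep <- names(counts)[counts >= min_cells]
  if (length(keep) < 2)
    stop("fewer than 2 cell types with >= ", min_cells,
         " cells; differential score undefined")
  keep <- sort(keep)
  G <- length(m$genes)
  nz <- cv <- matrix(NA_real_, G, length(keep),
                     dimnames = list(m$genes, keep))
  for (k in keep) {
    xk <- m$values[, type == k, drop = FALSE]
    n <- ncol(xk)
    nz[, k] <- Matrix::rowSums(xk > 0) / n
    mu <- Matrix::rowSums(xk) / n
    ex2 <- Matrix::rowSums(xk^2) / n
    s <- sqrt(pmax(ex2 - mu^2, 0))        # population sd
    cv[, k] <- ifelse(mu > 0, s / mu, Inf)
  }
  structure(list(nz = nz, cv = cv,
                 n_cells = stats::setNames(as.integer(counts[keep]), keep)),
            class = "stability_stats")
}

.frac_rank <- function(x) rank(x, ties.method = "average") / length(x)

#' Differential-stability cell-identity scores
#'
#' Within each cell type, genes are ranked (ascending fractional ranks, ties
#' averaged, divided by the gene count) by their nonzero fraction and by
#' their negated coefficient of variation, so that genes expressed broadly
#' and stably in a type rank high. The identity score of gene g in type k is
#' the average, over the other types k', of the mean rank difference:
#'
#' \deqn{s(g,k) = \frac{1}{K-1} \sum_{k' \ne k}
#'   \frac{(r_1(g,k)-r_1(g,k')) + (r_2(g,k)-r_2(g,k'))}{2}}
#'
#' Scores lie in (-1, 1) and sum to zero across cell types for every gene.
#' High scores mark genes whose stable expression is specific to that type —
#' cell-identity genes.
#'
#' @param s a [stability_stats()] result.
#' @param dataset,batch identifiers recorded on the result.
#' @return An `identity_scores` object: list with the gene-by-type `scores`
#'   matrix plus `dataset` and `batch`.
#' @export
identity_scores <- function(s, dataset = NA_character_, batch = NA_character_) {
  stopifnot(inherits(s, "stability_stats"))
  K <- ncol(s$nz)
  G <- nrow(s$nz)
  if (K < 2) stop("need at least 2 cell types")
  if (G < 2) stop("need at least 2 genes")
  r1 <- apply(s$nz, 2, .frac_rank)
  r2 <- apply(-s$cv, 2, .frac_rank)
  r <- (r1 + r2) / 2
  # s(g,k) = r(g,k) - mean over other types; algebraically identical to the
  # pairwise-difference form
  tot <- rowSums(r)
  scores <- r - (tot - r) / (K - 1)
  dimnames(scores) <- dimnames(s$nz)
  structure(list(scores = scores, dataset = dataset, batch = batch),
            class = "identity_scores")
}

#' @exportS3Method base::print
print.identity_scores <- function(x, ...) {
  cat(sprintf("<identity_scores> %d genes x %d cell types (%s / %s)\n",
              nrow(x$scores), ncol(x$scores), x$dataset, x$batch))
  invisible(x)
}

.score_matrix <- function(x) {
  if (inherits(x, "identity_scores")) x$scores
  else if (inherits(x, "reference_atlas")) x$mean_scores
  else as.matrix(x)
}

#' Average identity scores over batches
#'
#' Unweighted mean per (gene, cell type) over the common gene universe
#' (intersection across batches). A cell type absent from a batch is skipped
#' in that batch's contribution: the divisor is the number of batches that
#' contain the type.
#'
#' @param batch_scores list of [identity_scores()] (or plain gene-by-type
#'   matrices).
#' @return A gene-by-type matrix of averaged scores.
#' @export
average_scores <- function(batch_scores) {
  mats <- lapply(batch_scores, .score_matrix)
  if (!length(mats)) stop("no batches supplied")
  genes <- Reduce(intersect, lapply(mats, rownames))
  if (!length(genes)) stop("empty intersection of gene universes")
  types <- sort(unique(unlist(lapply(mats, colnames))))
  acc <- matrix(0, length(genes), length(types),
                dimnames = list(genes, types))
  nb <- stats::setNames(numeric(length(types)), types)
  for (mat in mats) {
    ks <- colnames(mat)
    acc[, ks] <- acc[, ks] + mat[genes, ks, drop = FALSE]
    nb[ks] <- nb[ks] + 1
  }
  sweep(acc, 2, nb, "/")
}

#' Build a reference atlas from tissue batches
#'
#' Scores each (dataset, batch) independently ([stability_stats()] then
#' [identity_scores()]), averages the score matrices, pools cell-type
#' proportions across batches, and keeps the per-batch score profiles ordered
#' by developmental age for the maturation metric. Fetal references can be
#' subdivided at `age_split_dpc` days post-conception into early and late
#' groups. Mean log-normalized expression centroids per cell type are stored
#' for reference-based classification.
#'
#' @param batches list of `list(matrix = , annotation = )` pairs; matrices may
#'   be counts (normalized internally) or lognorm.
#' @param group one of `"mature"`, `"fetal"`, `"fetal_early"`, `"fetal_late"`.
#' @param age_split_dpc age split for early/late fetal references
#'   (default 100 dpc).
#' @param min_cells passed to [stability_stats()].
#' @return A `reference_atlas`: list with `group`, `mean_scores`,
#'   `proportions`, `age_profiles` (per batch: age_rank, age_dpc, dataset,
#'   batch, scores) and `centroids`.
#' @export
build_reference <- function(batches, group = c("mature", "fetal",
                                               "fetal_early", "fetal_late"),
                            age_split_dpc = 100, min_cells = 20) {
  group <- match.arg(group)
  want_src <- if (group == "mature") "tissue_mature" else "tissue_fetal"
  for (b in batches) {
    src <- unique(b$annotation$source)
    if (!all(src == want_src))
      stop("group '", group, "' requires source ", want_src,
           " but got: ", paste(src, collapse = ", "))
  }
  ages <- vapply(batches, function(b) {
    a <- unique(b$annotation$age_dpc)
    if (all(is.na(a))) NA_real_ else stats::median(a, na.rm = TRUE)
  }, numeric(1))
  if (group == "fetal_early") {
    sel <- which(!is.na(ages) & ages <= age_split_dpc)
    if (!length(sel)) stop("no fetal samples at or below ", age_split_dpc, " dpc")
    batches <- batches[sel]; ages <- ages[sel]
  } else if (group == "fetal_late") {
    sel <- which(!is.na(ages) & ages > age_split_dpc)
    if (!length(sel)) stop("no fetal samples above ", age_split_dpc, " dpc")
    batches <- batches[sel]; ages <- ages[sel]
  }
  per_batch <- vector("list", length(batches))
  counts_pool <- list()
  centroid_sum <- NULL; centroid_n <- NULL
  for (i in seq_along(batches)) {
    b <- batches[[i]]
    m <- b$matrix
    if (m$layer == "counts") m <- log_normalize(m)
    ss <- stability_stats(m, b$annotation, min_cells = min_cells)
    ds <- unique(b$annotation$dataset)[1]
    bt <- unique(b$annotation$batch)[1]
    per_batch[[i]] <- identity_scores(ss, dataset = ds, batch = bt)
    counts_pool[[i]] <- table(b$annotation$cell_type[
      match(m$cells, b$annotation$cell_id)])
    # expression centroids on the batch's retained types
    type <- as.character(b$annotation$cell_type[match(m$cells,
                                                      b$annotation$cell_id)])
    for (k in colnames(ss$nz)) {
      mu <- Matrix::rowMeans(m$values[, type == k, drop = FALSE])
      key <- k
      if (is.null(centroid_sum)) {
        centroid_sum <- list(); centroid_n <- list()
      }
      if (is.null(centroid_sum[[key]])) {
        centroid_sum[[key]] <- mu; centroid_n[[key]] <- 1
      } else {
        shared <- intersect(names(centroid_sum[[key]]), names(mu))
        centroid_sum[[key]] <- centroid_sum[[key]][shared] + mu[shared]
        centroid_n[[key]] <- centroid_n[[key]] + 1
      }
    }
  }
  mean_scores <- average_scores(per_batch)
  all_counts <- table(unlist(lapply(counts_pool, function(tb)
    rep(names(tb), as.integer(tb)))))
  proportions <- as.numeric(all_counts) / sum(all_counts)
  names(proportions) <- names(all_counts)
  ord <- order(ages, na.last = TRUE)
  age_profiles <- lapply(seq_along(ord), function(j) {
    i <- ord[j]
    list(age_rank = j, age_dpc = ages[i],
         dataset = per_batch[[i]]$dataset, batch = per_batch[[i]]$batch,
         scores = per_batch[[i]]$scores)
  })
  genes <- rownames(mean_scores)
  centroids <- do.call(cbind, lapply(names(centroid_sum), function(k) {
    v <- centroid_sum[[k]] / centroid_n[[k]]
    v[genes]
  }))
  colnames(centroids) <- names(centroid_sum)
  rownames(centroids) <- genes
  structure(list(group = group, mean_scores = mean_scores,
                 proportions = proportions, age_profiles = age_profiles,
                 centroids = centroids, batch_scores = per_batch),
            class = "reference_atlas")
}

#' @exportS3Method base::print
print.reference_atlas <- function(x, ...) {
  cat(sprintf("<reference_atlas> group=%s: %d genes x %d types, %d batches\n",
              x$group, nrow(x$mean_scores), ncol(x$mean_scores),
              length(x$age_profiles)))
  invisible(x)
}

#' Annotation confidence by ensemble reclassification
#'
#' Semi-supervised assessment of cell-type labels: over `n_rounds` rounds, a
#' nearest-centroid classifier in PCA space is trained on a stratified random
#' `train_frac` of the cells and used to predict the held-out cells. The
#' confidence of a cell's label is the fraction of rounds, among those in
#' which it was held out, whose prediction agrees with the original label.
#' Cells of types with fewer than 3 cells are excluded (probability `NA`);
#' cells never held out get probability 1 with a warning.
#'
#' @param m an [expression_matrix()] with `layer = "lognorm"`.
#' @param ann a [cell_annotation()] covering `m`'s cells.
#' @param n_rounds number of resampling rounds (>= 10; default 50).
#' @param train_frac training fraction per round (default 0.8).
#' @param n_pcs number of principal components (default 20).
#' @param seed integer seed.
#' @return A data.frame `cell_id`, `probability`, `band` (`very_high` > 0.9,
#'   `high` > 0.7, `low` otherwise).
#' @export
annotation_confidence <- function(m, ann, n_rounds = 50, train_frac = 0.8,
                                  n_pcs = 20, seed = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$layer != "lognorm") stop("annotation_confidence expects lognorm values")
  if (!is.numeric(n_rounds) || n_rounds < 10)
    stop("n_rounds must be at least 10")
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be in (0, 1)")
  idx <- match(m$cells, ann$cell_id)
  if (anyNA(idx)) stop("annotation does not cover all cells")
  type <- as.character(ann$cell_type[idx])
  counts <- table(type)
  eligible_types <- names(counts)[counts >= 3]
  if (length(eligible_types) < 2) stop("need at least 2 cell types with >= 3 cells")
  elig <- type %in% eligible_types
  x <- t(as.matrix(m$values[, elig, drop = FALSE]))
  ty <- type[elig]
  npc <- min(n_pcs, nrow(x) - 1L, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = npc)$x
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pc)
  held <- integer(n); correct <- integer(n)
  by_type <- split(seq_len(n), ty)
  for (r in seq_len(n_rounds)) {
    train <- unlist(lapply(by_type, function(ii) {
      ntr <- max(1L, floor(train_frac * length(ii)))
      sample(ii, ntr)
    }), use.names = FALSE)
    test <- setdiff(seq_len(n), train)
    if (!length(test)) next
    cent <- do.call(rbind, lapply(by_type, function(ii) {
      colMeans(pc[intersect(ii, train), , drop = FALSE])
    }))
    # nearest centroid, squared Euclidean
    d2 <- outer(rowSums(pc[test, , drop = FALSE]^2), rowSums(cent^2), "+") -
      2 * pc[test, , drop = FALSE] %*% t(cent)
    pred <- rownames(cent)[max.col(-d2, ties.method = "first")]
    held[test] <- held[test] + 1L
    correct[test] <- correct[test] + as.integer(pred == ty[test])
  }
  prob_elig <- ifelse(held > 0, correct / pmax(held, 1L), 1)
  if (any(held == 0))
    warning(sum(held == 0), " cell(s) were never held out; probability set to 1")
  probability <- rep(NA_real_, length(type))
  probability[elig] <- prob_elig
  band <- ifelse(is.na(probability), NA_character_,
                 ifelse(probability > 0.9, "very_high",
                        ifelse(probability > 0.7, "high", "low")))
  data.frame(cell_id = m$cells, probability = probability, band = band,
             stringsAsFactors = FALSE)
}

#' Retain cells annotated above a confidence threshold
#'
#' Keeps cells with confidence probability strictly greater than `threshold`
#' (default 0.9, the "very high" band). Cells with `NA` probability are
#' dropped.
#'
#' @param ann a [cell_annotation()].
#' @param conf the data.frame from [annotation_confidence()].
#' @param threshold retention threshold in \[0, 1\].
#' @return The filtered annotation.
#' @export
filter_by_confidence <- function(ann, conf, threshold = 0.9) {
  stopifnot(threshold >= 0, threshold <= 1)
  p <- conf$probability[match(ann$cell_id, conf$cell_id)]
  keep <- !is.na(p) & p > threshold
  out <- ann[keep, , drop = FALSE]
  if (!nrow(out)) {
    warning("no cells pass the confidence threshold")
  } else {
    frac <- tapply(keep, ann$dataset, mean)
    message("retained fraction per dataset: ",
            paste(sprintf("%s=%.2f", names(frac), frac), collapse = ", "))
  }
  out
}
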
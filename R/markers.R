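#' Select top identity genes per cell type
#'
#' Takes, for each cell type, the `top_n` genes by descending identity score;
#' ties are broken lexicographically by gene identifier so the selection is
#' deterministic.
#'
#' @param reference_scores gene-by-type score matrix (or [identity_scores()]
#'   / `reference_atlas`).
#' @param top_n markers per type (default 50).
#' @return A `marker_set`: named list of data.frames (gene, score, rank) per
#'   cell type, with attribute `top_n`.
#' @export
select_markers <- function(reference_scores, top_n = 50) {
  scores <- .score_matrix(reference_scores)
  if (top_n < 1) stop("top_n must be >= 1")
  if (top_n > nrow(scores)) {
    warning("top_n exceeds gene count; truncated to ", nrow(scores))
    top_n <- nrow(scores)
  }
  genes <- rownames(scores)
  out <- lapply(colnames(scores), function(k) {
    ord <- order(-scores[, k], genes)[seq_len(top_n)]
    data.frame(gene = genes[ord], score = scores[ord, k],
               rank = seq_len(top_n), novelty = NA_character_,
               stringsAsFactors = FALSE)
  })
  names(out) <- colnames(scores)
  structure(out, top_n = top_n, class = "marker_set")
}

#' @exportS3Method base::print
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d cell types, top_n = %d\n",
              length(x), attr(x, "top_n")))
  invisible(x)
}

#' Annotate marker novelty from a literature query-count table
#'
#' Given precomputed publication counts per gene (e.g. from a literature
#' search run outside this package), classifies each marker as `known`
#' (count > 0), `novel` (count = 0) or `unannotated` (gene absent from the
#' table).
#'
#' @param ms a [select_markers()] result.
#' @param query_counts named numeric vector or two-column data.frame
#'   (gene, count).
#' @return The marker set with the `novelty` column filled in.
#' @export
annotate_novelty <- function(ms, query_counts) {
  if (is.data.frame(query_counts))
    query_counts <- stats::setNames(query_counts[[2]],
                                    as.character(query_counts[[1]]))
  if (any(!is.na(query_counts) & query_counts < 0))
    stop("format error: negative query counts")
  for (k in names(ms)) {
    cnt <- query_counts[ms[[k]]$gene]
    ms[[k]]$novelty <- ifelse(is.na(cnt), "unannotated",
                              ifelse(cnt > 0, "known", "novel"))
  }
  ms
}

#' Expression specificity of marker genes
#'
#' For each requested gene and cell type, the proportion of cells with
#' nonzero expression; and per gene and type, the fraction of
#' (dataset, batch) units in which the gene is detected in more than
#' `det_frac` of that type's cells.
#'
#' @param m an [expression_matrix()] with `layer = "lognorm"`.
#' @param ann a [cell_annotation()] covering `m`'s cells.
#' @param genes genes to profile.
#' @param det_frac detection fraction defining unit-level presence
#'   (default 0.1).
#' @return list with matrices `prop_cells` and `batch_presence`
#'   (gene x type); unknown genes get NA rows with a warning.
#' @export
expression_specificity <- function(m, ann, genes, det_frac = 0.1) {
  stopifnot(inherits(m, "expr_matrix"))
  idx <- match(m$cells, ann$cell_id)
  type <- as.character(ann$cell_type[idx])
  unit <- paste(ann$dataset[idx], ann$batch[idx], sep = "\r")
  known <- genes[genes %in% m$genes]
  unknown <- setdiff(genes, known)
  if (length(unknown))
    warning("unknown gene(s): ", paste(unknown, collapse = ", "))
  types <- sort(unique(type))
  prop <- pres <- matrix(NA_real_, length(genes), length(types),
                         dimnames = list(genes, types))
  det <- m$values[known, , drop = FALSE] > 0
  for (k in types) {
    sel <- type == k
    prop[known, k] <- Matrix::rowSums(det[, sel, drop = FALSE]) / sum(sel)
    units_k <- unique(unit[sel])
    hit <- matrix(0, length(known), length(units_k))
    for (j in seq_along(units_k)) {
      su <- sel & unit == units_k[j]
      hit[, j] <- Matrix::rowSums(det[, su, drop = FALSE]) / sum(su) > det_frac
    }
    pres[known, k] <- rowMeans(hit)
  }
  list(prop_cells = prop, batch_presence = pres)
}

.dense_subset <- function(m, genes) {
  as.matrix(m$values[genes, , drop = FALSE])
}

#' Validate markers with a kNN classifier
#'
#' Classifies test cells by k-nearest-neighbor vote among training cells,
#' using the Pearson correlation distance (1 - r) computed on the given gene
#' subset. Vote ties are broken by the larger summed similarity, then
#' lexicographically.
#'
#' @param train,test each a `list(matrix = expression_matrix, labels = )`.
#' @param genes gene subset (intersected with both universes).
#' @param k neighborhood size; must be odd (default 5).
#' @return list with `overall` accuracy, `per_type` accuracies and the
#'   predicted labels.
#' @export
knn_validate <- function(train, test, genes, k = 5) {
  if (k %% 2 == 0) stop("k must be odd")
  genes <- Reduce(intersect, list(genes, train$matrix$genes,
                                  test$matrix$genes))
  if (!length(genes)) stop("empty gene subset after intersection")
  xtr <- .dense_subset(train$matrix, genes)
  xte <- .dense_subset(test$matrix, genes)
  sim <- suppressWarnings(stats::cor(xtr, xte))
  sim[is.na(sim)] <- -Inf
  labs <- as.character(train$labels)
  pred <- character(ncol(xte))
  for (j in seq_len(ncol(xte))) {
    nn <- order(sim[, j], decreasing = TRUE)[seq_len(min(k, nrow(sim)))]
    votes <- table(labs[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      ssum <- vapply(top, function(l)
        sum(sim[nn[labs[nn] == l], j]), numeric(1))
      top <- top[order(-ssum, top)]
    }
    pred[j] <- top[1]
  }
  truth <- as.character(test$labels)
  per_type <- tapply(pred == truth, truth, mean)
  list(overall = mean(pred == truth),
       per_type = per_type, predicted = pred)
}

#' Random-forest permutation importance of marker genes
#'
#' Fits a random-forest classifier of cell type on the given gene subset and
#' returns the permutation importance (mean decrease in accuracy), floored at
#' zero. Deterministic for a fixed seed.
#'
#' @param m an [expression_matrix()] with `layer = "lognorm"`.
#' @param ann a [cell_annotation()] covering `m`'s cells.
#' @param genes gene subset.
#' @param n_trees number of trees (default 500).
#' @param seed integer seed.
#' @return Named numeric vector of importances per gene.
#' @export
rf_importance <- function(m, ann, genes, n_trees = 500, seed = NULL) {
  genes <- intersect(genes, m$genes)
  if (!length(genes)) stop("empty gene subset")
  y <- factor(ann$cell_type[match(m$cells, ann$cell_id)])
  if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes")
  x <- t(.dense_subset(m, genes))
  colnames(x) <- make.names(genes)
  if (!is.null(seed)) set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = droplevels(y),
                                    ntree = n_trees, importance = TRUE)
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  stats::setNames(pmax(as.numeric(imp), 0), genes)
}
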
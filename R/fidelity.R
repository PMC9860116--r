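#' Cell-identity fidelity metric
#'
#' Per cell type shared between the organoid score matrix and the reference,
#' the Pearson correlation between the organoid's score column and the
#' reference's batch-averaged column over the shared gene universe; the
#' metric is the mean over shared types.
#'
#' @param org_scores an [identity_scores()] (or gene-by-type matrix) for one
#'   organoid unit.
#' @param ref a `reference_atlas` (or gene-by-type matrix).
#' @return list with `per_type` correlations and their `mean`.
#' @export
metric_cell_identity <- function(org_scores, ref) {
  a <- .score_matrix(org_scores)
  b <- .score_matrix(ref)
  types <- intersect(colnames(a), colnames(b))
  if (!length(types)) {
    warning("no shared cell types between organoid and reference")
    return(list(per_type = stats::setNames(numeric(0), character(0)),
                mean = NA_real_))
  }
  genes <- intersect(rownames(a), rownames(b))
  per_type <- vapply(types, function(k)
    suppressWarnings(stats::cor(a[genes, k], b[genes, k])), numeric(1))
  list(per_type = per_type, mean = mean(per_type, na.rm = TRUE))
}

#' Maturation fidelity metric
#'
#' For each cell type with at least 4 age-ordered reference profiles, the
#' organoid score column is correlated with the reference profile at every
#' age rank; the metric is the Pearson correlation of these similarities with
#' the age ranks. Positive values mean the organoid resembles older (more
#' adult-like) references, negative values younger (more fetal-like) ones.
#' The mean over cell types is reported unscaled in \[-1, 1\].
#'
#' @param org_scores an [identity_scores()] or gene-by-type matrix.
#' @param ref_age_profiles list of profiles, each
#'   `list(age_rank = , scores = gene-by-type matrix)`, as stored in a
#'   `reference_atlas$age_profiles` or built by [combine_age_profiles()].
#' @return list with `per_type` trajectory correlations and their `mean`.
#' @export
metric_maturation <- function(org_scores, ref_age_profiles) {
  a <- .score_matrix(org_scores)
  types <- colnames(a)
  per_type <- stats::setNames(rep(NA_real_, length(types)), types)
  for (k in types) {
    has <- vapply(ref_age_profiles, function(p) k %in% colnames(p$scores),
                  logical(1))
    if (sum(has) < 4) next
    profs <- ref_age_profiles[has]
    rks <- vapply(profs, function(p) as.numeric(p$age_rank), numeric(1))
    s <- vapply(profs, function(p) {
      g <- intersect(rownames(a), rownames(p$scores))
      suppressWarnings(stats::cor(a[g, k], p$scores[g, k]))
    }, numeric(1))
    ok <- !is.na(s)
    if (sum(ok) >= 4 && stats::sd(s[ok]) > 0)
      per_type[k] <- stats::cor(s[ok], rks[ok])
  }
  list(per_type = per_type, mean = mean(per_type, na.rm = TRUE))
}

#' Combine fetal and mature reference profiles on one age axis
#'
#' Fetal profiles keep their age order; mature profiles (which have no dpc)
#' are appended after them at higher age ranks, so the axis runs from
#' youngest fetal to mature tissue.
#'
#' @param fetal,mature `reference_atlas` objects (either may be `NULL`).
#' @return A list of age profiles usable by [metric_maturation()].
#' @export
combine_age_profiles <- function(fetal = NULL, mature = NULL) {
  profs <- list()
  if (!is.null(fetal)) profs <- fetal$age_profiles
  if (!is.null(mature)) {
    offset <- length(profs)
    profs <- c(profs, lapply(seq_along(mature$age_profiles), function(i) {
      p <- mature$age_profiles[[i]]
      p$age_rank <- offset + i
      p
    }))
  }
  for (i in seq_along(profs)) profs[[i]]$age_rank <- i
  profs
}

#' Cell-type coverage metric
#'
#' Fraction of the expected major cell types present in the dataset, where a
#' type counts as present when it has at least `min_cells` cells and at least
#' `min_prop` of all cells.
#'
#' @param ann a [cell_annotation()] with harmonized labels.
#' @param expected expected canonical types (default the 7 major retinal
#'   types).
#' @param min_cells minimum cell count (default 10).
#' @param min_prop minimum proportion (default 0.005).
#' @return Fraction in \[0, 1\].
#' @export
metric_coverage <- function(ann, expected = cell_type_vocabulary()$canonical,
                            min_cells = 10, min_prop = 0.005) {
  n <- nrow(ann)
  tb <- table(ann$cell_type)
  present <- vapply(expected, function(k) {
    ct <- if (k %in% names(tb)) as.integer(tb[[k]]) else 0L
    ct >= min_cells && ct / n >= min_prop
  }, logical(1))
  sum(present) / length(expected)
}

#' Cell-type proportion metric
#'
#' Similarity between the organoid's cell-type composition and the
#' reference's, over the union of types (missing types counted as 0). The
#' default is one minus the total-variation distance,
#' `1 - 0.5 * sum(|p - q|)`; `method = "pearson"` instead reports the
#' Pearson correlation of the proportion vectors mapped to \[0, 1\].
#'
#' @param ann a [cell_annotation()].
#' @param ref a `reference_atlas` (or named proportion vector).
#' @param method `"tv"` or `"pearson"`.
#' @return Similarity in \[0, 1\].
#' @export
metric_proportion <- function(ann, ref, method = c("tv", "pearson")) {
  method <- match.arg(method)
  q <- if (inherits(ref, "reference_atlas")) ref$proportions else ref
  tb <- table(ann$cell_type)
  p <- as.numeric(tb) / sum(tb)
  names(p) <- names(tb)
  types <- union(names(p), names(q))
  pv <- ifelse(types %in% names(p), p[types], 0)
  qv <- ifelse(types %in% names(q), q[types], 0)
  if (method == "tv") 1 - 0.5 * sum(abs(pv - qv))
  else (suppressWarnings(stats::cor(pv, qv)) + 1) / 2
}

#' Nearest-centroid classification with rejection
#'
#' Assigns each cell the reference cell type whose expression centroid it
#' correlates with best (Pearson, on the gene subset). A cell is `unassigned`
#' when its best similarity falls below `s_min`, and `intermediate` when the
#' margin between the best and second-best similarity is below `s_margin`.
#' Centroids with zero variance on the subset are excluded with their
#' similarity set to NA.
#'
#' @param m an [expression_matrix()] with `layer = "lognorm"`.
#' @param ref_train either a gene-by-type centroid matrix (e.g.
#'   `reference_atlas$centroids`) or a `list(matrix = , labels = )` from
#'   which centroids are computed.
#' @param genes gene subset; default all shared genes.
#' @param s_min minimum similarity for assignment (default 0.3).
#' @param s_margin minimum winning margin (default 0.05).
#' @return A `rejection_classification`: data.frame `cell_id`, `label`, with
#'   the similarity matrix as attribute `similarity`.
#' @export
classify_with_rejection <- function(m, ref_train, genes = NULL,
                                    s_min = 0.3, s_margin = 0.05) {
  stopifnot(inherits(m, "expr_matrix"))
  centroids <- if (is.list(ref_train) && !is.null(ref_train$matrix)) {
    labs <- as.character(ref_train$labels)
    vals <- ref_train$matrix$values
    do.call(cbind, lapply(sort(unique(labs)), function(k)
      Matrix::rowMeans(vals[, labs == k, drop = FALSE])))
  } else {
    as.matrix(ref_train)
  }
  if (is.list(ref_train) && !is.null(ref_train$matrix))
    colnames(centroids) <- sort(unique(as.character(ref_train$labels)))
  if (is.null(genes)) genes <- intersect(m$genes, rownames(centroids))
  genes <- Reduce(intersect, list(genes, m$genes, rownames(centroids)))
  if (length(genes) < 3) stop("fewer than 3 usable genes")
  cm <- centroids[genes, , drop = FALSE]
  ok_cent <- apply(cm, 2, stats::sd) > 0
  if (!any(ok_cent)) stop("all centroids constant on the gene subset")
  x <- .dense_subset(m, genes)
  sim <- matrix(NA_real_, ncol(x), ncol(cm),
                dimnames = list(m$cells, colnames(cm)))
  sim[, ok_cent] <- t(suppressWarnings(
    stats::cor(cm[, ok_cent, drop = FALSE], x)))
  label <- character(ncol(x))
  for (i in seq_len(ncol(x))) {
    s <- sim[i, ]
    s <- s[!is.na(s)]
    if (!length(s)) { label[i] <- "unassigned"; next }
    s <- sort(s, decreasing = TRUE)
    if (s[1] < s_min) label[i] <- "unassigned"
    else if (length(s) > 1 && (s[1] - s[2]) < s_margin)
      label[i] <- "intermediate"
    else label[i] <- names(s)[1]
  }
  structure(data.frame(cell_id = m$cells, label = label,
                       stringsAsFactors = FALSE),
            similarity = sim, class = c("rejection_classification",
                                        "data.frame"))
}

#' Off-target cell proportion metric
#'
#' Proportion of cells classified as `intermediate` or `unassigned` by
#' [classify_with_rejection()]. Lower is better.
#'
#' @param c a `rejection_classification`.
#' @return Proportion in \[0, 1\].
#' @export
metric_offtarget <- function(c) {
  if (!nrow(c)) stop("empty classification")
  mean(c$label %in% c("intermediate", "unassigned"))
}

.minmax <- function(x) {
  if (all(is.na(x))) return(rep(NA_real_, length(x)))
  r <- range(x, na.rm = TRUE)
  if (diff(r) == 0) rep(0.5, length(x)) else (x - r[1]) / diff(r)
}

#' Six-metric fidelity benchmark of organoid units
#'
#' Scores each organoid unit (protocol, dataset, batch) with six metrics
#' against tissue references: cell identity versus the mature and the fetal
#' reference, maturation along the age-resolved profiles, cell-type coverage,
#' cell-type proportion versus the mature reference, and the off-target cell
#' fraction. With two or more units, identity, coverage and proportion are
#' min-max scaled to \[0, 1\] across units; maturation stays signed and
#' off-target stays a raw proportion. The combined score is the mean of the
#' six components after orienting each so that higher is better (maturation
#' mapped to \[0, 1\], off-target inverted), and units are ranked by
#' descending combined score with ties broken by the mature identity metric.
#'
#' @param units list of `list(protocol = , matrix = , annotation = )`; the
#'   matrix may be counts (normalized internally).
#' @param refs list with `reference_atlas` elements `mature` and `fetal`
#'   (optionally `fetal_early`, `fetal_late`).
#' @param min_cells per-type minimum for unit scoring (default 20).
#' @param top_n_markers markers per type used for off-target classification
#'   (default 50).
#' @param s_min,s_margin rejection thresholds, see
#'   [classify_with_rejection()].
#' @return A `fidelity_report`: list with the per-unit metric `table`, the
#'   per-type identity breakdown `per_type_ci`, and `config`.
#' @export
benchmark <- function(units, refs, min_cells = 20, top_n_markers = 50,
                      s_min = 0.3, s_margin = 0.05) {
  if (!length(units)) stop("no units supplied")
  stopifnot(inherits(refs$mature, "reference_atlas"))
  # a real age axis needs the fetal (age-resolved) reference; mature batches
  # alone carry no age ordering, so maturation is undefined without it
  age_profiles <- if (!is.null(refs$fetal))
    combine_age_profiles(refs$fetal, refs$mature) else NULL
  marker_genes <- unique(unlist(lapply(
    select_markers(refs$mature, top_n = top_n_markers), `[[`, "gene")))
  rows <- list(); per_type_ci <- list()
  for (i in seq_along(units)) {
    u <- units[[i]]
    m <- u$matrix
    if (m$layer == "counts") m <- log_normalize(m)
    ann <- u$annotation
    sc <- identity_scores(stability_stats(m, ann, min_cells = min_cells),
                          dataset = unique(ann$dataset)[1],
                          batch = unique(ann$batch)[1])
    ci_m <- metric_cell_identity(sc, refs$mature)
    ci_f <- if (!is.null(refs$fetal)) metric_cell_identity(sc, refs$fetal)
            else list(per_type = NULL, mean = NA_real_)
    mat <- if (is.null(age_profiles)) list(mean = NA_real_)
           else metric_maturation(sc, age_profiles)
    cov <- metric_coverage(ann)
    prp <- metric_proportion(ann, refs$mature)
    cls <- classify_with_rejection(m, refs$mature$centroids,
                                   genes = marker_genes,
                                   s_min = s_min, s_margin = s_margin)
    off <- metric_offtarget(cls)
    rows[[i]] <- data.frame(
      protocol = if (is.null(u$protocol)) paste0("unit", i) else u$protocol,
      dataset = unique(ann$dataset)[1], batch = unique(ann$batch)[1],
      ci_mature = ci_m$mean, ci_fetal = ci_f$mean, maturation = mat$mean,
      coverage = cov, proportion = prp, offtarget = off,
      stringsAsFactors = FALSE)
    per_type_ci[[i]] <- list(mature = ci_m$per_type, fetal = ci_f$per_type)
  }
  tab <- do.call(rbind, rows)
  names(per_type_ci) <- tab$protocol
  if (nrow(tab) >= 2) {
    tab$ci_mature_scaled <- .minmax(tab$ci_mature)
    tab$ci_fetal_scaled <- .minmax(tab$ci_fetal)
    tab$coverage_scaled <- .minmax(tab$coverage)
    tab$proportion_scaled <- .minmax(tab$proportion)
  } else {
    warning("single unit: min-max scaling skipped, raw values used")
    tab$ci_mature_scaled <- tab$ci_mature
    tab$ci_fetal_scaled <- tab$ci_fetal
    tab$coverage_scaled <- tab$coverage
    tab$proportion_scaled <- tab$proportion
  }
  comp <- cbind(tab$ci_mature_scaled, tab$ci_fetal_scaled,
                (tab$maturation + 1) / 2, tab$coverage_scaled,
                tab$proportion_scaled, 1 - tab$offtarget)
  tab$combined <- rowMeans(comp, na.rm = TRUE)
  ord <- order(-tab$combined, -tab$ci_mature, tab$protocol)
  tab$rank <- integer(nrow(tab))
  tab$rank[ord] <- seq_len(nrow(tab))
  structure(list(table = tab, per_type_ci = per_type_ci,
                 config = list(min_cells = min_cells,
                               top_n_markers = top_n_markers,
                               s_min = s_min, s_margin = s_margin)),
            class = "fidelity_report")
}

#' @exportS3Method base::print
print.fidelity_report <- function(x, ...) {
  cat("<fidelity_report>\n")
  print(x$table[order(x$table$rank),
                c("protocol", "batch", "ci_mature", "ci_fetal", "maturation",
                  "coverage", "proportion", "offtarget", "combined", "rank")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
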
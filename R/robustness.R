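#' Correlation of identity-score profiles between two score tables
#'
#' Pearson correlation between every cell-type column of `a` and every column
#' of `b`, over the shared gene universe. Constant columns yield `NA` with a
#' warning.
#'
#' @param a,b gene-by-type score matrices (or [identity_scores()] objects).
#' @return A matrix of correlations, types of `a` in rows, of `b` in columns.
#' @export
score_similarity <- function(a, b) {
  a <- .score_matrix(a); b <- .score_matrix(b)
  genes <- intersect(rownames(a), rownames(b))
  if (length(genes) < 3) stop("fewer than 3 shared genes")
  av <- a[genes, , drop = FALSE]; bv <- b[genes, , drop = FALSE]
  const <- c(apply(av, 2, stats::sd) == 0, apply(bv, 2, stats::sd) == 0)
  if (any(const))
    warning("constant column(s); correlations reported as NA")
  suppressWarnings(stats::cor(av, bv))
}

#' Stability of averaged identity scores under batch subsampling
#'
#' For each subsampling fraction, repeatedly draws `ceiling(f * B)` batches
#' without replacement, averages their score matrices, and correlates each
#' cell-type column with the full-batch average; reports the mean correlation
#' over replicates. At fraction 1 the subsample is the full set and the
#' correlation is exactly 1.
#'
#' @param batch_scores list of [identity_scores()] (>= 4 batches).
#' @param fractions subsample fractions in (0, 1\]; default 0.5 to 0.9.
#' @param n_reps replicates per fraction (default 20).
#' @param seed integer seed.
#' @return A `stability_curve`: list with a long data.frame `curve`
#'   (fraction, cell_type, mean_correlation), `n_reps` and `seed`.
#' @export
subsample_stability <- function(batch_scores, fractions = seq(0.5, 0.9, 0.1),
                                n_reps = 20, seed = NULL) {
  B <- length(batch_scores)
  if (B < 4) stop("need at least 4 batches")
  full <- average_scores(batch_scores)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (f in fractions) {
    nb <- ceiling(f * B)
    if (nb < 1) {
      warning("fraction ", f, " selects no batches; skipped")
      next
    }
    if (nb >= B) {
      # the subsample is the full set: the correlation is 1 by definition
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, cell_type = colnames(full),
        mean_correlation = 1, stringsAsFactors = FALSE)
      next
    }
    sums <- stats::setNames(numeric(ncol(full)), colnames(full))
    cnts <- sums
    for (r in seq_len(n_reps)) {
      sub <- average_scores(batch_scores[sample.int(B, nb)])
      ks <- intersect(colnames(sub), colnames(full))
      g <- intersect(rownames(sub), rownames(full))
      cc <- vapply(ks, function(k)
        suppressWarnings(stats::cor(sub[g, k], full[g, k])), numeric(1))
      ok <- !is.na(cc)
      sums[ks[ok]] <- sums[ks[ok]] + cc[ok]
      cnts[ks[ok]] <- cnts[ks[ok]] + 1
    }
    mean_r <- ifelse(cnts > 0, sums / cnts, NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = f, cell_type = names(mean_r),
      mean_correlation = as.numeric(mean_r), stringsAsFactors = FALSE)
  }
  structure(list(curve = do.call(rbind, rows), n_reps = n_reps, seed = seed),
            class = "stability_curve")
}

.one_way_mom <- function(y, g) {
  # one-way random-effects variance component, method of moments
  g <- as.factor(droplevels(as.factor(g)))
  a <- nlevels(g); N <- length(y)
  if (a < 2 || a >= N) return(list(sigma2 = NA_real_, msw = NA_real_))
  ni <- as.numeric(table(g))
  ybar_i <- tapply(y, g, mean)
  ybar <- mean(y)
  msb <- sum(ni * (ybar_i - ybar)^2) / (a - 1)
  msw <- sum((y - ybar_i[g])^2) / (N - a)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  list(sigma2 = max(0, (msb - msw) / n0), msw = msw)
}

#' Principal variance component analysis
#'
#' Apportions the variance of sample score profiles to experimental factors.
#' Profiles are column-centered and decomposed by PCA; principal components
#' are retained until the cumulative explained variance reaches
#' `var_threshold` (or `n_pcs` when given). For each retained component, the
#' variance component of every factor is estimated by the one-way
#' random-effects method of moments, the residual is taken as the smallest
#' within-group mean square across factors, and the components are normalized
#' to proportions; the per-component proportions are then averaged with
#' eigenvalue-share weights.
#'
#' @param profiles sample-by-gene numeric matrix (one row per sample).
#' @param factors data.frame of per-sample factors (e.g. batch, cell_type).
#' @param n_pcs fixed number of components, or `NULL` to use `var_threshold`.
#' @param var_threshold cumulative variance cutoff (default 0.6).
#' @return A `pvca_result`: data.frame with columns `factor` and `proportion`
#'   (factors plus `residual`, summing to 1).
#' @export
pvca <- function(profiles, factors, n_pcs = NULL, var_threshold = 0.6) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) != nrow(factors))
    stop("profiles and factors must have one row per sample")
  keep <- apply(profiles, 2, stats::sd) > 0
  pc <- stats::prcomp(profiles[, keep, drop = FALSE], center = TRUE,
                      scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev[ev > 1e-12]
  share <- ev / sum(ev)
  npc <- if (!is.null(n_pcs)) min(n_pcs, length(ev))
         else max(1L, which(cumsum(share) >= var_threshold)[1])
  if (is.na(npc)) npc <- length(ev)
  fnames <- names(factors)
  prop <- matrix(0, npc, length(fnames) + 1L,
                 dimnames = list(NULL, c(fnames, "residual")))
  confounded <- character()
  for (j in seq_len(npc)) {
    y <- pc$x[, j]
    comps <- stats::setNames(numeric(length(fnames)), fnames)
    msws <- c()
    for (f in fnames) {
      est <- .one_way_mom(y, factors[[f]])
      if (is.na(est$sigma2)) {
        confounded <- union(confounded, f)
        comps[f] <- 0
      } else {
        comps[f] <- est$sigma2
        msws <- c(msws, est$msw)
      }
    }
    resid <- if (length(msws)) min(msws) else stats::var(y)
    tot <- sum(comps) + resid
    prop[j, ] <- c(comps, resid) / tot
  }
  if (length(confounded))
    warning("factor(s) confounded with samples, absorbed into residual: ",
            paste(confounded, collapse = ", "))
  w <- share[seq_len(npc)] / sum(share[seq_len(npc)])
  overall <- colSums(prop * w)
  structure(data.frame(factor = names(overall),
                       proportion = as.numeric(overall),
                       stringsAsFactors = FALSE),
            class = c("pvca_result", "data.frame"))
}

#' Concordance of sample clustering with known labelings
#'
#' Clusters sample profiles by average-linkage hierarchical clustering on the
#' Pearson correlation distance (1 - r) over the top-variance genes, cuts the
#' tree at the number of levels of each evaluated labeling, and reports the
#' adjusted Rand index against that labeling.
#'
#' @param profiles sample-by-gene numeric matrix.
#' @param label_sets named list of per-sample label vectors
#'   (e.g. cell_type, dataset, batch).
#' @param n_genes number of top-variance genes used (default all).
#' @param method hclust linkage (default "average").
#' @return data.frame with columns `label_set`, `k`, `ari` (NA for
#'   single-level labelings).
#' @export
clustering_concordance <- function(profiles, label_sets, n_genes = NULL,
                                   method = "average") {
  profiles <- as.matrix(profiles)
  if (!is.null(n_genes) && n_genes < ncol(profiles)) {
    v <- apply(profiles, 2, stats::var)
    profiles <- profiles[, order(v, decreasing = TRUE)[seq_len(n_genes)],
                         drop = FALSE]
  }
  d <- stats::as.dist(1 - suppressWarnings(stats::cor(t(profiles))))
  d[is.na(d)] <- 2
  hc <- stats::hclust(d, method = method)
  out <- lapply(names(label_sets), function(nm) {
    lab <- as.character(label_sets[[nm]])
    k <- length(unique(lab))
    ari <- if (k < 2) NA_real_ else
      mclust::adjustedRandIndex(stats::cutree(hc, k = k), lab)
    data.frame(label_set = nm, k = k, ari = ari, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
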
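#' Correlate identity scores with developmental age
#'
#' For each cell type observed in at least 4 samples with distinct ages,
#' correlates every gene's identity score across samples with developmental
#' age (days post-conception, min-max scaled to \[0, 1\]). Two-sided p-values
#' come from the t distribution with n - 2 degrees of freedom and are
#' BH-adjusted (within cell type by default). Categories follow FDR
#' thresholds: `highly_significant` (< 0.01), `significant` (0.01 to 0.05),
#' `insignificant` (> 0.05). Genes with constant score are excluded from the
#' adjustment (r reported as NA).
#'
#' @param sample_scores list of `list(scores = , age_dpc = )`, one entry per
#'   (dataset, batch) sample; `scores` an [identity_scores()] or matrix.
#' @param method `"pearson"` or `"spearman"`.
#' @param fdr_scope `"cell_type"` (BH within each type) or `"global"`.
#' @return A `maturation_table` data.frame: gene, cell_type, r, p_value, fdr,
#'   category, direction.
#' @export
age_association <- function(sample_scores, method = c("pearson", "spearman"),
                            fdr_scope = c("cell_type", "global")) {
  method <- match.arg(method)
  fdr_scope <- match.arg(fdr_scope)
  mats <- lapply(sample_scores, function(s) .score_matrix(s$scores))
  ages <- vapply(sample_scores, function(s) as.numeric(s$age_dpc), numeric(1))
  if (anyNA(ages)) stop("every sample needs an age_dpc")
  rng <- range(ages)
  age_scaled <- if (diff(rng) > 0) (ages - rng[1]) / diff(rng) else
    stop("ages are all identical")
  genes <- Reduce(intersect, lapply(mats, rownames))
  types <- sort(unique(unlist(lapply(mats, colnames))))
  out <- list()
  for (k in types) {
    has <- vapply(mats, function(m) k %in% colnames(m), logical(1))
    n <- sum(has)
    if (n < 4 || length(unique(ages[has])) < 4) {
      warning("cell type '", k, "' has fewer than 4 aged samples; skipped")
      next
    }
    x <- vapply(mats[has], function(m) m[genes, k], numeric(length(genes)))
    a <- age_scaled[has]
    if (method == "spearman") {
      a <- rank(a)
      x <- t(apply(x, 1, rank))
    }
    xc <- x - rowMeans(x)
    ac <- a - mean(a)
    denom <- sqrt(rowSums(xc^2) * sum(ac^2))
    r <- ifelse(denom > 0, rowSums(xc * rep(ac, each = nrow(xc))) / denom,
                NA_real_)
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p[!is.na(r) & abs(r) >= 1] <- 0
    out[[k]] <- data.frame(gene = genes, cell_type = k, r = r, p_value = p,
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no cell type had enough aged samples")
  tab <- do.call(rbind, out)
  tab$fdr <- NA_real_
  ok <- !is.na(tab$p_value)
  if (fdr_scope == "global") {
    tab$fdr[ok] <- stats::p.adjust(tab$p_value[ok], method = "BH")
  } else {
    for (k in unique(tab$cell_type)) {
      i <- ok & tab$cell_type == k
      tab$fdr[i] <- stats::p.adjust(tab$p_value[i], method = "BH")
    }
  }
  tab$category <- ifelse(is.na(tab$fdr), NA_character_,
                         ifelse(tab$fdr < 0.01, "highly_significant",
                                ifelse(tab$fdr <= 0.05, "significant",
                                       "insignificant")))
  tab$direction <- ifelse(is.na(tab$r), NA_character_,
                          ifelse(tab$r >= 0, "positive", "negative"))
  rownames(tab) <- NULL
  class(tab) <- c("maturation_table", "data.frame")
  tab
}

#' Per-cell-type proportions of maturation-significance categories
#'
#' @param t a `maturation_table` from [age_association()].
#' @return data.frame: cell_type, category, proportion (summing to 1 within
#'   each cell type).
#' @export
significance_summary <- function(t) {
  if (!nrow(t)) stop("empty maturation table")
  t <- t[!is.na(t$category), , drop = FALSE]
  cats <- c("highly_significant", "significant", "insignificant")
  out <- lapply(unique(t$cell_type), function(k) {
    sub <- t$category[t$cell_type == k]
    prop <- vapply(cats, function(cc) mean(sub == cc), numeric(1))
    data.frame(cell_type = k, category = cats, proportion = prop,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Overlap of significant maturation genes across cell types
#'
#' Partitions the genes significant at FDR < 0.05 in the given direction by
#' the exact combination of cell types in which they are significant, and
#' counts each combination (an upset-style partition: every gene is counted
#' in exactly one combination).
#'
#' @param t a `maturation_table`.
#' @param direction `"positive"` or `"negative"`.
#' @return data.frame: combination (cell types joined by "+"), n_types,
#'   count, percentage of all significant genes.
#' @export
gene_set_overlap <- function(t, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  sig <- t[!is.na(t$fdr) & t$fdr < 0.05 & t$direction == direction, ,
           drop = FALSE]
  if (!nrow(sig))
    return(data.frame(combination = character(), n_types = integer(),
                      count = integer(), percentage = numeric()))
  combos <- tapply(sig$cell_type, sig$gene, function(ks)
    paste(sort(unique(ks)), collapse = "+"))
  tb <- table(combos)
  out <- data.frame(combination = names(tb),
                    n_types = lengths(strsplit(names(tb), "+", fixed = TRUE)),
                    count = as.integer(tb),
                    percentage = 100 * as.integer(tb) / sum(tb),
                    stringsAsFactors = FALSE)
  out[order(-out$count), , drop = FALSE]
}

#' Similarity of maturation-association profiles between cell types
#'
#' Pearson correlation of the per-gene age-correlation vectors between every
#' pair of cell types, over genes with non-missing r in both. Pairs with
#' fewer than 3 shared genes get `NA`.
#'
#' @param t a `maturation_table`.
#' @return A symmetric cell-type correlation matrix.
#' @export
maturation_profile_similarity <- function(t) {
  types <- sort(unique(t$cell_type))
  genes <- sort(unique(t$gene))
  rmat <- matrix(NA_real_, length(genes), length(types),
                 dimnames = list(genes, types))
  rmat[cbind(match(t$gene, genes), match(t$cell_type, types))] <- t$r
  out <- matrix(NA_real_, length(types), length(types),
                dimnames = list(types, types))
  for (i in seq_along(types)) for (j in seq_len(i)) {
    sh <- !is.na(rmat[, i]) & !is.na(rmat[, j])
    if (sum(sh) >= 3)
      out[i, j] <- out[j, i] <-
        suppressWarnings(stats::cor(rmat[sh, i], rmat[sh, j]))
  }
  out
}
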
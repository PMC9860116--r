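#' Construct an expression matrix
#'
#' Light container for a sparse gene-by-cell expression matrix together with
#' its layer (raw counts or log-normalized values). Gene and cell identifiers
#' must be unique; values must be non-negative, and integral for the counts
#' layer.
#'
#' @param values matrix-like, genes in rows and cells in columns; coerced to
#'   a sparse `dgCMatrix`.
#' @param genes character vector of gene identifiers (length `nrow(values)`).
#' @param cells character vector of cell identifiers (length `ncol(values)`).
#' @param layer `"counts"` or `"lognorm"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (dgCMatrix with dimnames), `genes`, `cells`, `layer`.
#' @export
expression_matrix <- function(values, genes = rownames(values),
                              cells = colnames(values),
                              layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  values <- as(as(as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(genes) || is.null(cells))
    stop("gene and cell identifiers are required")
  genes <- as.character(genes)
  cells <- as.character(cells)
  if (nrow(values) != length(genes) || ncol(values) != length(cells))
    stop("dimension mismatch: matrix is ", nrow(values), "x", ncol(values),
         " but ", length(genes), " genes / ", length(cells),
         " cells were supplied")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (anyDuplicated(cells)) stop("duplicate cell identifiers")
  if (length(values@x) && min(values@x) < 0)
    stop("negative expression values are not allowed")
  if (layer == "counts" && length(values@x) &&
      any(abs(values@x - round(values@x)) > 1e-8))
    stop("counts layer must contain integer values")
  dimnames(values) <- list(genes, cells)
  structure(list(values = values, genes = genes, cells = cells, layer = layer),
            class = "expr_matrix")
}

#' @exportS3Method base::print
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, layer = %s\n",
              length(x$genes), length(x$cells), x$layer))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

.open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.read_id_column <- function(path) {
  con <- .open_maybe_gz(path)
  on.exit(close(con))
  tab <- read.delim(con, header = FALSE, sep = "\t",
                    colClasses = "character", quote = "")
  tab[[1L]]
}

.dedup_suffix <- function(ids) {
  # 10x-style: duplicates get "-1", "-2", ... appended, first occurrence too
  dup <- ids[duplicated(ids)]
  if (!length(dup)) return(ids)
  warning("de-duplicating ", length(unique(dup)),
          " repeated identifiers by suffixing")
  ave_idx <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  is_dup <- ids %in% dup
  ids[is_dup] <- paste0(ids[is_dup], "-", ave_idx[is_dup])
  ids
}

#' Read a sparse count matrix in Matrix-Market / 10x layout
#'
#' Reads a Matrix-Market triplet file plus newline-delimited gene and cell
#' identifier files (plain or gzipped). Identifier files may have one or more
#' tab-separated columns (10x v2 two-column and v3 three-column features files
#' are accepted); the first column is taken as the identifier. Duplicate gene
#' identifiers are de-duplicated by numeric suffixing with a warning.
#'
#' @param matrix_path path to the `.mtx` or `.mtx.gz` file.
#' @param genes_path path to the gene/feature identifier file.
#' @param cells_path path to the cell barcode file.
#' @return An [expression_matrix()] with `layer = "counts"`.
#' @export
read_counts <- function(matrix_path, genes_path, cells_path) {
  con <- .open_maybe_gz(matrix_path)
  on.exit(close(con))
  m <- tryCatch(Matrix::readMM(con),
                error = function(e) stop("format error reading ", matrix_path,
                                         ": ", conditionMessage(e)))
  genes <- .dedup_suffix(.read_id_column(genes_path))
  cells <- .read_id_column(cells_path)
  if (nrow(m) != length(genes))
    stop("format error: matrix header declares ", nrow(m),
         " genes but identifier file has ", length(genes))
  if (ncol(m) != length(cells))
    stop("format error: matrix header declares ", ncol(m),
         " cells but identifier file has ", length(cells))
  if (length(m@x)) {
    if (min(m@x) < 0) stop("format error: negative count entries")
    if (any(abs(m@x - round(m@x)) > 1e-8))
      stop("format error: non-integer count entries")
  }
  expression_matrix(m, genes, cells, layer = "counts")
}

#' Write a count matrix as Matrix-Market plus identifier files
#'
#' Inverse of [read_counts()]: writes `matrix.mtx`, `genes.tsv` and
#' `barcodes.tsv` under `out_dir`.
#'
#' @param m an [expression_matrix()].
#' @param out_dir output directory, created if missing.
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(m, out_dir) {
  stopifnot(inherits(m, "expr_matrix"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  Matrix::writeMM(m$values, paths[1L])
  writeLines(m$genes, paths[2L])
  writeLines(m$cells, paths[3L])
  invisible(paths)
}

#' Library-size normalize and log-transform counts
#'
#' Scales each cell to `scale` total counts and applies `log(1 + x)`. Cells
#' with zero total counts are dropped with a warning.
#'
#' @param m an [expression_matrix()] with `layer = "counts"`.
#' @param scale target library size (default 10,000).
#' @return An [expression_matrix()] with `layer = "lognorm"`.
#' @export
log_normalize <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$layer != "counts")
    stop("log_normalize expects a counts layer, got ", m$layer)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive number")
  totals <- Matrix::colSums(m$values)
  keep <- totals > 0
  if (!all(keep))
    warning("dropping ", sum(!keep), " cell(s) with zero total counts")
  if (!any(keep)) stop("no cells remain after dropping zero-count cells")
  v <- m$values[, keep, drop = FALSE]
  v <- v %*% Matrix::Diagonal(x = scale / totals[keep])
  v <- as(log1p(v), "CsparseMatrix")
  expression_matrix(v, m$genes, m$cells[keep], layer = "lognorm")
}

#' Validate a per-cell annotation table
#'
#' Required columns: `cell_id`, `cell_type`, `dataset`, `batch`, `source`
#' (one of `tissue_mature`, `tissue_fetal`, `organoid`); optional `protocol`
#' and `age_dpc` (days post-conception). Fetal tissue cells must carry an age.
#'
#' @param df a data.frame of per-cell annotations.
#' @return The validated data.frame (class `cell_annotation` prepended).
#' @export
cell_annotation <- function(df) {
  req <- c("cell_id", "cell_type", "dataset", "batch", "source")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id in annotation")
  ok_src <- c("tissue_mature", "tissue_fetal", "organoid")
  bad <- setdiff(unique(df$source), ok_src)
  if (length(bad))
    stop("unknown source value(s): ", paste(bad, collapse = ", "))
  if (!"protocol" %in% names(df)) df$protocol <- NA_character_
  if (!"age_dpc" %in% names(df)) df$age_dpc <- NA_real_
  fet <- df$source == "tissue_fetal"
  if (any(fet & is.na(df$age_dpc)))
    stop("tissue_fetal cells must have age_dpc")
  if (any(!is.na(df$age_dpc) & df$age_dpc <= 0))
    stop("age_dpc must be positive")
  class(df) <- unique(c("cell_annotation", class(df)))
  df
}

#' Canonical retinal cell-type vocabulary
#'
#' The canonical set covers the major retinal neuron and glial classes:
#' retinal ganglion cells (RGC), amacrine, bipolar and horizontal
#' interneurons, Muller glia, and rod and cone photoreceptors. The synonym
#' map translates common raw labels (case-insensitive) to canonical names.
#'
#' @param canonical character vector of canonical type names.
#' @param synonyms named character vector mapping lower-cased raw labels to
#'   canonical names; merged over the built-in defaults.
#' @return A list with elements `canonical` and `synonyms`.
#' @export
cell_type_vocabulary <- function(canonical = c("RGC", "amacrine", "bipolar",
                                               "horizontal", "muller_glia",
                                               "rod", "cone"),
                                 synonyms = character()) {
  base <- c(
    "rgc" = "RGC", "retinal ganglion cell" = "RGC", "ganglion" = "RGC",
    "ganglion cell" = "RGC", "retinal ganglion cells" = "RGC",
    "amacrine" = "amacrine", "amacrine cell" = "amacrine", "ac" = "amacrine",
    "amacrine cells" = "amacrine",
    "bipolar" = "bipolar", "bipolar cell" = "bipolar", "bc" = "bipolar",
    "bipolar cells" = "bipolar",
    "horizontal" = "horizontal", "horizontal cell" = "horizontal",
    "hc" = "horizontal", "horizontal cells" = "horizontal",
    "mg" = "muller_glia", "muller glia" = "muller_glia",
    "muller glial" = "muller_glia", "mueller glia" = "muller_glia",
    "müller glia" = "muller_glia", "muller_glia" = "muller_glia",
    "muller" = "muller_glia",
    "rod" = "rod", "rods" = "rod", "rod photoreceptor" = "rod",
    "cone" = "cone", "cones" = "cone", "cone photoreceptor" = "cone"
  )
  syn <- c(base[!names(base) %in% tolower(names(synonyms))],
           stats::setNames(as.character(synonyms), tolower(names(synonyms))))
  # canonical labels always map to themselves
  syn <- c(syn, stats::setNames(canonical, tolower(canonical)))
  syn <- syn[!duplicated(names(syn), fromLast = TRUE)]
  list(canonical = canonical, synonyms = syn)
}

#' Harmonize raw cell-type labels to the canonical vocabulary
#'
#' Looks raw labels up in the vocabulary's synonym map (case-insensitive,
#' whitespace-trimmed). Unmapped labels raise an error when `strict = TRUE`,
#' otherwise they are mapped to `"other"`.
#'
#' @param ann a [cell_annotation()] table.
#' @param vocab a [cell_type_vocabulary()].
#' @param strict raise on unmapped labels?
#' @return The annotation with `cell_type` replaced by canonical names.
#' @export
harmonize_cell_types <- function(ann, vocab = cell_type_vocabulary(),
                                 strict = FALSE) {
  raw <- trimws(as.character(ann$cell_type))
  key <- tolower(raw)
  mapped <- unname(vocab$synonyms[key])
  unmapped <- is.na(mapped) & key != "other"
  if (any(unmapped)) {
    offenders <- sort(unique(raw[unmapped]))
    if (strict)
      stop("unmapped cell-type label(s): ", paste(offenders, collapse = ", "))
    message("mapping unmatched label(s) to 'other': ",
            paste(offenders, collapse = ", "))
  }
  mapped[is.na(mapped)] <- "other"
  ann$cell_type <- mapped
  ann
}

#' Write a fidelity report to disk
#'
#' Writes a per-metric table (`metrics.csv`), the combined ranking
#' (`ranking.csv`) and a machine-readable JSON (`report.json`) holding all
#' raw and scaled values plus the configuration used.
#'
#' @param report a `fidelity_report` from [benchmark()].
#' @param out_dir output directory, created if missing.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  if (!inherits(report, "fidelity_report") || !nrow(report$table))
    stop("nothing to write: empty or invalid report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- report$table
  metrics_path <- file.path(out_dir, "metrics.csv")
  ranking_path <- file.path(out_dir, "ranking.csv")
  json_path <- file.path(out_dir, "report.json")
  utils::write.csv(tab, metrics_path, row.names = FALSE)
  rk <- tab[order(tab$rank),
            c("protocol", "dataset", "batch", "combined", "rank")]
  utils::write.csv(rk, ranking_path, row.names = FALSE)
  payload <- list(table = tab, per_type_ci = report$per_type_ci,
                  config = report$config)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(c(metrics_path, ranking_path, json_path))
}

#' Read a fidelity report back from its JSON serialization
#'
#' @param path path to a `report.json` written by [write_report()].
#' @return A `fidelity_report`.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(table = as.data.frame(payload$table),
                 per_type_ci = payload$per_type_ci,
                 config = payload$config),
            class = "fidelity_report")
}
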
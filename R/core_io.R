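#' @importFrom stats var sd cor coef lm model.matrix optim pchisq p.adjust
#'   predict quantile rbinom rnbinom rnorm runif setNames dist cutree hclust
#'   dnorm pnorm vcov qt complete.cases
#' @importFrom utils read.csv write.csv read.delim head
NULL

VALID_UNITS <- c("counts", "TPM", "CPM", "log10cpm1")

hd_log <- function(stage, ...) {
  if (isTRUE(getOption("haemodyn.verbose", FALSE)))
    message(sprintf("[%s] %s", stage, paste0(...)))
  invisible(NULL)
}

#' Cells-by-genes expression matrix with a declared unit
#'
#' The central container of the package: a numeric matrix with cells as rows
#' and genes as columns, together with the unit of its entries. All analysis
#' stages consume and return this type; no stage reads files directly.
#'
#' @param values numeric matrix, cells in rows, genes in columns.
#' @param unit one of `"counts"`, `"TPM"`, `"CPM"`, `"log10cpm1"`.
#' @param cell_ids,gene_ids character vectors of unique identifiers; default
#'   to the dimnames of `values`.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values` (dimnamed matrix) and `unit`.
#' @export
ExpressionMatrix <- function(values, unit,
                             cell_ids = rownames(values),
                             gene_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  unit <- match.arg(unit, VALID_UNITS)
  if (is.null(cell_ids) && nrow(values) == 0) cell_ids <- character(0)
  if (is.null(gene_ids) && ncol(values) == 0) gene_ids <- character(0)
  if (is.null(cell_ids) || is.null(gene_ids))
    stop("cell_ids and gene_ids must be supplied (or present as dimnames)")
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("length of cell_ids does not match number of rows")
  if (length(gene_ids) != ncol(values))
    stop("length of gene_ids does not match number of columns")
  dup <- cell_ids[duplicated(cell_ids)]
  if (length(dup)) stop("duplicate cell id(s): ", paste(unique(dup), collapse = ", "))
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(values)) stop("expression values contain NA")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative value at cell '%s', gene '%s'",
                 cell_ids[neg[1, 1]], gene_ids[neg[1, 2]]))
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, unit = unit), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Accessors for ExpressionMatrix identifiers
#' @param x an `ExpressionMatrix`.
#' @return character vector of identifiers.
#' @export
cell_ids <- function(x) rownames(x$values)

#' @rdname cell_ids
#' @export
gene_ids <- function(x) colnames(x$values)

#' Subset an ExpressionMatrix by cells and/or genes
#' @param x an `ExpressionMatrix`.
#' @param cells,genes identifiers or indices to keep; `NULL` keeps all.
#' @return an `ExpressionMatrix` with the same unit.
#' @export
em_subset <- function(x, cells = NULL, genes = NULL) {
  v <- x$values
  if (!is.null(cells)) v <- v[cells, , drop = FALSE]
  if (!is.null(genes)) v <- v[, genes, drop = FALSE]
  ExpressionMatrix(v, x$unit)
}

mtx_sidecars <- function(path) {
  base <- sub("\\.mtx$", "", path)
  list(rows = paste0(base, ".rowids.txt"), cols = paste0(base, ".colids.txt"))
}

#' Read an expression matrix from disk
#'
#' TSV files hold genes as rows and cells as columns (first column = gene id,
#' header = cell ids), the common on-disk convention; MatrixMarket files are
#' genes x cells with `<base>.rowids.txt` (gene ids) and `<base>.colids.txt`
#' (cell ids) sidecar files. Both are transposed to cells x genes on load.
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx"`.
#' @param unit declared unit of the stored values.
#' @return an `ExpressionMatrix`.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"), unit = "counts") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    g <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    ExpressionMatrix(t(m), unit, cell_ids = colnames(tab)[-1], gene_ids = g)
  } else {
    side <- mtx_sidecars(path)
    if (!file.exists(side$rows)) stop("missing row id file: ", side$rows)
    if (!file.exists(side$cols)) stop("missing column id file: ", side$cols)
    m <- as.matrix(Matrix::readMM(path))
    ExpressionMatrix(t(m), unit,
                     cell_ids = readLines(side$cols),
                     gene_ids = readLines(side$rows))
  }
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_counts()]: the matrix is stored genes x cells.
#'
#' @param m an `ExpressionMatrix`.
#' @param path destination path.
#' @param format `"tsv"` or `"mtx"`.
#' @return the path, invisibly.
#' @export
write_counts <- function(m, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "ExpressionMatrix"))
  gm <- t(m$values)
  if (format == "tsv") {
    tab <- data.frame(gene_id = rownames(gm), gm, check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    side <- mtx_sidecars(path)
    Matrix::writeMM(Matrix::Matrix(gm, sparse = TRUE), path)
    writeLines(rownames(gm), side$rows)
    writeLines(colnames(gm), side$cols)
  }
  invisible(path)
}

#' Read per-cell metadata
#'
#' Expects a CSV with header; `cell_id` is mandatory. Optional columns:
#' `branch_label`, `pseudotime`, `line`, `qc_pass` (defaults `TRUE`),
#' `class_label`. Every cell assigned to a branch must carry a pseudotime.
#'
#' @param path CSV path.
#' @return a data.frame of class `CellMetadata`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_cell_metadata(df)
}

#' Construct/validate cell metadata from a data.frame
#' @param df data.frame with at least a `cell_id` column.
#' @return a data.frame of class `CellMetadata`.
#' @export
as_cell_metadata <- function(df) {
  if (!"cell_id" %in% names(df)) stop("metadata must contain a 'cell_id' column")
  dup <- df$cell_id[duplicated(df$cell_id)]
  if (length(dup)) stop("duplicate cell id(s) in metadata: ",
                        paste(unique(dup), collapse = ", "))
  if (!"qc_pass" %in% names(df)) df$qc_pass <- TRUE
  df$qc_pass <- as.logical(df$qc_pass)
  if ("branch_label" %in% names(df) && "pseudotime" %in% names(df)) {
    bad <- !is.na(df$branch_label) & is.na(df$pseudotime)
    if (any(bad)) stop("pseudotime missing for branch-assigned cell(s): ",
                       paste(head(df$cell_id[bad], 5), collapse = ", "))
  }
  class(df) <- c("CellMetadata", "data.frame")
  df
}

#' Read per-gene annotation
#'
#' Expects a CSV with `gene_id` and `biotype` columns. Optional: `is_spikein`,
#' `is_mito` (default `FALSE`), `ribo_class` in none/cytosolic/mitochondrial
#' (default `"none"`). Spike-ins may not be protein_coding and always carry
#' `ribo_class = "none"`.
#'
#' @param path CSV path.
#' @return a data.frame of class `GeneAnnotation`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as_gene_annotation(read.csv(path, stringsAsFactors = FALSE))
}

#' Construct/validate gene annotation from a data.frame
#' @param df data.frame with `gene_id` and `biotype` columns.
#' @return a data.frame of class `GeneAnnotation`.
#' @export
as_gene_annotation <- function(df) {
  for (col in c("gene_id", "biotype"))
    if (!col %in% names(df)) stop("annotation must contain a '", col, "' column")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) stop("duplicate gene id(s) in annotation: ",
                        paste(unique(dup), collapse = ", "))
  if (!"is_spikein" %in% names(df)) df$is_spikein <- FALSE
  if (!"is_mito" %in% names(df)) df$is_mito <- FALSE
  if (!"ribo_class" %in% names(df)) df$ribo_class <- "none"
  df$is_spikein <- as.logical(df$is_spikein)
  df$is_mito <- as.logical(df$is_mito)
  bad <- setdiff(unique(df$ribo_class), c("none", "cytosolic", "mitochondrial"))
  if (length(bad)) stop("invalid ribo_class value(s): ", paste(bad, collapse = ", "))
  if (any(df$is_spikein & df$biotype == "protein_coding"))
    stop("spike-in genes must not be protein_coding")
  if (any(df$is_spikein & df$ribo_class != "none"))
    stop("spike-in genes must have ribo_class 'none'")
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

#' Write a metadata/annotation/report table as CSV
#' @param obj a data.frame-like object.
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
write_table <- function(obj, path) {
  write.csv(as.data.frame(obj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis configuration with the thresholds used downstream
#'
#' Central place for every tunable threshold. Defaults follow the published
#' workflow: cells need at least 1000 expressed genes (TPM > 1) and at most
#' 60\% spike-in and mitochondrial content, with an erythroid rescue for
#' cells expressing ba1 above 40,000 TPM and hbaa1 above 9000 TPM; genes must
#' reach CPM > 1 in at least 1\% of cells; differential/dynamic genes need
#' P < 0.01, BH q < 0.1 and expression in more than 50\% of the tested
#' cells; the stemness call threshold is 0.05; branch-level expression uses
#' the more-than-10\%-of-cells rule.
#'
#' @param ... named overrides of the defaults listed above.
#' @return a list of class `AnalysisConfig`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    min_expressed_genes = 1000,
    max_ercc_frac = 0.60,
    max_mito_frac = 0.60,
    ba1_tpm = 40000,
    hbaa1_tpm = 9000,
    rescue_genes = c("ba1", "hbaa1"),
    gene_filter_frac = 0.01,
    hvg_bio_cv2 = 0.25,
    hvg_fdr = 0.1,
    de_p = 0.01,
    de_fdr = 0.1,
    de_expr_frac = 0.5,
    dyn_expr_frac = 0.5,
    censor_threshold = 0,
    spline_df = 3,
    stemness_tau = 0.05,
    stemness_mode = "fixed",
    branch_expr_frac = 0.10,
    ribo_high_frac = 0.5,
    nonde_floor = 0.10,
    de_score_floor = NULL,
    dyn_genes_max = 300,
    rng_seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  fracs <- c("max_ercc_frac", "max_mito_frac", "gene_filter_frac", "de_expr_frac",
             "dyn_expr_frac", "branch_expr_frac", "ribo_high_frac", "de_fdr",
             "hvg_fdr", "de_p")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  for (f in c("min_expressed_genes", "ba1_tpm", "hbaa1_tpm", "stemness_tau",
              "nonde_floor", "hvg_bio_cv2"))
    if (cfg[[f]] < 0) stop(f, " must be non-negative")
  class(cfg) <- c("AnalysisConfig", "list")
  cfg
}
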
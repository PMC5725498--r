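#' Per-cell quality-control metrics
#'
#' Computes, per cell: the number of expressed genes (TPM > 1, spike-ins
#' excluded from the count), the fraction of total TPM coming from spike-ins
#' and the fraction coming from mitochondrially encoded genes (both over the
#' full TPM sum including spike-ins). Cells with zero total signal get both
#' fractions defined as 0 and are flagged degenerate.
#'
#' @param m an `ExpressionMatrix` with unit TPM.
#' @param ann a `GeneAnnotation` covering all genes of `m`.
#' @return a data.frame of class `QCReport` with columns `cell_id`,
#'   `n_expressed_genes`, `ercc_frac`, `mito_frac`, `degenerate`.
#' @export
compute_qc_metrics <- function(m, ann) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "TPM") stop("QC metrics require unit 'TPM', got '", m$unit, "'")
  ann <- as_gene_annotation(as.data.frame(ann))
  missing <- setdiff(gene_ids(m), ann$gene_id)
  if (length(missing))
    stop("annotation missing gene(s): ", paste(head(missing, 5), collapse = ", "))
  idx <- match(gene_ids(m), ann$gene_id)
  spike <- ann$is_spikein[idx]
  mito <- ann$is_mito[idx]
  v <- m$values
  total <- rowSums(v)
  n_expr <- rowSums(v[, !spike, drop = FALSE] > 1)
  ercc <- ifelse(total > 0, rowSums(v[, spike, drop = FALSE]) / total, 0)
  mitof <- ifelse(total > 0, rowSums(v[, mito, drop = FALSE]) / total, 0)
  rep <- data.frame(cell_id = cell_ids(m), n_expressed_genes = n_expr,
                    ercc_frac = ercc, mito_frac = mitof,
                    degenerate = total == 0, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(rep) <- c("QCReport", "data.frame")
  rep
}

#' Apply quality-control thresholds with the erythroid globin rescue
#'
#' A cell fails when it has fewer than `min_expressed_genes` expressed genes,
#' or more than `max_ercc_frac` spike-in content, or more than
#' `max_mito_frac` mitochondrial content (all strict comparisons, so a cell
#' sitting exactly at a threshold passes). A failing cell is rescued when it
#' expresses both globins above their thresholds (ba1 > 40,000 TPM and
#' hbaa1 > 9000 TPM by default, strict), reflecting that erythroid cells
#' legitimately express few genes. If the rescue genes are absent from the
#' matrix the rescue is disabled with a warning.
#'
#' @param m the TPM `ExpressionMatrix` the metrics were computed on.
#' @param ann a `GeneAnnotation`.
#' @param report a `QCReport` from [compute_qc_metrics()].
#' @param cfg an `AnalysisConfig`.
#' @return list with `matrix` (the TPM matrix restricted to passing cells)
#'   and `report` (the `QCReport` extended with `globin_rescue`, `qc_pass`,
#'   `failure_reasons`).
#' @export
apply_qc <- function(m, ann, report, cfg = analysis_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(report, "QCReport"))
  if (!identical(report$cell_id, cell_ids(m)))
    stop("report and matrix cells do not match")
  g <- cfg$rescue_genes
  have_rescue <- all(g %in% gene_ids(m))
  if (!have_rescue) {
    warning("rescue gene(s) ", paste(setdiff(g, gene_ids(m)), collapse = ", "),
            " absent; globin rescue disabled")
    rescue <- rep(FALSE, nrow(report))
  } else {
    rescue <- m$values[, g[1]] > cfg$ba1_tpm & m$values[, g[2]] > cfg$hbaa1_tpm
  }
  reasons <- character(nrow(report))
  add_reason <- function(reasons, hit, tag)
    ifelse(hit, ifelse(reasons == "", tag, paste(reasons, tag, sep = ";")),
           reasons)
  reasons <- add_reason(reasons, report$n_expressed_genes < cfg$min_expressed_genes,
                        "min_genes")
  reasons <- add_reason(reasons, report$ercc_frac > cfg$max_ercc_frac, "ercc")
  reasons <- add_reason(reasons, report$mito_frac > cfg$max_mito_frac, "mito")
  pass <- reasons == "" | rescue
  report$globin_rescue <- rescue
  report$qc_pass <- pass
  report$failure_reasons <- reasons
  hd_log("qc", sprintf("%d/%d cells pass (%d rescued)", sum(pass),
                       length(pass), sum(rescue & reasons != "")))
  list(matrix = em_subset(m, cells = which(pass)), report = report)
}

#' Counts-per-million normalisation
#'
#' Divides each cell's counts by its total and multiplies by one million,
#' so every row of the result sums to 1e6.
#'
#' @param m an `ExpressionMatrix` with unit counts.
#' @param size_factors optional per-cell size factors replacing the raw
#'   totals (hook for externally computed factors, e.g. deconvolution-based
#'   ones); must be positive and named or ordered by cell.
#' @return an `ExpressionMatrix` with unit CPM.
#' @export
cpm_normalize <- function(m, size_factors = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "counts") stop("expected unit 'counts', got '", m$unit, "'")
  tot <- rowSums(m$values)
  zero <- which(tot == 0)
  if (length(zero))
    stop("cell(s) with zero total count: ",
         paste(head(cell_ids(m)[zero], 5), collapse = ", "))
  if (is.null(size_factors)) {
    v <- m$values / tot * 1e6
  } else {
    if (any(size_factors <= 0)) stop("size factors must be positive")
    sf <- size_factors / mean(size_factors)
    v <- m$values / (tot * sf) * 1e6
  }
  ExpressionMatrix(v, "CPM")
}

#' Minimum-expression gene filter
#'
#' Retains genes with CPM > 1 in at least `ceiling(gene_filter_frac *
#' n_cells)` cells ("at least 1\% of all cells", rounded up). Spike-ins are
#' exempt when an annotation is supplied, since the technical-noise fit
#' needs them regardless of their prevalence.
#'
#' @param m an `ExpressionMatrix` with unit CPM.
#' @param cfg an `AnalysisConfig`.
#' @param ann optional `GeneAnnotation`; if given, spike-ins are kept.
#' @return the filtered `ExpressionMatrix`.
#' @export
filter_genes <- function(m, cfg = analysis_config(), ann = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "CPM") stop("expected unit 'CPM', got '", m$unit, "'")
  need <- ceiling(cfg$gene_filter_frac * nrow(m$values))
  n_expr <- colSums(m$values > 1)
  keep <- n_expr >= need
  if (!is.null(ann)) {
    ann <- as.data.frame(ann)
    keep <- keep | gene_ids(m) %in% ann$gene_id[ann$is_spikein]
  }
  hd_log("filter_genes", sprintf("%d/%d genes retained (need CPM>1 in >=%d cells)",
                                 sum(keep), length(keep), need))
  em_subset(m, genes = which(keep))
}

#' Log10(CPM+1) transform
#' @param m an `ExpressionMatrix` with unit CPM.
#' @return an `ExpressionMatrix` with unit log10cpm1.
#' @export
log10_cpm1 <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "CPM") stop("expected unit 'CPM', got '", m$unit, "'")
  ExpressionMatrix(log10(m$values + 1), "log10cpm1")
}
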
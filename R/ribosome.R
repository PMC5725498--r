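#' Average log-expression profiles per cell type
#'
#' Per cell type, the mean of log10(CPM+1) for each gene. A CPM-unit matrix
#' is transformed first; a log10cpm1 matrix is used as-is.
#'
#' @param m `ExpressionMatrix` with unit CPM or log10cpm1.
#' @param groups factor of cell-type labels, one per cell; every group must
#'   be non-empty.
#' @return numeric matrix, cell types x genes.
#' @export
celltype_average_profiles <- function(m, groups) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- switch(m$unit,
              CPM = log10(m$values + 1),
              log10cpm1 = m$values,
              stop("expected unit 'CPM' or 'log10cpm1', got '", m$unit, "'"))
  groups <- as.factor(groups)
  if (length(groups) != nrow(v)) stop("one group per cell required")
  if (any(table(groups) == 0)) stop("empty group")
  out <- t(vapply(levels(groups),
                  function(gl) colMeans(v[groups == gl, , drop = FALSE]),
                  numeric(ncol(v))))
  rownames(out) <- levels(groups)
  out
}

#' Coefficient of variation of a profile
#'
#' Sample standard deviation (n-1 divisor) divided by the mean. Returns NA
#' with a warning when the mean is not positive.
#'
#' @param x numeric vector (e.g. one gene's average expression across cell
#'   types).
#' @return scalar CV.
#' @export
cv_score <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || m <= 0) {
    warning("CV undefined for non-positive mean")
    return(NA_real_)
  }
  sd(x) / m
}

#' Per-gene CV across cell-type average profiles
#' @param profiles cell types x genes matrix from
#'   [celltype_average_profiles()].
#' @return named numeric vector of CVs (one per gene).
#' @export
profile_cv <- function(profiles) {
  apply(profiles, 2, function(x) {
    m <- mean(x)
    if (!is.finite(m) || m <= 0) NA_real_ else sd(x) / m
  })
}

#' Partition ribosomal genes into high/low expression tiers
#'
#' A ribosomal gene is tiered "high" when it is expressed (CPM > 1) in at
#' least `ribo_high_frac` of cells (default 50\%, boundary inclusive),
#' "low" otherwise. The tier-by-annotated-class cross-tabulation shows how
#' the expression split recovers the cytosolic versus mitochondrial
#' ribosomal programmes.
#'
#' @param m `ExpressionMatrix` with unit CPM.
#' @param ann a `GeneAnnotation` with `ribo_class`.
#' @param cfg an `AnalysisConfig` (field `ribo_high_frac`).
#' @return list of class `RiboSummary` pieces: `tiers` (data.frame gene_id,
#'   ribo_class, expressed_frac, tier) and `crosstab` (tier x ribo_class).
#' @export
partition_ribo_by_expression <- function(m, ann, cfg = analysis_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "CPM") stop("expected unit 'CPM', got '", m$unit, "'")
  ann <- as.data.frame(ann)
  ribo <- ann[ann$ribo_class != "none", c("gene_id", "ribo_class")]
  ribo <- ribo[ribo$gene_id %in% gene_ids(m), , drop = FALSE]
  if (nrow(ribo) == 0) stop("no ribosomal genes present in the matrix")
  frac <- colMeans(m$values[, ribo$gene_id, drop = FALSE] > 1)
  tiers <- data.frame(ribo, expressed_frac = unname(frac),
                      tier = ifelse(frac >= cfg$ribo_high_frac, "high", "low"),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(tiers = tiers,
       crosstab = table(tier = tiers$tier, ribo_class = tiers$ribo_class))
}

#' Pairwise Pearson correlations between cell-type average profiles
#'
#' Correlates each pair of cell types over the supplied genes (typically
#' the cytosolic ribosomal set). A zero-variance profile yields NA entries
#' with a warning; the diagonal is 1.
#'
#' @param profiles cell types x genes matrix, at least 3 genes.
#' @return symmetric correlation matrix (cell types x cell types).
#' @export
pairwise_profile_correlations <- function(profiles) {
  if (ncol(profiles) < 3) stop("need at least 3 genes")
  sds <- apply(profiles, 1, sd)
  if (any(sds == 0)) warning("zero-variance profile(s): ",
                             paste(rownames(profiles)[sds == 0], collapse = ", "))
  cc <- suppressWarnings(cor(t(profiles)))
  diag(cc) <- 1
  cc
}
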
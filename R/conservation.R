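#' Duplication-epoch taxon sets
#'
#' Taxa labelling a gene-duplication node as predating the ray-finned /
#' lobe-finned fish split (`PRE_TAXA`: ancestors shared with mammals) or
#' postdating it (`POST_TAXA`: ray-finned lineages down to zebrafish).
#'
#' @format character vectors.
#' @export
PRE_TAXA <- c("Euteleostomi", "Bilateria", "Chordata", "Vertebrata",
              "Opisthokonta")

#' @rdname PRE_TAXA
#' @export
POST_TAXA <- c("Neopterygii", "Otophysa", "Clupeocephala", "Danio rerio")

#' Branch-level expression indicator matrix
#'
#' A gene counts as expressed in a branch when it has CPM > 1 in more than
#' `branch_expr_frac` of that branch's cells (default 10\%, strict).
#'
#' @param m `ExpressionMatrix` with unit CPM.
#' @param groups factor of branch labels, one per cell.
#' @param cfg an `AnalysisConfig`.
#' @return logical matrix, genes x branches.
#' @export
branch_expression_matrix <- function(m, groups, cfg = analysis_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "CPM") stop("expected unit 'CPM', got '", m$unit, "'")
  groups <- droplevels(as.factor(groups))
  if (length(groups) != nrow(m$values)) stop("one group per cell required")
  out <- vapply(levels(groups), function(gl)
    colMeans(m$values[groups == gl, , drop = FALSE] > 1) > cfg$branch_expr_frac,
    logical(ncol(m$values)))
  rownames(out) <- gene_ids(m)
  out
}

#' Derive cell-type-specific and background gene sets
#'
#' The cell-type set for each group comprises the significant genes (from a
#' state-wise differential-expression result) that are protein-coding,
#' expressed (CPM > 1) in more than 50\% of the group's cells (strict), and
#' whose mean log10(CPM+1) within the group exceeds a score floor. The
#' floor defaults to the global mean of the per-gene average log10(CPM+1)
#' over all candidate (protein-coding, expressed) genes; set
#' `cfg$de_score_floor` to override. The non-DE background set comprises
#' protein-coding genes expressed in more than 1\% of all cells whose
#' global average log10(CPM+1) exceeds `cfg$nonde_floor` (default 0.10)
#' and that are not significant. Spike-ins can never enter any set.
#'
#' @param m `ExpressionMatrix` with unit CPM (QC-passed cells).
#' @param groups factor of cell-type labels, one per cell.
#' @param ann a `GeneAnnotation`.
#' @param de a `DynTestResult` from [de_test_states()] on the same genes.
#' @param cfg an `AnalysisConfig`.
#' @return list of class `CellTypeGeneSets`: `sets` (named list of gene id
#'   vectors per cell type), `non_de` (character vector), `score_floor`.
#' @export
derive_celltype_sets <- function(m, groups, ann, de, cfg = analysis_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(de, "DynTestResult"))
  if (m$unit != "CPM") stop("expected unit 'CPM', got '", m$unit, "'")
  groups <- droplevels(as.factor(groups))
  ann <- as.data.frame(ann)
  known <- c("protein_coding", "spike_in", "lincRNA", "pseudogene", "miRNA")
  odd <- setdiff(unique(ann$biotype), known)
  if (length(odd)) warning("unknown biotype value(s): ",
                           paste(odd, collapse = ", "))
  ids <- gene_ids(m)
  pc <- ids %in% ann$gene_id[ann$biotype == "protein_coding"]
  logv <- log10(m$values + 1)
  global_mean <- colMeans(logv)
  expressed_any <- colMeans(m$values > 1) >=
    ceiling(cfg$gene_filter_frac * nrow(m$values)) / nrow(m$values)
  candidates <- pc & expressed_any
  floor_val <- if (is.null(cfg$de_score_floor)) mean(global_mean[candidates])
               else cfg$de_score_floor
  sig <- ids %in% de$gene_id[de$significant]
  sets <- lapply(levels(groups), function(gl) {
    in_grp <- groups == gl
    expr_frac <- colMeans(m$values[in_grp, , drop = FALSE] > 1)
    grp_mean <- colMeans(logv[in_grp, , drop = FALSE])
    ids[sig & pc & expr_frac > 0.5 & grp_mean > floor_val]
  })
  names(sets) <- levels(groups)
  non_de <- ids[candidates & global_mean > cfg$nonde_floor & !sig]
  structure(list(sets = sets, non_de = non_de, score_floor = floor_val),
            class = c("CellTypeGeneSets", "list"))
}

#' Ortholog conservation percentage of a gene set
#'
#' Percentage of the set's genes with an ortholog present in every named
#' species (so `species = c("human", "mouse")` asks for an ortholog in
#' human and mouse).
#'
#' @param gene_set non-empty character vector of gene ids.
#' @param ortholog_table data.frame with `gene_id` and one logical column
#'   per species.
#' @param species species column name(s).
#' @return percentage in [0, 100].
#' @export
ortholog_conservation <- function(gene_set, ortholog_table, species) {
  if (length(gene_set) == 0) stop("gene set is empty")
  missing_sp <- setdiff(species, names(ortholog_table))
  if (length(missing_sp)) stop("species not in table: ",
                               paste(missing_sp, collapse = ", "))
  idx <- match(gene_set, ortholog_table$gene_id)
  pres <- vapply(seq_along(gene_set), function(i) {
    if (is.na(idx[i])) return(FALSE)
    all(vapply(species, function(s) isTRUE(ortholog_table[[s]][idx[i]]),
               logical(1)))
  }, logical(1))
  100 * sum(pres) / length(gene_set)
}

#' Split paralogs into exclusively pre- and post-speciation groups
#'
#' A gene belongs to the pre group when any of its duplication nodes is
#' labelled with a pre-speciation taxon, and to the post group when any is
#' labelled with a post-speciation taxon; genes found in both groups are
#' removed from both. Classification uses the `gene_id` column (the focal
#' gene of each duplication record).
#'
#' @param paralog_table data.frame with columns `gene_id`, `paralog_id`,
#'   `duplication_taxon`.
#' @return list with disjoint character vectors `pre_only`, `post_only`,
#'   and `removed` (genes duplicated in both epochs).
#' @export
split_paralog_groups <- function(paralog_table) {
  taxa <- unique(paralog_table$duplication_taxon)
  bad <- setdiff(taxa, c(PRE_TAXA, POST_TAXA))
  if (length(bad)) stop("unknown duplication taxon: ",
                        paste(bad, collapse = ", "))
  if (any(paralog_table$gene_id == paralog_table$paralog_id))
    stop("self-paralogy records are not allowed")
  pre <- unique(paralog_table$gene_id[
    paralog_table$duplication_taxon %in% PRE_TAXA])
  post <- unique(paralog_table$gene_id[
    paralog_table$duplication_taxon %in% POST_TAXA])
  both <- intersect(pre, post)
  out <- list(pre_only = sort(setdiff(pre, both)),
              post_only = sort(setdiff(post, both)),
              removed = sort(both))
  stopifnot(length(intersect(out$pre_only, out$post_only)) == 0)
  out
}

#' Classify expression conservation versus divergence of duplicated genes
#'
#' For each focal gene, the paralog partners are looked up in the paralog
#' table (both record orientations). A partner is "expressed" when it has a
#' non-empty branch set in `branch_expression`. The focal gene's expression
#' pattern is conserved when every expressed partner is expressed in
#' exactly the same cell type(s); it is diverged when at least one
#' expressed partner's branch set differs (any asymmetry, including a gene
#' expressed in several branches whose partner covers only some of them);
#' it is unclassifiable when no partner passes the expression rule or the
#' gene has no paralog records (the latter with a warning).
#'
#' @param genes focal gene ids (typically post-speciation duplicates among
#'   the cell-type DE genes).
#' @param paralog_table data.frame `gene_id`, `paralog_id`,
#'   `duplication_taxon`.
#' @param branch_expression logical genes x branches matrix from
#'   [branch_expression_matrix()]; genes absent from it count as
#'   unexpressed.
#' @return list of class `DivergenceResult`: `calls` (data.frame gene_id,
#'   call), and `summary` (data.frame per cell type and overall with
#'   percent conserved/diverged among classifiable genes).
#' @export
classify_divergence <- function(genes, paralog_table, branch_expression) {
  branch_set <- function(g) {
    if (!g %in% rownames(branch_expression)) return(character(0))
    colnames(branch_expression)[branch_expression[g, ]]
  }
  partners_of <- function(g) {
    unique(c(paralog_table$paralog_id[paralog_table$gene_id == g],
             paralog_table$gene_id[paralog_table$paralog_id == g]))
  }
  no_record <- vapply(genes, function(g) length(partners_of(g)) == 0,
                      logical(1))
  if (any(no_record))
    warning("gene(s) absent from the paralog table: ",
            paste(head(genes[no_record], 5), collapse = ", "))
  call <- vapply(genes, function(g) {
    partners <- partners_of(g)
    if (length(partners) == 0) return("unclassifiable")
    psets <- lapply(partners, branch_set)
    expressed <- lengths(psets) > 0
    if (!any(expressed)) return("unclassifiable")
    gset <- branch_set(g)
    same <- vapply(psets[expressed], function(s) setequal(s, gset), logical(1))
    if (all(same)) "conserved" else "diverged"
  }, character(1))
  calls <- data.frame(gene_id = genes, call = unname(call),
                      stringsAsFactors = FALSE)
  classifiable <- calls$call != "unclassifiable"
  pct <- function(sub) {
    n <- sum(sub$call != "unclassifiable")
    if (n == 0) return(c(conserved = NA_real_, diverged = NA_real_))
    c(conserved = 100 * sum(sub$call == "conserved") / n,
      diverged = 100 * sum(sub$call == "diverged") / n)
  }
  rows <- list(data.frame(cell_type = "overall", t(pct(calls)),
                          n = sum(classifiable)))
  for (b in colnames(branch_expression)) {
    in_b <- vapply(calls$gene_id, function(g) b %in% branch_set(g), logical(1))
    rows[[length(rows) + 1]] <-
      data.frame(cell_type = b, t(pct(calls[in_b, , drop = FALSE])),
                 n = sum(in_b & classifiable))
  }
  structure(list(calls = calls, summary = do.call(rbind, rows)),
            class = c("DivergenceResult", "list"))
}
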
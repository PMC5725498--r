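#' Run the full synthetic-data analysis walkthrough
#'
#' Executes the complete pipeline on a simulated dataset: simulate -> qc ->
#' normalize -> filter -> hvg -> train -> predict -> stemness -> dynamics ->
#' ribosome -> conserve (11 stages). Every source of randomness is seeded
#' from `cfg$rng_seed`, so a rerun with the same config and parameters is
#' bit-reproducible. Any stage failure aborts with the stage name and
#' cause. To keep the walkthrough desk-sized, the Tobit tests run on a
#' capped gene subset (`cfg$dyn_genes_max` highest-expressed genes); the
#' per-stage functions impose no such cap.
#'
#' @param cfg an `AnalysisConfig`.
#' @param sim a `SimulationParams`; defaults to [sim_params()] seeded from
#'   the config.
#' @param outdir optional directory: stage outputs, a config snapshot and a
#'   manifest with md5 checksums are written there.
#' @return a list of class `PipelineRun`: `manifest` (stage, n_in, n_out,
#'   seconds), `config`, `sim`, `results` (per-stage objects) and, when
#'   `outdir` is given, `files` (paths and md5 checksums).
#' @export
run_all <- function(cfg = analysis_config(), sim = NULL, outdir = NULL) {
  if (is.null(sim)) sim <- sim_params(seed = cfg$rng_seed)
  manifest <- data.frame()
  results <- list()
  stage <- function(name, n_in, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest <<- rbind(manifest, data.frame(
      stage = name, n_in = n_in, n_out = out$n,
      seconds = round(proc.time()[["elapsed"]] - t0, 3)))
    results[[name]] <<- out$value
    out$value
  }

  data <- stage("simulate", 0, {
    d <- simulate_dataset(sim)
    list(value = d, n = nrow(d$counts$values))
  })
  ann <- data$annotation

  qc <- stage("qc", nrow(data$counts$values), {
    tpm <- counts_to_tpm(data$counts)
    metrics <- compute_qc_metrics(tpm, ann)
    r <- apply_qc(tpm, ann, metrics, cfg)
    list(value = r, n = sum(r$report$qc_pass))
  })
  pass_cells <- qc$report$cell_id[qc$report$qc_pass]

  cpm <- stage("normalize", length(pass_cells), {
    if (length(pass_cells) == 0) stop("no cells passed QC")
    v <- cpm_normalize(em_subset(data$counts, cells = pass_cells))
    list(value = v, n = nrow(v$values))
  })

  cpm_f <- stage("filter", ncol(cpm$values), {
    v <- filter_genes(cpm, cfg, ann)
    list(value = v, n = ncol(v$values))
  })
  logm <- log10_cpm1(cpm_f)
  meta <- data$metadata[match(pass_cells, data$metadata$cell_id), ]

  hvg <- stage("hvg", ncol(cpm_f$values), {
    fit <- fit_technical_noise(cpm_f, ann)
    sel <- select_hvg(fit, cfg$hvg_bio_cv2, cfg$hvg_fdr)
    list(value = list(fit = fit, hvg = as.character(sel)),
         n = length(sel))
  })

  committed <- meta$branch_label != "HSPC"
  model <- stage("train", sum(committed), {
    mod <- train_classifier(logm$values[committed, , drop = FALSE],
                            meta$branch_label[committed],
                            classifier_spec(seed = cfg$rng_seed))
    list(value = mod, n = length(mod$classes))
  })

  probs <- stage("predict", nrow(logm$values), {
    p <- predict_probabilities(model, logm)
    list(value = p, n = nrow(p))
  })

  stem <- stage("stemness", nrow(probs), {
    s <- call_stem_cells(stemness_scores(probs), cfg)
    list(value = s, n = sum(s$scores$is_stem))
  })

  # highest-expressed endogenous genes, capped for the Tobit stages
  spike_ids <- ann$gene_id[ann$is_spikein]
  endo_ids <- setdiff(gene_ids(cpm_f), spike_ids)
  gene_rank <- order(colMeans(cpm_f$values[, endo_ids, drop = FALSE]),
                     decreasing = TRUE)
  test_genes <- endo_ids[gene_rank][seq_len(min(cfg$dyn_genes_max,
                                                length(endo_ids)))]

  dyn <- stage("dynamics", length(test_genes), {
    branches <- setdiff(levels(meta$branch_label), "HSPC")
    per_branch <- lapply(branches, function(b) {
      in_path <- meta$branch_label %in% c("HSPC", b)
      res <- dynamic_gene_test(logm$values[in_path, test_genes, drop = FALSE],
                               meta$pseudotime[in_path], cfg)
      sig <- res$gene_id[res$significant]
      clust <- NULL
      if (length(sig) >= 2) {
        tm <- trend_matrix(logm$values[in_path, , drop = FALSE],
                           meta$pseudotime[in_path], sig)
        clust <- cluster_trends(tm)
        clust$curves <- lapply(split(names(clust$cluster), clust$cluster),
          function(g) {
            avg <- colMeans(tm[g, , drop = FALSE])
            grid <- seq(min(meta$pseudotime[in_path]),
                        max(meta$pseudotime[in_path]), length.out = ncol(tm))
            fit_trend_curve(grid, avg)
          })
      }
      list(result = res, clusters = clust)
    })
    names(per_branch) <- branches
    list(value = per_branch,
         n = sum(vapply(per_branch, function(x) sum(x$result$significant),
                        numeric(1))))
  })

  ribo <- stage("ribosome", ncol(cpm_f$values), {
    profiles <- celltype_average_profiles(cpm_f, meta$branch_label)
    cyto <- intersect(ann$gene_id[ann$ribo_class == "cytosolic"],
                      colnames(profiles))
    mito <- intersect(ann$gene_id[ann$ribo_class == "mitochondrial"],
                      colnames(profiles))
    value <- list(
      profiles = profiles,
      correlations = pairwise_profile_correlations(
        profiles[, cyto, drop = FALSE]),
      cv_cyto = profile_cv(profiles[, cyto, drop = FALSE]),
      cv_mito = profile_cv(profiles[, mito, drop = FALSE]),
      partition = partition_ribo_by_expression(cpm_f, ann, cfg))
    list(value = value, n = length(cyto) + length(mito))
  })

  cons <- stage("conserve", length(test_genes), {
    de <- de_test_states(logm$values[, test_genes, drop = FALSE],
                         meta$branch_label, cfg)
    sets <- derive_celltype_sets(em_subset(cpm_f, genes = test_genes),
                                 meta$branch_label, ann, de, cfg)
    pc_ids <- intersect(gene_ids(cpm_f),
                        ann$gene_id[ann$biotype == "protein_coding"])
    hom <- simulate_homology(homology_params(pc_ids, seed = cfg$rng_seed))
    orth_pct <- vapply(sets$sets, function(s)
      if (length(s)) ortholog_conservation(s, hom$orthologs,
                                           c("human", "mouse"))
      else NA_real_, numeric(1))
    split <- split_paralog_groups(hom$paralogs)
    bexpr <- branch_expression_matrix(cpm_f, meta$branch_label, cfg)
    de_genes <- unique(unlist(sets$sets))
    focal <- intersect(split$post_only, de_genes)
    div <- if (length(focal))
      suppressWarnings(classify_divergence(focal, hom$paralogs, bexpr))
    else NULL
    list(value = list(de = de, sets = sets, homology = hom,
                      ortholog_pct = orth_pct, paralog_split = split,
                      divergence = div),
         n = length(unlist(sets$sets)))
  })

  run <- structure(list(manifest = manifest, config = cfg, sim = sim,
                        results = results),
                   class = "PipelineRun")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(outdir, x)
    write_counts(data$counts, fp("counts.tsv"))
    write_table(data$metadata, fp("metadata.csv"))
    write_table(ann, fp("annotation.csv"))
    write_table(qc$report, fp("qc_report.csv"))
    write_table(hvg$fit$genes, fp("noise_fit.csv"))
    writeLines(hvg$hvg, fp("hvg_genes.txt"))
    write_table(data.frame(cell_id = rownames(probs), probs,
                           check.names = FALSE), fp("class_probs.csv"))
    write_table(stem$scores, fp("stemness.csv"))
    for (b in names(dyn))
      write_table(dyn[[b]]$result, fp(sprintf("dynamics_%s.csv", b)))
    write_table(as.data.frame(ribo$correlations), fp("ribo_correlations.csv"))
    write_table(ribo$partition$tiers, fp("ribo_tiers.csv"))
    write_table(data.frame(cell_type = names(cons$ortholog_pct),
                           ortholog_pct = cons$ortholog_pct),
                fp("ortholog_pct.csv"))
    if (!is.null(cons$divergence))
      write_table(cons$divergence$summary, fp("divergence_summary.csv"))
    snap <- vapply(names(cfg), function(k)
      paste(k, paste(format(cfg[[k]]), collapse = ","), sep = "="),
      character(1))
    writeLines(snap, fp("config_snapshot.txt"))
    files <- setdiff(list.files(outdir, full.names = TRUE),
                     fp("manifest.csv"))
    run$files <- data.frame(file = basename(files),
                            md5 = unname(tools::md5sum(files)),
                            row.names = NULL)
    write_table(cbind(manifest, stringsAsFactors = FALSE), fp("manifest.csv"))
  }
  run
}

#' @export
print.PipelineRun <- function(x, ...) {
  cat("PipelineRun:\n")
  print(x$manifest, row.names = FALSE)
  invisible(x)
}
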
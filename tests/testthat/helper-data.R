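# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# default-condition simulation taken through QC/normalisation/filtering
default_processed <- function() memo("default_processed", {
  d <- simulate_dataset(sim_params(seed = 11))
  tpm <- counts_to_tpm(d$counts)
  qc <- apply_qc(tpm, d$annotation, compute_qc_metrics(tpm, d$annotation),
                 analysis_config())
  pass <- qc$report$cell_id[qc$report$qc_pass]
  cpm <- cpm_normalize(em_subset(d$counts, cells = pass))
  filt <- filter_genes(cpm, analysis_config(), d$annotation)
  list(data = d, qc = qc, cpm = filt, logm = log10_cpm1(filt),
       meta = d$metadata[match(pass, d$metadata$cell_id), ],
       truth = d$truth$cells[match(pass, d$truth$cells$cell_id), ])
})

# classifier trained on the committed cells of the default simulation,
# with predicted probabilities for all QC-passing cells
default_model <- function() memo("default_model", {
  pr <- default_processed()
  committed <- pr$meta$branch_label != "HSPC"
  model <- train_classifier(pr$logm$values[committed, , drop = FALSE],
                            pr$meta$branch_label[committed],
                            classifier_spec(seed = 11))
  probs <- predict_probabilities(model, pr$logm)
  list(model = model, probs = probs)
})

# two identically configured pipeline runs for determinism checks
pipeline_pair <- function() memo("pipeline_pair", {
  cfg <- analysis_config(rng_seed = 21L, dyn_genes_max = 120)
  sim <- sim_params(n_root = 60, n_per_branch = 60, seed = 21L)
  dirs <- file.path(tempfile("runall"), c("a", "b"))
  runs <- lapply(dirs, function(d) run_all(cfg, sim, outdir = d))
  list(runs = runs, dirs = dirs)
})
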
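mk_tpm <- function(v, genes, ann_extra = NULL) {
  m <- matrix(v, nrow = 1, dimnames = list("c1", genes))
  ExpressionMatrix(m / sum(m) * 1e6, "TPM")
}

test_that("QC metrics reproduce simple arithmetic and handle zero cells", {
  genes <- c("g1", "g2", "ERCC-1")
  ann <- as_gene_annotation(data.frame(
    gene_id = genes, biotype = c("protein_coding", "protein_coding", "spike_in"),
    is_spikein = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE))
  m <- ExpressionMatrix(matrix(c(300000, 100000, 600000), 1,
                               dimnames = list("c1", genes)), "TPM")
  rep <- compute_qc_metrics(m, ann)
  expect_equal(rep$ercc_frac, 0.6)
  expect_equal(rep$n_expressed_genes, 2)   # spike-in excluded from the count
  z <- ExpressionMatrix(matrix(0, 1, 3, dimnames = list("c1", genes)), "TPM")
  repz <- compute_qc_metrics(z, ann)
  expect_equal(repz$n_expressed_genes, 0)
  expect_equal(repz$ercc_frac, 0)
  expect_equal(repz$mito_frac, 0)
  expect_true(repz$degenerate)
  expect_error(compute_qc_metrics(ExpressionMatrix(z$values, "counts"), ann),
               "TPM")
})

test_that("QC metrics agree with a brute-force recount on random cells", {
  set.seed(9)
  genes <- sprintf("g%02d", 1:50)
  spike <- c(rep(FALSE, 40), rep(TRUE, 10))
  mito <- c(rep(TRUE, 5), rep(FALSE, 45))
  ann <- as_gene_annotation(data.frame(
    gene_id = genes, biotype = ifelse(spike, "spike_in", "protein_coding"),
    is_spikein = spike, is_mito = mito, stringsAsFactors = FALSE))
  v <- matrix(rexp(20 * 50, 1 / 100), 20, 50,
              dimnames = list(sprintf("c%02d", 1:20), genes))
  rep <- compute_qc_metrics(ExpressionMatrix(v, "TPM"), ann)
  for (i in 1:20) {
    n_e <- 0; s_s <- 0; s_m <- 0; s_t <- 0
    for (g in 1:50) {
      s_t <- s_t + v[i, g]
      if (!spike[g] && v[i, g] > 1) n_e <- n_e + 1
      if (spike[g]) s_s <- s_s + v[i, g]
      if (mito[g]) s_m <- s_m + v[i, g]
    }
    expect_equal(rep$n_expressed_genes[i], n_e)
    expect_equal(rep$ercc_frac[i], s_s / s_t, tolerance = 1e-12)
    expect_equal(rep$mito_frac[i], s_m / s_t, tolerance = 1e-12)
  }
})

test_that("QC thresholds are strict and the globin rescue overrides failures", {
  cfg <- analysis_config()
  genes <- c(sprintf("g%04d", 1:1100), "ba1", "hbaa1")
  ann <- as_gene_annotation(data.frame(
    gene_id = genes, biotype = "protein_coding", stringsAsFactors = FALSE))
  build <- function(n_expr, ba1 = 0, hbaa1 = 0) {
    v <- numeric(length(genes))
    v[seq_len(n_expr)] <- 2                      # TPM > 1
    v[length(genes) - 1] <- ba1
    v[length(genes)] <- hbaa1
    ExpressionMatrix(matrix(v, 1, dimnames = list("c1", genes)), "TPM")
  }
  run <- function(m) {
    rep <- compute_qc_metrics(m, ann)
    apply_qc(m, ann, rep, cfg)$report
  }
  r1 <- run(build(999))
  expect_false(r1$qc_pass)
  expect_match(r1$failure_reasons, "min_genes")
  r2 <- run(build(1000))
  expect_true(r2$qc_pass)
  # rescue: 500 expressed genes but both globins above their thresholds
  r3 <- run(build(500, ba1 = 40001, hbaa1 = 9001))
  expect_true(r3$qc_pass)
  expect_true(r3$globin_rescue)
  expect_match(r3$failure_reasons, "min_genes")  # the violation is recorded
  # thresholds are strict: exactly at the limit fails the rescue
  r4 <- run(build(500, ba1 = 40000, hbaa1 = 9001))
  expect_false(r4$qc_pass)
})

test_that("fractions exactly at 60% pass; strictly above fail", {
  genes <- c("g1", "ERCC-1", "mt1")
  ann <- as_gene_annotation(data.frame(
    gene_id = genes, biotype = c("protein_coding", "spike_in", "protein_coding"),
    is_spikein = c(FALSE, TRUE, FALSE), is_mito = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE))
  cfg <- analysis_config(min_expressed_genes = 0)
  m <- ExpressionMatrix(matrix(c(400000, 600000, 0), 1,
                               dimnames = list("c1", genes)), "TPM")
  r <- apply_qc(m, ann, compute_qc_metrics(m, ann), cfg)$report
  expect_true(r$qc_pass)          # ercc_frac == 0.60 exactly
  m2 <- ExpressionMatrix(matrix(c(399999, 600001, 0), 1,
                                dimnames = list("c1", genes)), "TPM")
  r2 <- apply_qc(m2, ann, compute_qc_metrics(m2, ann), cfg)$report
  expect_false(r2$qc_pass)
  expect_match(r2$failure_reasons, "ercc")
})

test_that("missing rescue genes disable the rescue with a warning", {
  genes <- c("g1", "g2")
  ann <- as_gene_annotation(data.frame(gene_id = genes,
                                       biotype = "protein_coding"))
  m <- ExpressionMatrix(matrix(c(5e5, 5e5), 1, dimnames = list("c1", genes)),
                        "TPM")
  rep <- compute_qc_metrics(m, ann)
  expect_warning(out <- apply_qc(m, ann, rep, analysis_config()),
                 "rescue")
  expect_false(out$report$globin_rescue)
})

test_that("CPM normalisation matches arithmetic, a loop oracle, and rejects empty cells", {
  m <- ExpressionMatrix(matrix(c(1, 1, 2), 1, dimnames = list("c1", c("a", "b", "g"))),
                        "counts")
  cpm <- cpm_normalize(m)
  expect_equal(unname(cpm$values[1, ]), c(250000, 250000, 500000))
  set.seed(2)
  v <- matrix(rpois(200, 10), 10, 20,
              dimnames = list(sprintf("c%02d", 1:10), sprintf("g%02d", 1:20)))
  v[v == 0] <- 1
  cpm2 <- cpm_normalize(ExpressionMatrix(v, "counts"))
  expect_true(all(abs(rowSums(cpm2$values) - 1e6) <= 1e-6 * 1e6))
  for (i in 1:10) for (g in 1:20)
    expect_equal(cpm2$values[i, g], v[i, g] / sum(v[i, ]) * 1e6,
                 tolerance = 1e-12)
  vz <- v; vz[3, ] <- 0
  expect_error(cpm_normalize(ExpressionMatrix(vz, "counts")), "c03")
})

test_that("gene filter applies the ceil(1%) rule with spike-in exemption", {
  set.seed(3)
  n_cells <- 200
  v <- matrix(0, n_cells, 4,
              dimnames = list(sprintf("c%03d", 1:n_cells),
                              c("keep2", "drop1", "zero", "ERCC-1")))
  v[1:2, "keep2"] <- 10      # CPM > 1 in exactly 2 cells = ceil(1% of 200)
  v[1, "drop1"] <- 10        # only 1 cell
  v[, 4] <- 0
  ann <- as_gene_annotation(data.frame(
    gene_id = colnames(v), biotype = c(rep("protein_coding", 3), "spike_in"),
    is_spikein = c(FALSE, FALSE, FALSE, TRUE), stringsAsFactors = FALSE))
  m <- ExpressionMatrix(v + 0.5, "CPM")   # baseline 0.5 keeps CPM<=1 elsewhere
  out <- filter_genes(m, analysis_config(), ann)
  expect_true("keep2" %in% gene_ids(out))
  expect_false("drop1" %in% gene_ids(out))
  expect_false("zero" %in% gene_ids(out))
  expect_true("ERCC-1" %in% gene_ids(out))   # exempt despite zero expression
  out2 <- filter_genes(m, analysis_config())
  expect_false("ERCC-1" %in% gene_ids(out2)) # no annotation, no exemption
})

test_that("QC decisions are exact on the generator and idempotent", {
  pr <- default_processed()
  rep <- pr$qc$report
  tr <- pr$data$truth$cells
  expect_identical(rep$qc_pass, !tr$qc_should_fail)
  # idempotence: re-running QC on the passing cells changes nothing
  m2 <- pr$qc$matrix
  rep2 <- apply_qc(m2, pr$data$annotation,
                   compute_qc_metrics(m2, pr$data$annotation),
                   analysis_config())$report
  expect_true(all(rep2$qc_pass))
})
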
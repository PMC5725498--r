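#' Parameters for the synthetic haematopoiesis dataset
#'
#' The generator emulates a branching blood-differentiation experiment:
#' a multipotent root (HSPC-like) population plus four committed branches,
#' lineage markers rising logistically in pseudotime within their own branch,
#' a cytosolic ribosomal programme decaying exponentially in all lineages,
#' low trend-free mitochondrial ribosomal genes, flat housekeeping/null
#' genes, a small mitochondrially encoded gene set, and 92 ERCC-style
#' spike-ins drawn from a fixed log-uniform concentration pool independent
#' of cell state. Counts are negative binomial around analytic means scaled
#' by a log-normal library-size factor; spike-ins are Poisson (technical
#' noise only). A minority of cells are planted as QC violators and a
#' fraction of erythroid cells as globin-rescue cases (few expressed genes
#' but very high ba1/hbaa1).
#'
#' @param n_root,n_per_branch cells in the root population and in each of
#'   the four branches (defaults 100 each, 500 cells total).
#' @param branches committed branch names.
#' @param n_markers_per_branch,n_cyto_ribo,n_mito_ribo,n_house,n_null,n_mito_genes
#'   genes per programme.
#' @param n_spikeins number of spike-ins (default 92).
#' @param lib_sd_log log-normal sd of the per-cell library-size factor.
#' @param nb_dispersion negative binomial dispersion (1/size) of endogenous
#'   genes.
#' @param marker_fold fold-rise of a marker over its branch's pseudotime.
#' @param ribo_decay exponential decay rate of the cytosolic ribosomal
#'   programme over pseudotime in [0, 1].
#' @param frac_low_quality fraction of cells planted as QC violators.
#' @param frac_rescue fraction of erythroid cells planted as globin-rescue
#'   cases.
#' @param return_means if `TRUE`, the ground truth carries the full analytic
#'   per-cell mean matrix (memory-heavy; used for mean-accuracy checks).
#' @param seed RNG seed; identical params + seed give bit-identical output.
#' @return a list of class `SimulationParams`.
#' @export
sim_params <- function(n_root = 100, n_per_branch = 100,
                       branches = c("erythroid", "monocyte", "neutrophil",
                                    "thrombocyte"),
                       n_markers_per_branch = 50, n_cyto_ribo = 80,
                       n_mito_ribo = 60, n_house = 800, n_null = 400,
                       n_mito_genes = 13, n_spikeins = 92,
                       lib_sd_log = 0.3, nb_dispersion = 0.3,
                       marker_fold = 8, ribo_decay = 1.5,
                       frac_low_quality = 0.05, frac_rescue = 0.05,
                       return_means = FALSE, seed = 1L) {
  p <- as.list(environment())
  counts <- c(p$n_root, p$n_per_branch, p$n_markers_per_branch, p$n_cyto_ribo,
              p$n_mito_ribo, p$n_house, p$n_null, p$n_spikeins)
  if (any(counts <= 0)) stop("cell and gene counts must be positive")
  if (length(p$branches) < 1) stop("at least one branch required")
  for (f in c("frac_low_quality", "frac_rescue"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]")
  class(p) <- c("SimulationParams", "list")
  p
}

# Per-gene static parameter table: one row per gene with its programme and
# the gene-specific scale drawn once from the programme's distribution.
build_gene_table <- function(p) {
  ids <- list(); prog <- list(); br <- list(); scale <- list()
  add <- function(id, pr, b, sc) {
    ids[[length(ids) + 1]] <<- id
    prog[[length(prog) + 1]] <<- rep(pr, length(id))
    br[[length(br) + 1]] <<- rep(b, length(id))
    scale[[length(scale) + 1]] <<- sc
  }
  for (b in p$branches) {
    n <- p$n_markers_per_branch
    nm <- if (b == "erythroid" && n >= 2)
      c("ba1", "hbaa1", sprintf("%s_mk%03d", substr(b, 1, 4), seq_len(n - 2) + 2L))
    else sprintf("%s_mk%03d", substr(b, 1, 4), seq_len(n))
    add(nm, "marker", b, exp(rnorm(n, log(5), 0.4)))       # base level
  }
  add(sprintf("cyto_rp%03d", seq_len(p$n_cyto_ribo)), "cyto_ribo", NA,
      exp(rnorm(p$n_cyto_ribo, log(100), 0.3)))
  add(sprintf("mito_rp%03d", seq_len(p$n_mito_ribo)), "mito_ribo", NA,
      exp(rnorm(p$n_mito_ribo, log(0.25), 0.25)))
  add(sprintf("hk%04d", seq_len(p$n_house)), "housekeeping", NA,
      exp(rnorm(p$n_house, log(20), 0.5)))
  add(sprintf("null%04d", seq_len(p$n_null)), "null", NA,
      exp(rnorm(p$n_null, log(5), 0.5)))
  add(sprintf("mt_g%02d", seq_len(p$n_mito_genes)), "mito_genome", NA,
      exp(rnorm(p$n_mito_genes, log(30), 0.3)))
  add(sprintf("ERCC-%04d", seq_len(p$n_spikeins)), "spikein", NA,
      exp(runif(p$n_spikeins, log(1), log(100))))          # log-uniform pool
  data.frame(gene_id = unlist(ids), program = unlist(prog),
             marker_branch = unlist(br), scale = unlist(scale),
             stringsAsFactors = FALSE)
}

MARKER_OFF_LEVEL <- 0.1   # marker mean outside its own branch
MARKER_MIDPOINT <- 0.5    # logistic midpoint on the [0,1] pseudotime scale
MARKER_STEEPNESS <- 0.12
ROOT_MIX_T <- 0.6         # branch-curve evaluation point for root mixtures

marker_curve <- function(base, peak, t) {
  base + (peak - base) * stats::plogis((t - MARKER_MIDPOINT) / MARKER_STEEPNESS)
}

# Analytic noise-free mean of one gene for a committed cell of `branch` at
# pseudotime t (vectorised over t). Root cells are handled separately
# because their marker expression is a centroid mixture.
gene_mean_curve <- function(gene_row, branch, t, p) {
  sc <- gene_row$scale
  switch(gene_row$program,
    marker = {
      peak <- sc * p$marker_fold
      if (!is.na(gene_row$marker_branch) && gene_row$marker_branch == branch)
        marker_curve(sc, peak, t)
      else rep(MARKER_OFF_LEVEL, length(t))
    },
    cyto_ribo = sc * exp(-p$ribo_decay * t),
    mito_ribo = rep(sc, length(t)),
    housekeeping = rep(sc, length(t)),
    null = rep(sc, length(t)),
    mito_genome = rep(sc, length(t)),
    spikein = rep(sc, length(t)),
    stop("unknown program: ", gene_row$program)
  )
}

#' Analytic mean of a generator gene along pseudotime
#'
#' Evaluates the generator's noise-free mean function (library-size factor
#' 1) for one gene, as seen by committed cells of a given branch. This is
#' the reference against which trend claims are tested, independent of any
#' sampling.
#'
#' @param truth a `GroundTruth` list from [simulate_dataset()].
#' @param gene_id gene identifier.
#' @param branch branch name.
#' @param t numeric vector of pseudotimes in [0, 1].
#' @return numeric vector of means.
#' @export
expected_mean_profile <- function(truth, gene_id, branch, t) {
  gr <- truth$genes[truth$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(gr) != 1) stop("unknown gene: ", gene_id)
  gene_mean_curve(as.list(gr), branch, t, truth$params)
}

#' Simulate a branching haematopoiesis single-cell dataset
#'
#' See [sim_params()] for the generative model. Returns raw counts; use
#' [counts_to_tpm()] for the QC input and [cpm_normalize()] downstream.
#'
#' @param params a `SimulationParams` list.
#' @return a list with elements `counts` (`ExpressionMatrix`, unit counts),
#'   `metadata` (`CellMetadata` with true branch, pseudotime, line),
#'   `annotation` (`GeneAnnotation`) and `truth` (`GroundTruth`: per-cell
#'   and per-gene planted labels, per-gene programme parameters, and the
#'   generator parameters).
#' @export
simulate_dataset <- function(params = sim_params()) {
  p <- params
  set.seed(p$seed)
  genes <- build_gene_table(p)
  n_genes <- nrow(genes)
  n_branch_cells <- length(p$branches) * p$n_per_branch
  n_cells <- p$n_root + n_branch_cells

  branch <- c(rep("HSPC", p$n_root), rep(p$branches, each = p$n_per_branch))
  t_pseudo <- c(runif(p$n_root, 0, 0.3), runif(n_branch_cells, 0.3, 1))
  lib <- exp(rnorm(n_cells, 0, p$lib_sd_log))
  line <- sample(c("cd41", "runx1", "kdrl"), n_cells, replace = TRUE)
  cell_id <- sprintf("cell_%04d", seq_len(n_cells))

  # analytic mean matrix (cells x genes), library factor applied afterwards
  mu <- matrix(0, n_cells, n_genes, dimnames = list(cell_id, genes$gene_id))
  is_root <- branch == "HSPC"
  # root marker mixtures: convex combination of branch centroid marker levels
  mix_w <- matrix(stats::rgamma(sum(is_root) * length(p$branches), shape = 8),
                  ncol = length(p$branches))
  mix_w <- mix_w / rowSums(mix_w)
  colnames(mix_w) <- p$branches
  for (g in seq_len(n_genes)) {
    row <- as.list(genes[g, ])
    if (row$program == "marker") {
      for (b in p$branches) {
        idx <- branch == b
        mu[idx, g] <- gene_mean_curve(row, b, t_pseudo[idx], p)
      }
      own <- row$marker_branch
      centroid <- gene_mean_curve(row, own, ROOT_MIX_T, p)
      mu[is_root, g] <- mix_w[, own] * centroid +
        (1 - mix_w[, own]) * MARKER_OFF_LEVEL
    } else {
      mu[, g] <- gene_mean_curve(row, branch[1], t_pseudo, p)
    }
  }

  endo <- genes$program != "spikein"
  mu[, endo] <- mu[, endo] * lib   # library size affects endogenous genes only

  # planted QC violators and erythroid globin-rescue cells
  n_lowq <- round(p$frac_low_quality * n_cells)
  lowq_type <- rep(NA_character_, n_cells)
  lowq_cells <- if (n_lowq > 0) sample(seq_len(n_cells), n_lowq) else integer(0)
  if (n_lowq > 0)
    lowq_type[lowq_cells] <- rep(c("few_genes", "high_ercc", "high_mito"),
                                 length.out = n_lowq)
  ery_cells <- setdiff(which(branch == "erythroid"), lowq_cells)
  n_rescue <- round(p$frac_rescue * p$n_per_branch)
  rescue_cells <- if (n_rescue > 0) sample(ery_cells, min(n_rescue, length(ery_cells)))
                  else integer(0)

  spike <- genes$program == "spikein"
  mito <- genes$program == "mito_genome"
  for (i in lowq_cells) {
    switch(lowq_type[i],
      few_genes = { mu[i, endo] <- mu[i, endo] * 0.02 },
      high_ercc = { mu[i, endo] <- mu[i, endo] * 0.3
                    mu[i, spike] <- mu[i, spike] * 50 },
      high_mito = { mu[i, mito] <- mu[i, mito] * 200 })
  }
  for (i in rescue_cells) {
    mu[i, endo] <- mu[i, endo] * 0.02
    mu[i, "ba1"] <- 5000
    mu[i, "hbaa1"] <- 1200
  }

  counts <- matrix(0, n_cells, n_genes, dimnames = dimnames(mu))
  size <- 1 / p$nb_dispersion
  counts[, endo] <- rnbinom(n_cells * sum(endo), mu = mu[, endo], size = size)
  counts[, spike] <- stats::rpois(n_cells * sum(spike), lambda = mu[, spike])

  metadata <- as_cell_metadata(data.frame(
    cell_id = cell_id,
    branch_label = factor(branch, levels = c("HSPC", p$branches)),
    pseudotime = t_pseudo, line = line, stringsAsFactors = FALSE))

  annotation <- as_gene_annotation(data.frame(
    gene_id = genes$gene_id,
    biotype = ifelse(genes$program == "spikein", "spike_in", "protein_coding"),
    is_spikein = genes$program == "spikein",
    is_mito = genes$program == "mito_genome",
    ribo_class = c(marker = "none", cyto_ribo = "cytosolic",
                   mito_ribo = "mitochondrial", housekeeping = "none",
                   null = "none", mito_genome = "none",
                   spikein = "none")[genes$program],
    stringsAsFactors = FALSE))

  truth_genes <- genes
  truth_genes$trend <- c(marker = "up", cyto_ribo = "down", mito_ribo = "flat",
                         housekeeping = "flat", null = "flat",
                         mito_genome = "flat", spikein = "flat")[genes$program]
  truth <- list(
    cells = data.frame(cell_id = cell_id, branch = branch,
                       pseudotime = t_pseudo, multipotent = is_root,
                       qc_should_fail = !is.na(lowq_type),
                       lowq_type = lowq_type,
                       globin_rescue = seq_len(n_cells) %in% rescue_cells,
                       stringsAsFactors = FALSE),
    genes = truth_genes,
    params = p)
  if (isTRUE(p$return_means)) truth$mean_matrix <- mu
  class(truth) <- c("GroundTruth", "list")

  list(counts = ExpressionMatrix(counts, "counts"),
       metadata = metadata, annotation = annotation, truth = truth)
}

#' Per-million scaling of simulated counts for QC
#'
#' All simulated genes share one effective length, so the length-corrected
#' per-million abundance (TPM) coincides with the per-million count scaling.
#'
#' @param m an `ExpressionMatrix` with unit counts.
#' @return an `ExpressionMatrix` with unit TPM.
#' @export
counts_to_tpm <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "counts") stop("expected unit 'counts', got '", m$unit, "'")
  tot <- rowSums(m$values)
  v <- m$values
  nz <- tot > 0
  v[nz, ] <- v[nz, , drop = FALSE] / tot[nz] * 1e6
  ExpressionMatrix(v, "TPM")
}

#' Spike-in noise benchmark for the technical-noise fit
#'
#' Generates a CPM matrix whose spike-ins and null genes carry Poisson
#' (purely technical) counting noise while a planted gene set carries extra
#' biological variation, injected as a per-cell log-normal multiplier with
#' the requested squared coefficient of variation.
#'
#' @param n_cells number of cells.
#' @param n_null,n_planted null and planted endogenous genes.
#' @param n_spikeins spike-ins.
#' @param bio_cv2 biological CV^2 of the planted genes.
#' @param depth expected counts per cell over all genes.
#' @param seed RNG seed.
#' @return list with `cpm` (`ExpressionMatrix`), `annotation`, and gene id
#'   vectors `null_genes`, `planted_genes`.
#' @export
simulate_noise_benchmark <- function(n_cells = 5000, n_null = 2000,
                                     n_planted = 100, n_spikeins = 92,
                                     bio_cv2 = 1.0, depth = 50000,
                                     seed = 1L) {
  set.seed(seed)
  spike_mu <- exp(runif(n_spikeins, log(0.5), log(200)))
  null_mu <- exp(runif(n_null, log(1), log(200)))
  planted_mu <- exp(runif(n_planted, log(20), log(200)))  # moderate means
  mu <- c(spike_mu, null_mu, planted_mu)
  mu <- mu / sum(mu) * depth
  n_genes <- length(mu)
  ids <- c(sprintf("ERCC-%04d", seq_len(n_spikeins)),
           sprintf("null%04d", seq_len(n_null)),
           sprintf("hvg%03d", seq_len(n_planted)))
  counts <- matrix(stats::rpois(n_cells * n_genes, rep(mu, each = n_cells)),
                   n_cells, n_genes, dimnames = list(
                     sprintf("cell_%05d", seq_len(n_cells)), ids))
  if (n_planted > 0) {
    sdlog <- sqrt(log1p(bio_cv2))
    fac <- matrix(exp(rnorm(n_cells * n_planted, -sdlog^2 / 2, sdlog)),
                  n_cells, n_planted)
    pl <- n_spikeins + n_null + seq_len(n_planted)
    counts[, pl] <- stats::rpois(n_cells * n_planted,
                                 rep(mu[pl], each = n_cells) * fac)
  }
  ann <- as_gene_annotation(data.frame(
    gene_id = ids,
    biotype = ifelse(seq_len(n_genes) <= n_spikeins, "spike_in",
                     "protein_coding"),
    is_spikein = seq_len(n_genes) <= n_spikeins,
    stringsAsFactors = FALSE))
  cpm <- cpm_normalize(ExpressionMatrix(counts, "counts"))
  list(cpm = cpm, annotation = ann,
       null_genes = ids[n_spikeins + seq_len(n_null)],
       planted_genes = ids[n_spikeins + n_null + seq_len(n_planted)])
}

#' Separable four-class benchmark for the lineage classifier
#'
#' Gaussian class blobs in gene space: each class has a distinct centroid on
#' a subset of informative genes, unit noise everywhere.
#'
#' @param n_cells total cells, split evenly over classes.
#' @param n_genes total genes.
#' @param n_informative genes carrying class signal.
#' @param shift centroid displacement on informative genes.
#' @param classes class names.
#' @param seed RNG seed.
#' @return list with `x` (cells x genes matrix) and `labels` (factor).
#' @export
simulate_classifier_benchmark <- function(n_cells = 800, n_genes = 2000,
                                          n_informative = 200, shift = 1.5,
                                          classes = c("erythroid", "monocyte",
                                                      "neutrophil",
                                                      "thrombocyte"),
                                          seed = 1L) {
  set.seed(seed)
  k <- length(classes)
  lab <- factor(rep(classes, length.out = n_cells), levels = classes)
  centroids <- matrix(0, k, n_genes)
  centroids[, seq_len(n_informative)] <-
    matrix(rnorm(k * n_informative, 0, shift), k)
  x <- centroids[as.integer(lab), ] + matrix(rnorm(n_cells * n_genes),
                                             n_cells, n_genes)
  dimnames(x) <- list(sprintf("cell_%04d", seq_len(n_cells)),
                      sprintf("g%04d", seq_len(n_genes)))
  list(x = x, labels = lab)
}

#' Parameters for the toy homology generator
#'
#' @param gene_ids genes to annotate.
#' @param species species columns of the ortholog table.
#' @param ortholog_prob per-species probability that a gene has an ortholog
#'   (scalar or named vector).
#' @param n_pre_only,n_post_only,n_both planted counts of genes duplicated
#'   exclusively pre-speciation, exclusively post-speciation, or in both
#'   epochs (the "both" genes are the ones the pre/post split removes).
#' @param max_partners maximal paralog partners per duplicated gene.
#' @param seed RNG seed.
#' @return a list of class `HomologyParams`.
#' @export
homology_params <- function(gene_ids,
                            species = c("human", "mouse", "chimpanzee", "rat",
                                        "chicken", "xenopus", "coelacanth",
                                        "lamprey"),
                            ortholog_prob = 0.8,
                            n_pre_only = NULL, n_post_only = NULL,
                            n_both = NULL, max_partners = 3, seed = 1L) {
  if (length(species) == 0) stop("species list must be non-empty")
  n <- length(gene_ids)
  if (is.null(n_pre_only)) n_pre_only <- round(0.45 * n)
  if (is.null(n_post_only)) n_post_only <- round(0.20 * n)
  if (is.null(n_both)) n_both <- round(0.10 * n)
  if (n_pre_only + n_post_only + n_both > n)
    stop("planted group sizes exceed the number of genes")
  structure(as.list(environment()), class = c("HomologyParams", "list"))
}

#' Simulate toy ortholog and paralog tables with planted truth
#'
#' Emulates a BioMart-style export: a gene-by-species ortholog presence
#' table and a paralog pair table annotated with the taxon of each
#' duplication node (pre-speciation taxa Euteleostomi, Bilateria, Chordata,
#' Vertebrata, Opisthokonta; post-speciation taxa Neopterygii, Otophysa,
#' Clupeocephala, Danio rerio).
#'
#' @param params a `HomologyParams` list.
#' @return a list of class `HomologyTables`: `orthologs` (data.frame gene_id
#'   + one logical column per species), `paralogs` (data.frame gene_id,
#'   paralog_id, duplication_taxon), and `truth` (lists `pre_only`,
#'   `post_only`, `both`).
#' @export
simulate_homology <- function(params) {
  p <- params
  set.seed(p$seed)
  n <- length(p$gene_ids)
  prob <- if (length(p$ortholog_prob) == 1)
    setNames(rep(p$ortholog_prob, length(p$species)), p$species)
  else p$ortholog_prob[p$species]
  orth <- data.frame(gene_id = p$gene_ids, stringsAsFactors = FALSE)
  for (s in p$species) orth[[s]] <- runif(n) < prob[[s]]

  pool <- sample(p$gene_ids)
  pre_only <- pool[seq_len(p$n_pre_only)]
  post_only <- pool[p$n_pre_only + seq_len(p$n_post_only)]
  both <- pool[p$n_pre_only + p$n_post_only + seq_len(p$n_both)]

  make_rows <- function(g, taxa_pool) {
    k <- sample(seq_len(p$max_partners), 1)
    partners <- sample(setdiff(p$gene_ids, g), k)
    data.frame(gene_id = g, paralog_id = partners,
               duplication_taxon = sample(taxa_pool, k, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (g in pre_only) rows[[length(rows) + 1]] <- make_rows(g, PRE_TAXA)
  for (g in post_only) rows[[length(rows) + 1]] <- make_rows(g, POST_TAXA)
  for (g in both) {
    rows[[length(rows) + 1]] <- make_rows(g, PRE_TAXA)
    rows[[length(rows) + 1]] <- make_rows(g, POST_TAXA)
  }
  paralogs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), paralog_id = character(),
               duplication_taxon = character(), stringsAsFactors = FALSE)
  structure(list(orthologs = orth, paralogs = paralogs,
                 truth = list(pre_only = sort(pre_only),
                              post_only = sort(post_only),
                              both = sort(both))),
            class = c("HomologyTables", "list"))
}
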
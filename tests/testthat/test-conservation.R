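test_that("ortholog percentages follow the counting rule", {
  tab <- data.frame(gene_id = sprintf("g%02d", 1:10),
                    human = c(rep(TRUE, 9), FALSE),
                    mouse = rep(TRUE, 10))
  expect_equal(ortholog_conservation(tab$gene_id, tab, "human"), 90)
  expect_equal(ortholog_conservation(tab$gene_id, tab, "mouse"), 100)
  expect_equal(ortholog_conservation(tab$gene_id, tab, c("human", "mouse")), 90)
  expect_error(ortholog_conservation(character(0), tab, "human"), "empty")
  expect_error(ortholog_conservation(tab$gene_id, tab, "dolphin"),
               "not in table")
  # genes absent from the table count as lacking the ortholog
  expect_equal(ortholog_conservation(c("g01", "zzz"), tab, "human"), 50)
})

test_that("ortholog percentage matches an enumeration oracle on random tables", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(5:25, 1)
    tab <- data.frame(gene_id = sprintf("r%03d", 1:n),
                      s1 = runif(n) < 0.6, s2 = runif(n) < 0.6)
    set <- sample(tab$gene_id, sample(2:n, 1))
    cnt <- 0
    for (g in set) {
      row <- which(tab$gene_id == g)
      if (tab$s1[row] && tab$s2[row]) cnt <- cnt + 1
    }
    expect_equal(ortholog_conservation(set, tab, c("s1", "s2")),
                 100 * cnt / length(set))
  }
})

test_that("paralog split removes genes duplicated in both epochs", {
  ptab <- data.frame(
    gene_id = c("A", "B", "B", "C", "C", "D"),
    paralog_id = c("x1", "x2", "x3", "x4", "x5", "x6"),
    duplication_taxon = c("Euteleostomi", "Bilateria", "Clupeocephala",
                          "Chordata", "Danio rerio", "Neopterygii"),
    stringsAsFactors = FALSE)
  out <- split_paralog_groups(ptab)
  expect_equal(out$pre_only, "A")
  expect_equal(out$post_only, "D")
  expect_equal(out$removed, c("B", "C"))
  expect_length(intersect(out$pre_only, out$post_only), 0)
  # disjoint inputs pass through unchanged
  ptab2 <- ptab[c(1, 6), ]
  out2 <- split_paralog_groups(ptab2)
  expect_equal(out2$pre_only, "A")
  expect_equal(out2$post_only, "D")
  expect_length(out2$removed, 0)
  expect_error(split_paralog_groups(data.frame(
    gene_id = "A", paralog_id = "B", duplication_taxon = "Hominidae")),
    "Hominidae")
  expect_error(split_paralog_groups(data.frame(
    gene_id = "A", paralog_id = "A", duplication_taxon = "Otophysa")),
    "self-paralogy")
})

test_that("divergence classification follows the expression-pattern rules", {
  bexpr <- rbind(g = c(TRUE, FALSE), p1 = c(TRUE, FALSE),
                 p2 = c(TRUE, FALSE))
  colnames(bexpr) <- c("erythroid", "monocyte")
  ptab <- data.frame(gene_id = c("g", "g"), paralog_id = c("p1", "p2"),
                     duplication_taxon = "Clupeocephala",
                     stringsAsFactors = FALSE)
  out <- classify_divergence("g", ptab, bexpr)
  expect_equal(out$calls$call, "conserved")
  bexpr["p2", ] <- c(FALSE, TRUE)           # one paralog in a different type
  out2 <- classify_divergence("g", ptab, bexpr)
  expect_equal(out2$calls$call, "diverged")
  bexpr["p1", ] <- c(FALSE, FALSE)          # and the conserved partner silent
  bexpr["p2", ] <- c(FALSE, FALSE)
  out3 <- classify_divergence("g", ptab, bexpr)
  expect_equal(out3$calls$call, "unclassifiable")
  expect_warning(classify_divergence("orphan", ptab, bexpr), "absent")
})

test_that("divergence calls match the exhaustive oracle on random toy instances", {
  set.seed(42)
  branches <- c("ery", "mono", "neut", "thromb")
  for (rep in 1:100) {
    n <- sample(6:20, 1)
    ids <- sprintf("t%02d", 1:n)
    bexpr <- matrix(runif(n * 4) < 0.4, n, 4,
                    dimnames = list(ids, branches))
    n_pairs <- sample(3:12, 1)
    ptab <- data.frame(
      gene_id = sample(ids, n_pairs, replace = TRUE),
      paralog_id = sample(ids, n_pairs, replace = TRUE),
      duplication_taxon = sample(c(PRE_TAXA, POST_TAXA), n_pairs,
                                 replace = TRUE),
      stringsAsFactors = FALSE)
    ptab <- ptab[ptab$gene_id != ptab$paralog_id, , drop = FALSE]
    if (nrow(ptab) == 0) next
    focal <- sample(ids, sample(2:5, 1))
    got <- suppressWarnings(classify_divergence(focal, ptab, bexpr))
    expect_equal(got$calls$call, divergence_oracle(focal, ptab, bexpr))
    expect_equal(sum(got$calls$call %in%
                       c("conserved", "diverged", "unclassifiable")),
                 length(focal))
    # split oracle: per-gene epoch membership by direct enumeration
    sp <- split_paralog_groups(ptab)
    for (g in unique(ptab$gene_id)) {
      taxa <- ptab$duplication_taxon[ptab$gene_id == g]
      pre <- any(taxa %in% PRE_TAXA); post <- any(taxa %in% POST_TAXA)
      expect_equal(g %in% sp$pre_only, pre && !post)
      expect_equal(g %in% sp$post_only, post && !pre)
      expect_equal(g %in% sp$removed, pre && post)
    }
  }
})

test_that("cell-type gene sets honour biotype, prevalence and score rules", {
  set.seed(43)
  n <- 90
  groups <- factor(rep(c("A", "B", "C"), each = 30))
  genes <- c("mkA", "mkB", "spike", "edge", "weak", "bg1", "bg2")
  v <- matrix(rexp(n * length(genes), 1 / 50), n, length(genes),
              dimnames = list(sprintf("c%02d", 1:n), genes))
  v[, "mkA"] <- ifelse(groups == "A", 500, 0.1)
  v[, "mkB"] <- ifelse(groups == "B", 500, 0.1)
  v[, "spike"] <- ifelse(groups == "A", 500, 0.1)
  v[, "edge"] <- 0; v[groups == "A", "edge"][1:15] <- 500  # exactly 50% of A
  v[, "weak"] <- ifelse(groups == "A", 1.5, 1.2)           # expressed, low score
  ann <- as_gene_annotation(data.frame(
    gene_id = genes,
    biotype = ifelse(genes == "spike", "spike_in", "protein_coding"),
    is_spikein = genes == "spike", stringsAsFactors = FALSE))
  m <- ExpressionMatrix(v, "CPM")
  de <- de_test_states(log10_cpm1(m), groups)
  sets <- derive_celltype_sets(m, groups, ann, de, analysis_config())
  expect_true("mkA" %in% sets$sets$A)
  expect_false("mkA" %in% sets$sets$B)
  expect_true("mkB" %in% sets$sets$B)
  expect_false("spike" %in% unlist(sets$sets))   # biotype exclusion
  expect_false("edge" %in% sets$sets$A)          # >50% is strict
  expect_false("weak" %in% sets$sets$A)          # below the score floor
  expect_false("spike" %in% sets$non_de)
  expect_length(intersect(unlist(sets$sets), sets$non_de), 0)
})

test_that("branch expression uses the strict >10% rule", {
  v <- matrix(0, 20, 2, dimnames = list(sprintf("c%02d", 1:20), c("a", "b")))
  v[1:2, "a"] <- 10     # 2/20 = 10% exactly -> not expressed
  v[1:3, "b"] <- 10     # 15% -> expressed
  be <- branch_expression_matrix(ExpressionMatrix(v, "CPM"),
                                 factor(rep("x", 20)))
  expect_false(be["a", "x"])
  expect_true(be["b", "x"])
})
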
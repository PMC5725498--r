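test_that("tobit log-likelihood reduces to the Gaussian one without censoring", {
  set.seed(21)
  n <- 40
  X <- cbind(1, runif(n))
  beta <- c(5, 1)
  y <- drop(X %*% beta) + 0.3 * rnorm(n)   # all well above c = 0
  ll <- tobit_loglik(y, X, beta, 0.3, c = 0)
  gauss <- sum(dnorm(y, drop(X %*% beta), 0.3, log = TRUE))
  expect_equal(ll, gauss, tolerance = 1e-12)
})

test_that("with everything censored far below threshold the log-likelihood tends to zero", {
  X <- cbind(rep(1, 20))
  y <- rep(0, 20)
  ll <- tobit_loglik(y, X, beta = -50, sigma = 1, c = 0)
  expect_lte(ll, 0)
  expect_gt(ll, -1e-10)
  ll2 <- tobit_loglik(y, X, beta = -5, sigma = 1, c = 0)
  expect_lt(ll2, 0)
  expect_gt(ll2, -1e-4)
})

test_that("tobit log-likelihood matches a per-observation oracle to 1e-10", {
  set.seed(22)
  for (rep in 1:5) {
    n <- 30
    X <- cbind(1, rnorm(n), runif(n))
    beta <- rnorm(3)
    sigma <- runif(1, 0.2, 2)
    y <- pmax(drop(X %*% beta) + sigma * rnorm(n), 0)
    expect_equal(tobit_loglik(y, X, beta, sigma, c = 0),
                 tobit_loglik_oracle(y, X, beta, sigma, 0),
                 tolerance = 1e-10)
  }
  expect_error(tobit_loglik(c(1, NA), cbind(1, 1), 0, 1), "non-finite")
  expect_error(tobit_loglik(c(1, 2), cbind(c(1, 1)), 0, -1), "positive")
})

test_that("the MLE agrees with the survreg left-censored gaussian fit", {
  skip_if_not_installed("survival")
  set.seed(23)
  n <- 300
  x <- runif(n)
  y <- pmax(0.5 + 1.2 * x + 0.6 * rnorm(n), 0)
  ours <- tobit_fit(y, cbind(1, x), c = 0)
  sr <- survival::survreg(survival::Surv(y, y > 0, type = "left") ~ x,
                          dist = "gaussian")
  expect_equal(unname(ours$coefficients), unname(coef(sr)), tolerance = 1e-4)
  expect_equal(unname(ours$sigma), unname(sr$scale), tolerance = 1e-4)
  expect_equal(ours$loglik, as.numeric(logLik(sr)), tolerance = 1e-6)
})

test_that("state test: constant genes are null, planted shifts are found, LRT is non-negative", {
  set.seed(24)
  states <- factor(rep(1:3, each = 40))
  v <- cbind(const = rep(0.7, 120),
             shift = pmax(c(rnorm(40, 0.3, 0.4), rnorm(40, 1.3, 0.4),
                            rnorm(40, 0.3, 0.4)), 0),
             noise = pmax(rnorm(120, 0.8, 0.5), 0))
  res <- de_test_states(v, states)
  expect_equal(res$stat[res$gene_id == "const"], 0)
  expect_equal(res$p[res$gene_id == "const"], 1)
  expect_lt(res$p[res$gene_id == "shift"], 0.01)
  expect_true(all(res$stat >= 0, na.rm = TRUE))
  expect_true(all(res$q >= 0 & res$q <= 1, na.rm = TRUE))
  # small states excluded with a warning
  st2 <- factor(c(rep(1, 58), rep(2, 60), rep(3, 2)))
  expect_warning(de_test_states(v, st2), "fewer than 3")
  expect_error(de_test_states(v, factor(rep(1, 120))), "at least 2 states")
})

test_that("BH adjustment equals a from-scratch implementation", {
  set.seed(25)
  states <- factor(rep(1:2, each = 30))
  v <- matrix(pmax(rnorm(60 * 25, 0.6, 0.5), 0), 60, 25,
              dimnames = list(NULL, sprintf("g%02d", 1:25)))
  res <- de_test_states(v, states)
  ok <- !is.na(res$p)
  expect_equal(res$q[ok], bh_oracle(res$p[ok]), tolerance = 1e-12)
})

test_that("pseudotime test finds planted trends and is invariant to reversal", {
  set.seed(26)
  n <- 120
  pt <- runif(n)
  up <- pmax(outer(pt, rep(1.5, 8)) + matrix(rnorm(n * 8, 0.3, 0.4), n), 0)
  flat <- pmax(matrix(rnorm(n * 8, 0.8, 0.5), n), 0)
  v <- cbind(up, flat)
  colnames(v) <- c(sprintf("up%d", 1:8), sprintf("fl%d", 1:8))
  res <- dynamic_gene_test(v, pt)
  expect_true(all(res$p[1:8] < 0.01))
  expect_gte(mean(res$significant[1:8]), 0.9)
  res_rev <- dynamic_gene_test(v, max(pt) - pt)
  flat_idx <- 9:16
  expect_equal(res$p[flat_idx], res_rev$p[flat_idx], tolerance = 1e-3)
  expect_error(dynamic_gene_test(v[1:10, ], pt[1:10]), "at least 20")
})

test_that("trend clustering recovers planted up/down groups and guards degeneracy", {
  skip_if_not_installed("mclust")
  set.seed(27)
  n <- 150
  pt <- sort(runif(n))
  mk_up <- vapply(1:20, function(i) pt * runif(1, 1, 2) +
                    rnorm(n, 0, 0.15), numeric(n))
  mk_dn <- vapply(1:20, function(i) (1 - pt) * runif(1, 1, 2) +
                    rnorm(n, 0, 0.15), numeric(n))
  v <- pmax(cbind(mk_up, mk_dn), 0)
  colnames(v) <- c(sprintf("up%02d", 1:20), sprintf("dn%02d", 1:20))
  tm <- trend_matrix(v, pt, colnames(v))
  cl <- cluster_trends(tm)
  expect_equal(cl$k, 2L)
  truth <- rep(1:2, each = 20)
  expect_gte(mclust::adjustedRandIndex(cl$cluster, truth), 0.9)
  # permutation invariance up to label renaming
  perm <- sample(ncol(v))
  cl_p <- cluster_trends(trend_matrix(v, pt, colnames(v)[perm]))
  expect_equal(mclust::adjustedRandIndex(cl_p$cluster[names(cl$cluster)],
                                         cl$cluster), 1)
  # all-identical trends: silhouette floor returns a single cluster
  same <- tm[rep(1, 10), ] + matrix(rnorm(10 * ncol(tm), 0, 1e-4), 10)
  rownames(same) <- sprintf("s%02d", 1:10)
  expect_warning(cl1 <- cluster_trends(same), "single cluster")
  expect_equal(cl1$k, 1L)
  expect_warning(cl2 <- cluster_trends(tm[1:2, ]), "single cluster")
  expect_equal(unname(cl2$cluster), c(1L, 1L))
})

test_that("quadratic trend fit recovers exact and least-squares solutions", {
  t <- seq(0, 2, length.out = 12)
  y <- 2 + 3 * t - t^2
  fit <- fit_trend_curve(t, y)
  expect_equal(unname(fit$coefficients), c(2, 3, -1), tolerance = 1e-10)
  expect_lt(fit$sigma, 1e-10)
  fitc <- fit_trend_curve(t, rep(5, 12))
  expect_equal(unname(fitc$coefficients[2:3]), c(0, 0), tolerance = 1e-10)
  # noisy case against the closed-form normal equations
  set.seed(28)
  yn <- y + rnorm(12, 0, 0.3)
  fit2 <- fit_trend_curve(t, yn)
  Xd <- cbind(1, t, t^2)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% yn)
  expect_equal(unname(fit2$coefficients), unname(drop(beta)),
               tolerance = 1e-8)
  expect_true(all(fit2$band$upper >= fit2$band$lower))
  expect_error(fit_trend_curve(t[1:3], y[1:3]), "at least 4")
  expect_error(fit_trend_curve(rep(1, 5), 1:5), "rank deficient")
})
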
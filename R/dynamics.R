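#' Log-likelihood of the left-censored Gaussian (Tobit) model
#'
#' Expression on the log10(CPM+1) scale is modelled as a latent Gaussian
#' x beta + sigma eps observed only above the detection limit c; values at
#' or below c (the zeros, with the default c = 0) are censored. The
#' log-likelihood is
#' sum over uncensored cells of log phi((y - x beta)/sigma)/sigma plus
#' sum over censored cells of log Phi((c - x beta)/sigma).
#'
#' @param y numeric response vector.
#' @param X design matrix (rows = cells).
#' @param beta coefficient vector.
#' @param sigma positive scale.
#' @param c censoring threshold (default 0).
#' @return the log-likelihood (scalar).
#' @export
tobit_loglik <- function(y, X, beta, sigma, c = 0) {
  if (sigma <= 0) stop("sigma must be positive")
  if (!all(is.finite(y)) || !all(is.finite(X)) || !all(is.finite(beta)))
    stop("non-finite inputs")
  eta <- drop(X %*% beta)
  cens <- y <= c
  ll <- 0
  if (any(!cens))
    ll <- ll + sum(dnorm((y[!cens] - eta[!cens]) / sigma, log = TRUE) -
                   log(sigma))
  if (any(cens))
    ll <- ll + sum(pnorm((c - eta[cens]) / sigma, log.p = TRUE))
  ll
}

# negative log-likelihood and gradient in par = c(beta, log sigma)
tobit_negll <- function(par, y, X, c) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  sigma <- exp(par[p + 1])
  -tobit_loglik(y, X, beta, sigma, c)
}

tobit_negll_grad <- function(par, y, X, c) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  sigma <- exp(par[p + 1])
  eta <- drop(X %*% beta)
  cens <- y <= c
  gbeta <- numeric(p)
  glogs <- 0
  if (any(!cens)) {
    r <- (y[!cens] - eta[!cens]) / sigma
    gbeta <- gbeta + drop(crossprod(X[!cens, , drop = FALSE], r / sigma))
    glogs <- glogs + sum(r^2 - 1)
  }
  if (any(cens)) {
    z <- (c - eta[cens]) / sigma
    lambda <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
    gbeta <- gbeta - drop(crossprod(X[cens, , drop = FALSE], lambda / sigma))
    glogs <- glogs - sum(lambda * z)
  }
  -c(gbeta, glogs)
}

#' Maximum-likelihood fit of the Tobit model
#'
#' Quasi-Newton (BFGS) optimisation in (beta, log sigma) with the analytic
#' gradient, started from the ordinary least-squares fit; an optional
#' second start lets likelihood-ratio callers seed the full model from the
#' reduced solution so the statistic can never go negative.
#'
#' @param y response vector.
#' @param X design matrix.
#' @param c censoring threshold.
#' @param start optional additional start `c(beta, log sigma)`.
#' @param maxit,reltol optimiser controls.
#' @return an object of class `tobit_fit`: coefficients, `sigma`, `c`,
#'   `loglik`, `n_params`, `converged`.
#' @export
tobit_fit <- function(y, X, c = 0, start = NULL, maxit = 500, reltol = 1e-10) {
  X <- as.matrix(X)
  p <- ncol(X)
  ols <- stats::lm.fit(X, y)
  s0 <- sd(ols$residuals)
  if (!is.finite(s0) || s0 < 0.05) s0 <- 0.05
  starts <- list(c(ifelse(is.finite(ols$coefficients), ols$coefficients, 0),
                   log(s0)))
  if (!is.null(start)) starts <- c(starts, list(start))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, tobit_negll, tobit_negll_grad, y = y, X = X, c = c,
            method = "BFGS", control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    # genes with (near-)zero residual variance drive sigma to 0 and the
    # likelihood to infinity; refit with a floored scale in that case
    if (is.null(fit) || fit$convergence != 0 || fit$par[p + 1] < log(1e-3)) {
      fit2 <- tryCatch(
        optim(st, tobit_negll, tobit_negll_grad, y = y, X = X, c = c,
              method = "L-BFGS-B",
              lower = c(rep(-Inf, p), log(1e-3)),
              upper = c(rep(Inf, p), log(1e4)),
              control = list(maxit = maxit)),
        error = function(e) NULL)
      if (!is.null(fit2) &&
          (is.null(fit) || fit$convergence != 0 || fit2$value < fit$value))
        fit <- fit2
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("tobit fit failed")
  beta <- unname(best$par[seq_len(p)])
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, sigma = unname(exp(best$par[p + 1])),
                 c = c, loglik = -best$value, n_params = p + 1,
                 converged = best$convergence == 0),
            class = "tobit_fit")
}

#' @export
print.tobit_fit <- function(x, ...) {
  cat(sprintf("tobit_fit: %d coefficients, sigma = %.4g, logLik = %.4f\n",
              length(x$coefficients), x$sigma, x$loglik))
  invisible(x)
}

# Tobit likelihood-ratio test of a full design against the intercept-only
# reduced model; returns NA p for non-convergent or degenerate genes.
tobit_lrt <- function(y, X_full, c) {
  cens <- y <= c
  if (all(cens) || var(y) < 1e-12)
    return(list(stat = 0, loglik_full = NA, loglik_red = NA, ok = TRUE,
                degenerate = TRUE))
  red <- tryCatch(tobit_fit(y, matrix(1, length(y)), c = c),
                  error = function(e) NULL)
  if (is.null(red)) return(list(stat = NA, ok = FALSE, degenerate = FALSE))
  start_full <- c(red$coefficients[1], rep(0, ncol(X_full) - 1),
                  log(red$sigma))
  full <- tryCatch(tobit_fit(y, X_full, c = c, start = start_full),
                   error = function(e) NULL)
  if (is.null(full)) return(list(stat = NA, ok = FALSE, degenerate = FALSE))
  stat <- max(0, 2 * (full$loglik - red$loglik))
  list(stat = stat, loglik_full = full$loglik, loglik_red = red$loglik,
       ok = full$converged && red$converged, degenerate = FALSE)
}

finish_dyn_result <- function(res, cfg, expr_col = "expressed_frac") {
  ok <- !is.na(res$p)
  res$q <- NA_real_
  res$q[ok] <- p.adjust(res$p[ok], method = "BH")
  res$significant <- ok & res$p < cfg$de_p & res$q < cfg$de_fdr &
    res[[expr_col]] > cfg$de_expr_frac
  class(res) <- c("DynTestResult", "data.frame")
  res
}

extract_log_values <- function(m) {
  if (inherits(m, "ExpressionMatrix")) {
    if (m$unit != "log10cpm1")
      stop("expected unit 'log10cpm1', got '", m$unit,
           "' (use log10_cpm1() first)")
    m$values
  } else as.matrix(m)
}

#' State-wise differential expression by Tobit likelihood-ratio test
#'
#' Per gene, compares the full Tobit model with a state factor design
#' (~ state) against the intercept-only reduced model (~ 1); the statistic
#' is referred to a chi-square distribution with (number of states - 1)
#' degrees of freedom. P-values are BH-adjusted across tested genes and a
#' gene is called significant when p < 0.01, q < 0.1 and it is expressed
#' (above the censoring threshold) in more than 50\% of the tested cells
#' (thresholds from the config). States with fewer than 3 cells are
#' excluded with a warning; non-convergent genes get NA and are excluded
#' from the BH adjustment.
#'
#' @param m `ExpressionMatrix` with unit log10cpm1 (or a bare matrix on
#'   that scale).
#' @param states factor of state labels, one per cell.
#' @param cfg an `AnalysisConfig`.
#' @return a data.frame of class `DynTestResult` with per-gene columns
#'   gene_id, stat, df, p, q, expressed_frac, significant.
#' @export
de_test_states <- function(m, states, cfg = analysis_config()) {
  v <- extract_log_values(m)
  states <- droplevels(as.factor(states))
  if (length(states) != nrow(v)) stop("one state per cell required")
  if (nlevels(states) < 2) stop("need at least 2 states")
  tab <- table(states)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warning("state(s) with fewer than 3 cells excluded: ",
            paste(small, collapse = ", "))
    keep <- !states %in% small
    v <- v[keep, , drop = FALSE]
    states <- droplevels(states[keep])
    if (nlevels(states) < 2) stop("need at least 2 states after exclusion")
  }
  X <- model.matrix(~states)
  df <- nlevels(states) - 1
  c0 <- cfg$censor_threshold
  res <- data.frame(gene_id = colnames(v), stat = NA_real_, df = df,
                    p = NA_real_, expressed_frac = NA_real_,
                    stringsAsFactors = FALSE)
  for (g in seq_len(ncol(v))) {
    y <- v[, g]
    res$expressed_frac[g] <- mean(y > c0)
    lrt <- tobit_lrt(y, X, c0)
    if (!isTRUE(lrt$ok)) next
    res$stat[g] <- lrt$stat
    res$p[g] <- pchisq(lrt$stat, df = df, lower.tail = FALSE)
  }
  finish_dyn_result(res, cfg)
}

#' Pseudotime-dependent gene test along one branch
#'
#' Per gene, the full Tobit model uses a natural cubic spline basis of
#' pseudotime (df = 3, the default of the spline smoother the trajectory
#' framework applies) against the intercept-only reduced model; chi-square
#' with df = 3. Cells must come from a single root-to-tip branch path.
#' Significance uses the same three-part rule as [de_test_states()],
#' with the expressed fraction evaluated over the tested cells.
#'
#' @param m `ExpressionMatrix` with unit log10cpm1 (or matrix).
#' @param pseudotime numeric vector, one value per cell.
#' @param cfg an `AnalysisConfig` (fields `spline_df`, `censor_threshold`,
#'   `de_p`, `de_fdr`, `de_expr_frac`).
#' @return a data.frame of class `DynTestResult`.
#' @export
dynamic_gene_test <- function(m, pseudotime, cfg = analysis_config()) {
  v <- extract_log_values(m)
  if (length(pseudotime) != nrow(v)) stop("one pseudotime per cell required")
  if (nrow(v) < 20) stop("need at least 20 cells in the branch")
  basis <- splines::ns(pseudotime, df = cfg$spline_df)
  X <- cbind(1, basis)
  df <- cfg$spline_df
  c0 <- cfg$censor_threshold
  res <- data.frame(gene_id = colnames(v), stat = NA_real_, df = df,
                    p = NA_real_, expressed_frac = NA_real_,
                    stringsAsFactors = FALSE)
  for (g in seq_len(ncol(v))) {
    y <- v[, g]
    res$expressed_frac[g] <- mean(y > c0)
    lrt <- tobit_lrt(y, X, c0)
    if (!isTRUE(lrt$ok)) next
    res$stat[g] <- lrt$stat
    res$p[g] <- pchisq(lrt$stat, df = df, lower.tail = FALSE)
  }
  finish_dyn_result(res, cfg)
}

#' Smoothed standardised pseudotime trends for a gene set
#'
#' Fits each gene's expression on a natural-spline basis of pseudotime by
#' least squares, evaluates the fitted curve on an equally spaced grid
#' spanning the observed pseudotime range, and z-scores each curve; genes
#' with a flat fitted curve map to zero.
#'
#' @param m `ExpressionMatrix` (log10cpm1) or matrix.
#' @param pseudotime numeric per-cell pseudotime.
#' @param genes gene ids to include.
#' @param grid_n grid resolution (default 100 points).
#' @param df spline degrees of freedom.
#' @return genes x grid matrix of standardised trends.
#' @export
trend_matrix <- function(m, pseudotime, genes, grid_n = 100, df = 3) {
  v <- extract_log_values(m)
  v <- v[, genes, drop = FALSE]
  grid <- seq(min(pseudotime), max(pseudotime), length.out = grid_n)
  basis <- splines::ns(pseudotime, df = df)
  Xg <- cbind(1, predict(basis, grid))
  X <- cbind(1, basis)
  coefs <- qr.coef(qr(X), v)           # least squares for all genes at once
  fitted <- t(Xg %*% coefs)            # genes x grid
  ctr <- fitted - rowMeans(fitted)
  s <- sqrt(rowMeans(ctr^2))
  out <- ctr / ifelse(s > 1e-12, s, 1)
  out[s <= 1e-12, ] <- 0
  rownames(out) <- genes
  out
}

#' Cluster pseudotime trends with a silhouette-chosen number of clusters
#'
#' Hierarchical clustering (Euclidean distance, Ward's ward.D2 linkage) of
#' standardised trend vectors; the number of clusters is the value in
#' `k_range` maximising the mean silhouette width. When the best mean
#' silhouette falls below `min_silhouette` the genes are regarded as one
#' undivided trend and a single cluster is returned with a warning, which
#' also guards the degenerate all-identical case.
#'
#' @param trends genes x grid matrix (e.g. from [trend_matrix()]).
#' @param k_range candidate cluster numbers (default 2:6).
#' @param min_silhouette acceptance floor for the best mean silhouette.
#' @return list with `cluster` (named integer vector), `k`, and
#'   `silhouette` (data.frame of k vs mean silhouette width).
#' @export
cluster_trends <- function(trends, k_range = 2:6, min_silhouette = 0.25) {
  n <- nrow(trends)
  if (n < 2) stop("need at least 2 genes to cluster")
  if (n <= min(k_range)) {
    warning("fewer genes than the smallest cluster number; single cluster")
    return(list(cluster = setNames(rep(1L, n), rownames(trends)), k = 1L,
                silhouette = data.frame(k = integer(), mean_sil = numeric())))
  }
  k_range <- k_range[k_range < n]
  d <- dist(trends)
  hc <- hclust(d, method = "ward.D2")
  sil <- vapply(k_range, function(k) {
    cl <- cutree(hc, k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  best <- which.max(sil)
  if (sil[best] < min_silhouette) {
    warning(sprintf("best mean silhouette %.3f below %.2f; single cluster",
                    sil[best], min_silhouette))
    cl <- setNames(rep(1L, n), rownames(trends))
    k <- 1L
  } else {
    k <- k_range[best]
    cl <- cutree(hc, k)
    names(cl) <- rownames(trends)
  }
  list(cluster = cl, k = k,
       silhouette = data.frame(k = k_range, mean_sil = sil))
}

#' Quadratic trend-line fit with a standard-error band
#'
#' Ordinary least squares of the averaged trend on {1, t, t^2} (the
#' y ~ poly(x, 2) smoother), with a pointwise confidence band from the fit
#' covariance at the requested level (default 0.95).
#'
#' @param t pseudotime values (at least 4, not all equal).
#' @param y trend values.
#' @param level band coverage level.
#' @param grid_n resolution of the returned band.
#' @return list of class `TrendCurve`: `coefficients` (intercept, linear,
#'   quadratic), `vcov`, `sigma`, and `band` (data.frame t, fit, lower,
#'   upper).
#' @export
fit_trend_curve <- function(t, y, level = 0.95, grid_n = 100) {
  if (length(t) < 4) stop("need at least 4 points")
  if (length(unique(t)) == 1) stop("design is rank deficient: all t equal")
  fit <- lm(y ~ t + I(t^2))
  grid <- seq(min(t), max(t), length.out = grid_n)
  pr <- predict(fit, newdata = data.frame(t = grid), se.fit = TRUE)
  crit <- qt((1 + level) / 2, df = fit$df.residual)
  structure(list(
    coefficients = setNames(coef(fit), c("intercept", "linear", "quadratic")),
    vcov = vcov(fit), sigma = summary(fit)$sigma,
    band = data.frame(t = grid, fit = pr$fit,
                      lower = pr$fit - crit * pr$se.fit,
                      upper = pr$fit + crit * pr$se.fit)),
    class = "TrendCurve")
}
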
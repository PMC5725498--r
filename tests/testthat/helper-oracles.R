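# Independent oracle implementations used across tests. These deliberately
# use plain loops / textbook formulas, not the package's vectorised paths.

bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

kl_oracle <- function(probs, pbar) {
  s <- numeric(nrow(probs))
  for (i in seq_len(nrow(probs))) {
    acc <- 0
    for (j in seq_len(ncol(probs))) {
      pij <- probs[i, j]
      if (pij > 0) acc <- acc + pij * log(pij / pbar[j])
    }
    s[i] <- acc
  }
  s
}

tobit_loglik_oracle <- function(y, X, beta, sigma, cc) {
  ll <- 0
  for (i in seq_along(y)) {
    mu <- sum(X[i, ] * beta)
    if (y[i] > cc) {
      ll <- ll + dnorm((y[i] - mu) / sigma, log = TRUE) - log(sigma)
    } else {
      ll <- ll + pnorm((cc - mu) / sigma, log.p = TRUE)
    }
  }
  ll
}

pearson_oracle <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# exhaustive re-application of the divergence rules, written independently
divergence_oracle <- function(genes, ptab, bexpr) {
  bset <- function(g) {
    if (!g %in% rownames(bexpr)) character(0)
    else colnames(bexpr)[bexpr[g, ]]
  }
  out <- character(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    partners <- character(0)
    for (r in seq_len(nrow(ptab))) {
      if (ptab$gene_id[r] == g) partners <- c(partners, ptab$paralog_id[r])
      if (ptab$paralog_id[r] == g) partners <- c(partners, ptab$gene_id[r])
    }
    partners <- unique(partners)
    if (length(partners) == 0) { out[i] <- "unclassifiable"; next }
    expressed <- partners[vapply(partners, function(p) length(bset(p)) > 0,
                                 logical(1))]
    if (length(expressed) == 0) { out[i] <- "unclassifiable"; next }
    gs <- bset(g)
    div <- FALSE
    for (p in expressed)
      if (!setequal(bset(p), gs)) div <- TRUE
    out[i] <- if (div) "diverged" else "conserved"
  }
  out
}
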
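#' Specification of the feed-forward lineage classifier
#'
#' The network maps a cell's standardised expression vector to softmax
#' probabilities over the differentiated lineages: two hidden layers of 100
#' and 50 rectified-linear nodes, L2 weight decay with lambda = 0.001 on all
#' weight matrices, and Gaussian dropout with rate 0.8 between the hidden
#' layers. Gaussian dropout rate r multiplies activations by N(1, r/(1-r))
#' noise during training, so rate 0.8 means noise standard deviation 2; the
#' alternative "keep probability 0.8" reading would give sd 0.5 and is not
#' used here. Training minimises categorical cross-entropy with the Adam
#' optimiser on minibatches, holds out a stratified validation fraction
#' (default 20\%), and stops early on the validation loss.
#'
#' @param hidden hidden layer sizes.
#' @param l2 weight-decay coefficient lambda.
#' @param gaussian_dropout Gaussian dropout rate between the hidden layers.
#' @param val_frac validation fraction of the input data.
#' @param max_epochs,patience training length and early-stopping patience.
#' @param lr,batch_size Adam learning rate and minibatch size.
#' @param seed RNG seed controlling the split, initialisation, shuffling
#'   and dropout noise.
#' @return a list of class `ClassifierSpec`.
#' @export
classifier_spec <- function(hidden = c(100, 50), l2 = 0.001,
                            gaussian_dropout = 0.8, val_frac = 0.2,
                            max_epochs = 60, patience = 8, lr = 1e-3,
                            batch_size = 64, seed = 1L) {
  stopifnot(all(hidden > 0), l2 >= 0,
            gaussian_dropout >= 0, gaussian_dropout < 1,
            val_frac > 0, val_frac < 1)
  structure(as.list(environment()), class = c("ClassifierSpec", "list"))
}

#' Per-gene z-score standardisation
#'
#' Centres and scales each gene by its mean and population standard
#' deviation (divisor n). When `stats` is supplied (the prediction path)
#' those statistics are applied unchanged, with no re-centering on the new
#' data; genes with zero standard deviation map to 0.
#'
#' @param m numeric cells-by-genes matrix or `ExpressionMatrix`.
#' @param stats optional list with `mean` and `sd` vectors from a previous
#'   call.
#' @return list with `values` (standardised matrix) and `stats`.
#' @export
standardize <- function(m, stats = NULL) {
  x <- if (inherits(m, "ExpressionMatrix")) m$values else as.matrix(m)
  if (is.null(stats)) {
    mu <- colMeans(x)
    sd_pop <- sqrt(colMeans(x^2) - mu^2)
    sd_pop[sd_pop < 1e-12] <- 0
    stats <- list(mean = mu, sd = sd_pop)
  }
  denom <- ifelse(stats$sd > 0, stats$sd, 1)
  z <- sweep(sweep(x, 2, stats$mean, "-"), 2, denom, "/")
  z[, stats$sd == 0] <- 0
  list(values = z, stats = stats)
}

relu <- function(z) { z[z < 0] <- 0; z }

softmax_rows <- function(z) {
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

mlp_forward <- function(w, x, noise_sd = 0) {
  z1 <- x %*% w$W1
  z1 <- sweep(z1, 2, w$b1, "+")
  h1 <- relu(z1)
  d <- NULL
  if (noise_sd > 0) {
    d <- matrix(rnorm(length(h1), 1, noise_sd), nrow(h1))
    h1d <- h1 * d
  } else h1d <- h1
  z2 <- sweep(h1d %*% w$W2, 2, w$b2, "+")
  h2 <- relu(z2)
  z3 <- sweep(h2 %*% w$W3, 2, w$b3, "+")
  list(z1 = z1, h1 = h1, d = d, h1d = h1d, z2 = z2, h2 = h2,
       p = softmax_rows(z3))
}

mlp_loss <- function(w, p, y, l2) {
  ce <- -mean(log(pmax(p[cbind(seq_len(nrow(p)), y)], 1e-12)))
  ce + l2 * (sum(w$W1^2) + sum(w$W2^2) + sum(w$W3^2))
}

#' Train the lineage classifier
#'
#' @param m cells-by-genes matrix or `ExpressionMatrix` (typically
#'   log10(CPM+1) values of the genes surviving the expression filter).
#' @param labels factor of lineage labels, one per cell; every level must
#'   have at least two cells.
#' @param spec a `ClassifierSpec`.
#' @return an object of class `haem_classifier`: standardisation stats,
#'   layer weights, class order, gene ids, and the per-epoch training
#'   history with final validation metrics.
#' @export
train_classifier <- function(m, labels, spec = classifier_spec()) {
  x_all <- if (inherits(m, "ExpressionMatrix")) m$values else as.matrix(m)
  labels <- droplevels(as.factor(labels))
  if (length(labels) != nrow(x_all)) stop("one label per cell required")
  tab <- table(labels)
  if (any(tab < 2))
    stop("class(es) with fewer than 2 cells: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  set.seed(spec$seed)
  classes <- levels(labels)
  k <- length(classes)
  # stratified validation split
  val_idx <- unlist(lapply(classes, function(cl) {
    idx <- which(labels == cl)
    sample(idx, max(1, round(spec$val_frac * length(idx))))
  }))
  tr_idx <- setdiff(seq_len(nrow(x_all)), val_idx)
  std <- standardize(x_all[tr_idx, , drop = FALSE])
  x_tr <- std$values
  x_val <- standardize(x_all[val_idx, , drop = FALSE], std$stats)$values
  y_tr <- as.integer(labels[tr_idx])
  y_val <- as.integer(labels[val_idx])
  d <- ncol(x_tr)
  h <- spec$hidden
  he <- function(n_in, n_out) matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)),
                                     n_in, n_out)
  w <- list(W1 = he(d, h[1]), b1 = rep(0, h[1]),
            W2 = he(h[1], h[2]), b2 = rep(0, h[2]),
            W3 = he(h[2], k), b3 = rep(0, k))
  adam_m <- lapply(w, function(p) p * 0)
  adam_v <- lapply(w, function(p) p * 0)
  step <- 0
  noise_sd <- sqrt(spec$gaussian_dropout / (1 - spec$gaussian_dropout))
  onehot <- function(y) { m0 <- matrix(0, length(y), k)
                          m0[cbind(seq_along(y), y)] <- 1; m0 }
  history <- data.frame()
  best <- list(loss = Inf, w = w, epoch = 0)
  wait <- 0
  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample(length(tr_idx))
    for (start in seq(1, length(ord), by = spec$batch_size)) {
      b <- ord[start:min(start + spec$batch_size - 1, length(ord))]
      xb <- x_tr[b, , drop = FALSE]
      yb <- onehot(y_tr[b])
      f <- mlp_forward(w, xb, noise_sd)
      nb <- length(b)
      dz3 <- (f$p - yb) / nb
      g <- list()
      g$W3 <- crossprod(f$h2, dz3) + 2 * spec$l2 * w$W3
      g$b3 <- colSums(dz3)
      dh2 <- tcrossprod(dz3, w$W3)
      dz2 <- dh2 * (f$z2 > 0)
      g$W2 <- crossprod(f$h1d, dz2) + 2 * spec$l2 * w$W2
      g$b2 <- colSums(dz2)
      dh1d <- tcrossprod(dz2, w$W2)
      dh1 <- if (is.null(f$d)) dh1d else dh1d * f$d
      dz1 <- dh1 * (f$z1 > 0)
      g$W1 <- crossprod(xb, dz1) + 2 * spec$l2 * w$W1
      g$b1 <- colSums(dz1)
      step <- step + 1
      for (nm in names(w)) {
        adam_m[[nm]] <- 0.9 * adam_m[[nm]] + 0.1 * g[[nm]]
        adam_v[[nm]] <- 0.999 * adam_v[[nm]] + 0.001 * g[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - 0.9^step)
        vhat <- adam_v[[nm]] / (1 - 0.999^step)
        w[[nm]] <- w[[nm]] - spec$lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
    p_tr <- mlp_forward(w, x_tr)$p
    p_val <- mlp_forward(w, x_val)$p
    row <- data.frame(
      epoch = epoch,
      loss = mlp_loss(w, p_tr, y_tr, spec$l2),
      accuracy = mean(max.col(p_tr) == y_tr),
      val_loss = mlp_loss(w, p_val, y_val, spec$l2),
      val_accuracy = mean(max.col(p_val) == y_val))
    history <- rbind(history, row)
    if (row$val_loss < best$loss - 1e-6) {
      best <- list(loss = row$val_loss, w = w, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= spec$patience) break
    }
  }
  structure(list(stats = std$stats, weights = best$w, classes = classes,
                 genes = colnames(x_all), spec = spec, history = history,
                 best_epoch = best$epoch,
                 validation = history[history$epoch == best$epoch,
                                      c("val_loss", "val_accuracy")]),
            class = "haem_classifier")
}

#' @export
print.haem_classifier <- function(x, ...) {
  cat(sprintf(
    "haem_classifier: %d genes -> %s -> %d classes (%s)\n",
    length(x$genes), paste(x$spec$hidden, collapse = "/"),
    length(x$classes), paste(x$classes, collapse = ", ")))
  cat(sprintf("  best epoch %d: val_loss %.4f, val_accuracy %.3f\n",
              x$best_epoch, x$validation$val_loss, x$validation$val_accuracy))
  invisible(x)
}

#' Predict lineage probabilities for cells
#'
#' Genes are matched to the training gene set by identifier; genes absent
#' from the input are imputed as 0 after standardisation (the training
#' mean) with a warning. Dropout is disabled at prediction, so the output
#' is deterministic.
#'
#' @param model a `haem_classifier`.
#' @param m cells-by-genes matrix or `ExpressionMatrix` with gene ids.
#' @return matrix of class probabilities (cells x classes), rows summing
#'   to 1.
#' @export
predict_probabilities <- function(model, m) {
  x <- if (inherits(m, "ExpressionMatrix")) m$values else as.matrix(m)
  if (nrow(x) == 0) stop("empty input")
  if (is.null(colnames(x))) stop("input must carry gene ids as column names")
  z <- matrix(0, nrow(x), length(model$genes),
              dimnames = list(rownames(x), model$genes))
  common <- intersect(model$genes, colnames(x))
  n_missing <- length(model$genes) - length(common)
  if (n_missing > 0)
    warning(n_missing, " training gene(s) absent from input; imputed as 0")
  sub_stats <- list(mean = model$stats$mean[match(common, model$genes)],
                    sd = model$stats$sd[match(common, model$genes)])
  z[, common] <- standardize(x[, common, drop = FALSE], sub_stats)$values
  p <- mlp_forward(model$weights, z)$p
  colnames(p) <- model$classes
  rownames(p) <- rownames(x)
  p
}

#' @export
predict.haem_classifier <- function(object, newdata, ...) {
  predict_probabilities(object, newdata)
}
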
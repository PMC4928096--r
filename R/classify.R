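#' Leave-one-out nu-SVM classification
#'
#' One LOO fold per sample: the training split is normalized per
#' dimension by subtracting its median and dividing by its MAD (with an
#' epsilon floor on zero MADs), the held-out sample is mapped with the
#' training constants (no leakage), and a nu-SVM (`nu = 0.5`) with a
#' radial basis kernel and `gamma = 1/n_features` is trained and queried.
#'
#' @param X numeric matrix or data.frame of features (rows = samples).
#' @param labels factor or character vector of two classes.
#' @param nu nu parameter, default 0.5.
#' @param gamma kernel width; default `1/ncol(X)`.
#' @return object of class `classification_result`: `confusion` (2 x 2
#'   row percentages), `accuracy` (percent), `predictions`, `labels`.
#' @export
loo_classify <- function(X, labels, nu = 0.5, gamma = NULL) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("exactly two classes required")
  if (min(table(labels)) < 2) stop("need >= 2 samples per class")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  n <- nrow(X)
  preds <- factor(rep(NA_character_, n), levels = levels(labels))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (nlevels(droplevels(labels[tr])) < 2)
      stop("a training fold lost a class entirely")
    nrm <- median_mad_normalizer(X[tr, , drop = FALSE])
    fit <- e1071::svm(nrm$apply(X[tr, , drop = FALSE]), labels[tr],
                      type = "nu-classification", kernel = "radial",
                      nu = nu, gamma = gamma, scale = FALSE)
    preds[i] <- stats::predict(fit, nrm$apply(X[i, , drop = FALSE]))
  }
  confusion_result(labels, preds)
}

median_mad_normalizer <- function(Xtr, eps = 1e-12) {
  med <- apply(Xtr, 2, stats::median)
  mads <- apply(Xtr, 2, stats::mad, constant = 1)
  zero <- mads < eps
  if (any(zero)) {
    warning(sum(zero), " dimension(s) with zero training MAD; ",
            "epsilon floor applied")
    mads[zero] <- eps
  }
  list(apply = function(M)
    sweep(sweep(as.matrix(M), 2, med), 2, mads, "/"))
}

confusion_result <- function(labels, preds) {
  tab <- table(truth = labels, pred = preds)
  conf <- 100 * prop.table(tab, 1)
  acc <- 100 * mean(preds == labels)
  structure(list(confusion = conf, accuracy = acc,
                 predictions = preds, labels = labels),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("LOO classification: accuracy %.2f%%\n", x$accuracy))
  print(round(x$confusion, 2))
  invisible(x)
}

# kernel-space weight criterion W2 = sum alpha_i alpha_j y_i y_j K_ij of
# a trained nu-SVM, and its change when one feature is removed (RBF
# kernels factorize, so removal divides K elementwise)
rfe_criteria <- function(Xn, y, nu, gamma) {
  fit <- e1071::svm(Xn, y, type = "nu-classification", kernel = "radial",
                    nu = nu, gamma = gamma, scale = FALSE)
  sv <- fit$SV
  co <- fit$coefs            # alpha_i * y_i
  d2 <- as.matrix(stats::dist(sv))^2
  K <- exp(-gamma * d2)
  W2 <- drop(t(co) %*% K %*% co)
  vapply(seq_len(ncol(Xn)), function(f) {
    df <- outer(sv[, f], sv[, f], "-")^2
    Kf <- K * exp(gamma * df)          # kernel without feature f
    W2f <- drop(t(co) %*% Kf %*% co)
    abs(W2 - W2f)                      # small change = uninformative
  }, numeric(1))
}

#' Nonlinear SVM-RFE feature ranking with correlation-bias reduction
#'
#' Within each leave-one-out training fold, features are eliminated
#' recursively: at every step a radial-basis nu-SVM is trained on the
#' surviving (median/MAD normalized) features and the feature whose
#' removal changes the kernel-space weight criterion
#' `W^2 = sum alpha_i alpha_j y_i y_j K(x_i, x_j)` the least is dropped.
#' Features whose pairwise correlation within the fold exceeds
#' `cor_threshold` are grouped and scored by the group's average
#' criterion before elimination, reducing the bias against correlated
#' informative features. Ties break on the original feature index. The
#' per-feature median rank over folds is reported (rank 1 = retained
#' longest), with an accuracy-versus-top-k curve recomputed by
#' [loo_classify()] on the top-k features.
#'
#' @inheritParams loo_classify
#' @param cor_threshold correlation-grouping threshold, default 0.95.
#' @param curve if TRUE compute the accuracy-vs-top-k curve.
#' @return list `ranks` (median rank per feature), `rank_matrix`
#'   (folds x features), `curve` (data.frame k, accuracy, or NULL).
#' @export
svm_rfe_rank <- function(X, labels, nu = 0.5, gamma = NULL,
                         cor_threshold = 0.95, curve = FALSE) {
  X <- as.matrix(X)
  labels <- factor(labels)
  nfeat <- ncol(X)
  if (is.null(gamma)) gamma <- 1 / nfeat
  n <- nrow(X)
  if (nfeat == 1) {
    res <- loo_classify(X, labels, nu = nu, gamma = gamma)
    return(list(ranks = 1,
                rank_matrix = matrix(1, n, 1),
                curve = data.frame(k = 1, accuracy = res$accuracy)))
  }
  RK <- matrix(NA_integer_, n, nfeat)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    nrm <- median_mad_normalizer(X[tr, , drop = FALSE])
    Xn <- nrm$apply(X[tr, , drop = FALSE])
    y <- droplevels(labels[tr])
    surviving <- seq_len(nfeat)
    rank_pos <- nfeat
    while (length(surviving) > 1) {
      crit <- rfe_criteria(Xn[, surviving, drop = FALSE], y, nu, gamma)
      # correlation-bias reduction: pool the criterion over groups of
      # highly correlated surviving features
      cm <- suppressWarnings(stats::cor(Xn[, surviving, drop = FALSE]))
      cm[!is.finite(cm)] <- 0
      groups <- cor_groups(cm, cor_threshold)
      gcrit <- vapply(seq_along(surviving), function(q)
        mean(crit[groups == groups[q]]), numeric(1))
      drop_q <- which(gcrit == min(gcrit))[1]   # stable index tie-break
      RK[i, surviving[drop_q]] <- rank_pos
      rank_pos <- rank_pos - 1L
      surviving <- surviving[-drop_q]
    }
    RK[i, surviving] <- 1L
  }
  med_rank <- apply(RK, 2, stats::median)
  cv <- NULL
  if (curve) {
    ord <- order(med_rank, seq_len(nfeat))
    cv <- data.frame(k = seq_len(nfeat), accuracy = NA_real_)
    for (k in seq_len(nfeat)) {
      cv$accuracy[k] <- loo_classify(X[, ord[seq_len(k)], drop = FALSE],
                                     labels, nu = nu,
                                     gamma = gamma)$accuracy
    }
  }
  list(ranks = med_rank, rank_matrix = RK, curve = cv)
}

# single-linkage grouping of features with |cor| above the threshold
cor_groups <- function(cm, threshold) {
  p <- ncol(cm)
  grp <- seq_len(p)
  for (a in seq_len(p - 1)) for (b in (a + 1):p) {
    if (abs(cm[a, b]) > threshold) {
      gb <- grp[b]; ga <- grp[a]
      grp[grp == gb] <- ga
    }
  }
  grp
}
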
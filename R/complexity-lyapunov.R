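#' Fit a sparse cubic NAR model by Fast Orthogonal Search
#'
#' Candidate regressors are all Laguerre monomials up to order three —
#' `l_i`, `l_i l_j` (i <= j) and `l_i l_j l_k` (i <= j <= k) of the
#' Laguerre-filtered differenced history, plus a constant. Terms are
#' added greedily by the reduction of residual variance of their
#' orthogonalized (Gram-Schmidt against the selected set) versions,
#' stopping when the best marginal relative reduction falls below
#' `threshold` or candidates are exhausted. Unselected coefficients are
#' zero, so the returned model is sparse.
#'
#' @param series_window differenced-interval sequence (seconds).
#' @param basis a [laguerre_basis()]; its functions generate the
#'   candidate monomials.
#' @param P number of Laguerre functions entering the monomials
#'   (default: all in the basis).
#' @param threshold marginal relative residual-variance reduction below
#'   which selection stops, default 1e-4.
#' @return a cubic [narl_parameters()] (shape set to 1; only the mean
#'   polynomial is estimated here) with attribute `selected` listing the
#'   chosen term labels, and `residual_sd`.
#' @export
fit_cubic_nar <- function(series_window, basis, P = NULL,
                          threshold = 1e-4) {
  d <- as.numeric(series_window)
  Tn <- basis$truncation
  if (is.null(P)) P <- basis$num_functions
  # candidate count: constant + P + C(P+1,2) + C(P+2,3)
  n_cand <- 1 + P + P * (P + 1) / 2 + P * (P + 1) * (P + 2) / 6
  if (length(d) < Tn + 1 + 3 * n_cand)
    stop("window too short for the candidate set (need >= 3 terms each)")
  E <- stats::embed(d, Tn + 1)           # col 1 newest
  y <- E[, 1]
  Lm <- E[, -1, drop = FALSE] %*%
    t(basis$basis_matrix[seq_len(P), , drop = FALSE])
  terms <- cubic_term_table(P)
  X <- matrix(1, nrow(Lm), nrow(terms))
  for (c in seq_len(nrow(terms))) {
    tr <- terms[c, ]
    if (tr$order >= 1) X[, c] <- Lm[, tr$i]
    if (tr$order >= 2) X[, c] <- X[, c] * Lm[, tr$j]
    if (tr$order >= 3) X[, c] <- X[, c] * Lm[, tr$k]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient candidate set on this window")

  sel <- integer(0)
  Q <- NULL
  res <- y
  tss <- sum(y^2)
  repeat {
    remaining <- setdiff(seq_len(ncol(X)), sel)
    if (length(remaining) == 0) break
    red <- vapply(remaining, function(c) {
      v <- X[, c]
      if (!is.null(Q)) v <- v - Q %*% crossprod(Q, v)
      nv <- sum(v^2)
      if (nv < 1e-12 * sum(X[, c]^2)) return(0)
      sum(v * res)^2 / nv
    }, numeric(1))
    best <- which.max(red)
    if (red[best] < threshold * tss) break
    c <- remaining[best]
    v <- X[, c]
    if (!is.null(Q)) v <- v - Q %*% crossprod(Q, v)
    v <- v / sqrt(sum(v^2))
    Q <- cbind(Q, v)
    res <- res - v * sum(v * res)
    sel <- c(sel, c)
  }

  g0 <- 0
  g1 <- rep(0, P)
  g2 <- matrix(0, P, P)
  g3 <- array(0, c(P, P, P))
  rsd <- stats::sd(y)
  if (length(sel) > 0) {
    coef <- qr.coef(qr(X[, sel, drop = FALSE]), y)
    rsd <- stats::sd(y - X[, sel, drop = FALSE] %*% coef)
    for (s in seq_along(sel)) {
      tr <- terms[sel[s], ]
      b <- coef[s]
      if (tr$order == 0) g0 <- b
      else if (tr$order == 1) g1[tr$i] <- b
      else if (tr$order == 2) {
        share <- b / (if (tr$i == tr$j) 1 else 2)
        g2[tr$i, tr$j] <- g2[tr$i, tr$j] + share
        if (tr$i != tr$j) g2[tr$j, tr$i] <- g2[tr$j, tr$i] + share
      } else {
        ids <- c(tr$i, tr$j, tr$k)
        perms <- unique(perms3(ids))
        share <- b / length(perms)
        for (p in perms) g3[p[1], p[2], p[3]] <-
            g3[p[1], p[2], p[3]] + share
      }
    }
  }
  out <- narl_parameters(shape = 1, g0 = g0, g1 = g1, g2 = g2, g3 = g3)
  attr(out, "selected") <- terms$label[sel]
  attr(out, "residual_sd") <- rsd
  out
}

cubic_term_table <- function(P) {
  rows <- list(data.frame(order = 0L, i = NA_integer_, j = NA_integer_,
                          k = NA_integer_, label = "const"))
  for (i in seq_len(P))
    rows[[length(rows) + 1]] <- data.frame(order = 1L, i = i, j = NA, k = NA,
                                           label = sprintf("l%d", i))
  for (i in seq_len(P)) for (j in i:P)
    rows[[length(rows) + 1]] <- data.frame(order = 2L, i = i, j = j, k = NA,
                                           label = sprintf("l%d.l%d", i, j))
  for (i in seq_len(P)) for (j in i:P) for (k in j:P)
    rows[[length(rows) + 1]] <- data.frame(order = 3L, i = i, j = j, k = k,
                                           label = sprintf("l%d.l%d.l%d",
                                                           i, j, k))
  do.call(rbind, rows)
}

perms3 <- function(v) {
  p <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
            c(3, 1, 2), c(3, 2, 1))
  unique(lapply(p, function(i) v[i]))
}

#' Lyapunov exponents from a Jacobian chain by QR accumulation
#'
#' Successive Jacobians are accumulated by repeated QR factorization
#' (treppen iteration): with `J_j Q_(j-1) = Q_j R_j`, the i-th exponent
#' is `sum_j log R_(j)ii / (N * dt)`. Diagonal signs are normalized
#' positive at each step.
#'
#' @param jacobians list of square Jacobian matrices along the orbit.
#' @param dt time per step (1 for per-iteration exponents).
#' @param n_exp number of exponents to return.
#' @return numeric vector of exponents, decreasing.
#' @export
lyapunov_qr <- function(jacobians, dt = 1, n_exp = 2) {
  N <- length(jacobians)
  if (N == 0) stop("empty Jacobian chain")
  dim0 <- nrow(jacobians[[1]])
  n_exp <- min(n_exp, dim0)
  Q <- diag(dim0)
  acc <- rep(0, dim0)
  for (J in jacobians) {
    A <- J %*% Q
    qrA <- qr(A)
    Q <- qr.Q(qrA); R <- qr.R(qrA)
    s <- sign(diag(R)); s[s == 0] <- 1
    Q <- Q * rep(s, each = dim0)
    dR <- abs(diag(R))
    if (any(dR == 0)) return(rep(NA_real_, n_exp))
    acc <- acc + log(dR)
  }
  sort(acc / (N * dt), decreasing = TRUE)[seq_len(n_exp)]
}

# Jacobians of a fitted cubic NARL map along an observed differenced
# sequence, in companion form over the raw-lag state
# x_j = (d_j, ..., d_(j-T+1)); the first row is the chain-rule product
# of the polynomial gradient in Laguerre space with the basis matrix.
narl_jacobians <- function(params, basis, d_seq) {
  Tn <- basis$truncation
  phi <- basis$basis_matrix
  P <- basis$num_functions
  E <- stats::embed(d_seq, Tn)            # states, newest first per row
  n <- nrow(E)
  L <- E %*% t(phi)
  comp <- rbind(0, cbind(diag(Tn - 1), 0))
  lapply(seq_len(n), function(r) {
    l <- L[r, ]
    gl <- rep(0, P)
    if (length(params$g1)) gl[seq_along(params$g1)] <-
        gl[seq_along(params$g1)] + params$g1
    if (!is.null(params$g2)) {
      P2 <- nrow(params$g2)
      gl[seq_len(P2)] <- gl[seq_len(P2)] +
        2 * as.numeric(params$g2 %*% l[seq_len(P2)])
    }
    if (!is.null(params$g3)) {
      P3 <- dim(params$g3)[1]
      l3 <- l[seq_len(P3)]
      quad <- apply(params$g3, 1, function(m) drop(t(l3) %*% m %*% l3))
      gl[seq_len(P3)] <- gl[seq_len(P3)] + 3 * quad
    }
    J <- comp
    J[1, ] <- as.numeric(gl %*% phi)
    J
  })
}

#' Instantaneous Lyapunov exponents of the heartbeat series
#'
#' On a strided grid, a sparse cubic NAR model is refitted by
#' [fit_cubic_nar()] on the trailing window of the differenced interval
#' series; the companion-form Jacobians of the fitted map evaluated
#' along the observed states in that window are accumulated by QR
#' factorization, giving the first two exponents. Both per-beat
#' (nats/beat) and per-second (nats/s, divided by the window's mean
#' interval) values are reported; a singular Jacobian chain flags the
#' grid time missing.
#'
#' @param events an [event_series()].
#' @param traj a `parameter_trajectory` (supplies grid and window).
#' @param basis Laguerre basis for the cubic map; defaults to a compact
#'   `alpha = 0.1`, 2-function, 10-lag basis so the Jacobian state stays
#'   small.
#' @param stride evaluate every `stride`-th grid time.
#' @param threshold FOS stopping threshold.
#' @param window trailing window, seconds; defaults to the fitting
#'   window W.
#' @return object of class `lyapunov_estimate`: `times`, `lambda1`,
#'   `lambda2` (nats/s), `lambda1_beat`, `lambda2_beat` (nats/beat).
#' @export
lyapunov_spectrum <- function(events, traj, basis = NULL, stride = 1,
                              threshold = 1e-4, window = NULL) {
  if (is.null(basis)) basis <- laguerre_basis(0.1, 2, truncation = 10)
  W <- window %||% traj$config$window_W
  grid <- traj$grid_times
  idx <- seq(1, length(grid), by = stride)
  u <- events$event_times
  rr <- events$rr_intervals
  drr <- diff(rr)
  drr_t <- u[-(1:2)]                      # time at which each drr closes
  l1 <- l2 <- l1b <- l2b <- rep(NA_real_, length(idx))
  for (r in seq_along(idx)) {
    t <- grid[idx[r]]
    sel <- which(drr_t > t - W & drr_t <= t)
    if (length(sel) < basis$truncation + 12) next
    dwin <- drr[sel]
    fit <- tryCatch(
      fit_cubic_nar(dwin, basis, threshold = threshold),
      error = function(e) NULL)
    if (is.null(fit)) next
    J <- narl_jacobians(fit, basis, dwin)
    lam <- lyapunov_qr(J, dt = 1, n_exp = 2)
    if (any(!is.finite(lam))) next
    mean_rr <- mean(rr[sel])
    l1b[r] <- lam[1]; l2b[r] <- lam[2]
    l1[r] <- lam[1] / mean_rr; l2[r] <- lam[2] / mean_rr
  }
  structure(list(times = grid[idx], lambda1 = l1, lambda2 = l2,
                 lambda1_beat = l1b, lambda2_beat = l2b),
            class = "lyapunov_estimate")
}
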
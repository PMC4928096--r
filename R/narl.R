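#' NARL parameter set
#'
#' Time-varying parameter vector of the inverse-Gaussian point-process
#' model whose first moment is a Nonlinear Autoregressive model with
#' Laguerre expansion (NARL): shape `xi0 > 0`, constant `g0` (seconds),
#' linear coefficients `g1` (length P1), symmetric quadratic matrix `g2`
#' (P2 x P2) and optional symmetric cubic array `g3` (P3^3).
#'
#' @param shape inverse-Gaussian shape, > 0.
#' @param g0 zero-order coefficient, seconds.
#' @param g1 numeric vector of first-order coefficients (may be empty).
#' @param g2 symmetric matrix of second-order coefficients or NULL.
#' @param g3 symmetric 3-d array of third-order coefficients or NULL.
#' @return object of class `narl_parameters`.
#' @export
narl_parameters <- function(shape, g0 = 0, g1 = numeric(0), g2 = NULL,
                            g3 = NULL) {
  if (length(shape) != 1 || !is.finite(shape) || shape <= 0)
    stop("shape must be a positive scalar")
  if (!is.null(g2)) {
    g2 <- as.matrix(g2)
    if (nrow(g2) != ncol(g2) || max(abs(g2 - t(g2))) > 1e-12)
      stop("g2 must be symmetric")
  }
  if (!is.null(g3)) {
    if (length(dim(g3)) != 3 || length(unique(dim(g3))) != 1)
      stop("g3 must be a cubic array")
    for (p in list(c(2, 1, 3), c(1, 3, 2))) {
      if (max(abs(g3 - aperm(g3, p))) > 1e-12)
        stop("g3 must be symmetric under index permutation")
    }
  }
  structure(list(shape = shape, g0 = g0, g1 = as.numeric(g1),
                 g2 = g2, g3 = g3),
            class = "narl_parameters")
}

#' @export
print.narl_parameters <- function(x, ...) {
  cat(sprintf(
    "narl_parameters: xi0 = %.4g, g0 = %.4g, P1 = %d, P2 = %d, P3 = %d\n",
    x$shape, x$g0, length(x$g1),
    if (is.null(x$g2)) 0L else nrow(x$g2),
    if (is.null(x$g3)) 0L else dim(x$g3)[1]))
  invisible(x)
}

#' Instantaneous conditional mean of the next R-R interval
#'
#' The NARL first-moment model on the differenced interval series,
#' reconstructed to seconds by adding the most recent complete interval:
#' \deqn{\mu_{RR}(t) = RR_{\tilde N(t)} + g_0 + \sum_i g_1(i) l_i +
#'   \sum_{i,j} g_2(i,j) l_i l_j + \sum_{i,j,k} g_3(i,j,k) l_i l_j l_k.}
#'
#' @param params a [narl_parameters()].
#' @param coeffs Laguerre filter outputs: a `laguerre_coefficients` object
#'   from [filter_history()], or a bare numeric vector `l`.
#' @param last_rr most recent complete interval (seconds); taken from
#'   `coeffs` when it carries one.
#' @return the conditional mean, seconds. A non-positive value is
#'   returned as-is with attribute `valid = FALSE` so the caller (the
#'   fitter) can treat the step as infeasible.
#' @export
conditional_mean <- function(params, coeffs, last_rr = NULL) {
  l <- if (inherits(coeffs, "laguerre_coefficients")) coeffs$values
       else as.numeric(coeffs)
  if (is.null(last_rr)) {
    if (!inherits(coeffs, "laguerre_coefficients"))
      stop("last_rr required when coeffs is a bare vector")
    last_rr <- coeffs$last_rr
  }
  if (!is.finite(last_rr) || last_rr <= 0) stop("last_rr must be > 0")
  mu <- last_rr + params$g0
  P1 <- length(params$g1)
  if (P1 > 0) mu <- mu + sum(params$g1 * l[seq_len(P1)])
  if (!is.null(params$g2)) {
    P2 <- nrow(params$g2)
    l2 <- l[seq_len(P2)]
    mu <- mu + drop(t(l2) %*% params$g2 %*% l2)
  }
  if (!is.null(params$g3)) {
    P3 <- dim(params$g3)[1]
    l3 <- l[seq_len(P3)]
    mu <- mu + sum(params$g3 * outer(outer(l3, l3), l3))
  }
  if (mu <= 0) attr(mu, "valid") <- FALSE
  mu
}

# --- internal parameter packing -------------------------------------------
# theta = (g0, g1[1..P1], g2 upper triangle by column, eta = log shape).
# The design row z is built so that mu = last_rr + theta[-end] . z with the
# off-diagonal quadratic entries doubled (g2 symmetric).

narl_dim <- function(P1, P2) 1L + P1 + P2 * (P2 + 1L) / 2L

narl_design_row <- function(l, P1, P2) {
  z <- 1
  if (P1 > 0) z <- c(z, l[seq_len(P1)])
  if (P2 > 0) {
    l2 <- l[seq_len(P2)]
    q <- outer(l2, l2)
    mult <- matrix(2, P2, P2); diag(mult) <- 1
    z <- c(z, (q * mult)[upper.tri(q, diag = TRUE)])
  }
  z
}

# vectorized: rows of L -> design matrix
narl_design_matrix <- function(L, P1, P2) {
  n <- nrow(L)
  Z <- matrix(1, n, 1)
  if (P1 > 0) Z <- cbind(Z, L[, seq_len(P1), drop = FALSE])
  if (P2 > 0) {
    l2 <- L[, seq_len(P2), drop = FALSE]
    cols <- list()
    for (j in seq_len(P2)) for (i in seq_len(j)) {
      cols[[length(cols) + 1L]] <-
        (if (i == j) 1 else 2) * l2[, i] * l2[, j]
    }
    Z <- cbind(Z, do.call(cbind, cols))
  }
  Z
}

theta_to_params <- function(theta, P1, P2) {
  g0 <- theta[1]
  g1 <- if (P1 > 0) theta[1 + seq_len(P1)] else numeric(0)
  g2 <- NULL
  if (P2 > 0) {
    g2 <- matrix(0, P2, P2)
    g2[upper.tri(g2, diag = TRUE)] <-
      theta[1 + P1 + seq_len(P2 * (P2 + 1) / 2)]
    g2 <- g2 + t(g2) - diag(diag(g2), P2)
  }
  eta <- theta[length(theta)]
  narl_parameters(shape = exp(eta), g0 = g0, g1 = g1, g2 = g2)
}

params_to_theta <- function(params) {
  th <- params$g0
  if (length(params$g1)) th <- c(th, params$g1)
  if (!is.null(params$g2))
    th <- c(th, params$g2[upper.tri(params$g2, diag = TRUE)])
  c(th, log(params$shape))
}
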
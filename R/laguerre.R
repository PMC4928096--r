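#' Discrete orthonormal Laguerre basis
#'
#' The i-th discrete-time orthonormal Laguerre function with decay
#' parameter alpha (0 < alpha < 1) satisfies
#' \deqn{\phi_0(n) = \sqrt{1-\alpha}\,\alpha^{n/2}} and the all-pass
#' recursion \eqn{\phi_i(n) = \sqrt{\alpha}\,\phi_i(n-1) +
#' \phi_{i-1}(n-1) - \sqrt{\alpha}\,\phi_{i-1}(n)}. The functions are
#' orthonormal on the nonnegative integers; alpha sets the rate of
#' exponential asymptotic decline, so a few functions compress a
#' long-memory autoregression.
#'
#' @param alpha decay parameter in (0, 1).
#' @param num_functions number of functions phi_0..phi_(P-1).
#' @param truncation history length (lags) over which the functions are
#'   tabulated; default: smallest n with `alpha^(n/2) < 1e-8`, capped at
#'   200 and floored at `num_functions`.
#' @param check verify orthonormality to 1e-6 and error if the
#'   truncation is too short to reach it (the default); disable only for
#'   deliberately compact bases, e.g. the small state of the Lyapunov
#'   path, where the residual tail mass is accepted.
#' @return object of class `laguerre_basis` with `alpha`, `num_functions`,
#'   `truncation` and the `num_functions x truncation` matrix
#'   `basis_matrix` (`basis_matrix[i+1, n+1] = phi_i(n)`).
#' @examples
#' b <- laguerre_basis(0.2, 3)
#' tcrossprod(b$basis_matrix)  # ~ identity
#' @export
laguerre_basis <- function(alpha, num_functions, truncation = NULL,
                           check = TRUE) {
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly inside (0, 1)")
  if (num_functions < 1) stop("num_functions must be >= 1")
  if (is.null(truncation)) {
    truncation <- ceiling(2 * log(1e-8) / log(alpha))
    truncation <- max(min(truncation, 200L), num_functions, 1L)
  }
  if (truncation < num_functions)
    stop("truncation must be at least num_functions")
  n <- truncation
  phi <- matrix(0, num_functions, n)
  sa <- sqrt(alpha)
  phi[1, ] <- sqrt(1 - alpha) * alpha^((0:(n - 1)) / 2)
  if (num_functions > 1) {
    for (i in 2:num_functions) {
      phi[i, 1] <- -sa * phi[i - 1, 1]
      if (n > 1) for (k in 2:n) {
        phi[i, k] <- sa * phi[i, k - 1] + phi[i - 1, k - 1] - sa * phi[i - 1, k]
      }
    }
  }
  gram <- tcrossprod(phi)
  if (check && max(abs(gram - diag(num_functions))) > 1e-6)
    stop("basis not orthonormal to 1e-6 at this truncation; ",
         "increase truncation (history length)")
  structure(list(alpha = alpha, num_functions = num_functions,
                 truncation = truncation, basis_matrix = phi),
            class = "laguerre_basis")
}

#' @export
print.laguerre_basis <- function(x, ...) {
  cat(sprintf("laguerre_basis: P = %d, alpha = %g, truncation = %d lags\n",
              x$num_functions, x$alpha, x$truncation))
  invisible(x)
}

#' Laguerre-filtered history of the differenced R-R series
#'
#' The regressors of the NARL model: with `dRR_j = RR_j - RR_(j-1)` the
#' first-differenced interval series (differencing improves local
#' stationarity), the i-th filter output just before time t is
#' \deqn{l_i(t) = \sum_{n=0}^{T-1} \phi_i(n)\, dRR_{\tilde N(t)-n},}
#' where \eqn{\tilde N(t)} indexes the most recent complete interval
#' before t. The outputs are piecewise constant between beats.
#'
#' No zero padding is performed: values are undefined (an error) until
#' `truncation + 1` intervals have been observed, and downstream
#' consumers must respect this burn-in.
#'
#' @param events an [event_series()].
#' @param basis a [laguerre_basis()].
#' @param t evaluation time, seconds.
#' @return object of class `laguerre_coefficients`: `values` (length P),
#'   `eval_time`, `source_beat_index` (the index \eqn{\tilde N(t)} of the
#'   last beat at or before t), and `last_rr` (most recent complete
#'   interval, seconds).
#' @export
filter_history <- function(events, basis, t) {
  L <- laguerre_filter_all(events, basis)
  N <- findInterval(t, events$event_times)
  if (N < basis$truncation + 2 || !is.finite(L$values[N, 1]))
    stop("insufficient history before t: need truncation + 1 intervals")
  structure(list(values = L$values[N, ], eval_time = t,
                 source_beat_index = N, last_rr = L$last_rr[N]),
            class = "laguerre_coefficients")
}

# Filter outputs indexed by beat: row N gives l_i computed from the
# intervals completed strictly before beat N's successor, i.e. the
# regressors in force throughout [u_N, u_(N+1)). Rows inside the burn-in
# are NA. last_rr[N] is the interval ending at beat N.
laguerre_filter_all <- function(events, basis) {
  rr <- events$rr_intervals
  K <- length(events$event_times)
  P <- basis$num_functions
  Tn <- basis$truncation
  vals <- matrix(NA_real_, K, P)
  last_rr <- c(NA_real_, rr)
  if (length(rr) >= Tn + 1) {
    drr <- diff(rr)                       # drr[j] = rr[j+1] - rr[j]
    # row for beat N uses drr ending at interval rr[N-1], i.e. drr index N-2
    E <- stats::embed(drr, Tn)            # row m: drr[m+Tn-1], ..., drr[m]
    lag0_idx <- seq(Tn, length(drr))      # drr index of each row's newest lag
    Lm <- E %*% t(basis$basis_matrix[, 1:Tn, drop = FALSE])
    beat_idx <- lag0_idx + 2              # newest drr index N-2 -> beat N
    keep <- beat_idx <= K
    vals[beat_idx[keep], ] <- Lm[keep, , drop = FALSE]
  }
  list(values = vals, last_rr = last_rr,
       burn_in_beat = Tn + 2L)
}
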
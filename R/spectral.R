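#' Transform NARL coefficients into input-output Volterra transfer
#' functions
#'
#' The autoregressive kernels are reconstructed from the Laguerre
#' expansion, `k1(n) = sum_i g1(i) phi_i(n)` and
#' `k2(n, m) = sum_ij g2(i, j) phi_i(n) phi_j(m)`, and Fourier
#' transformed on the beat axis with the lag convention of the model
#' (the newest difference enters at lag 1):
#' `Gamma1(f) = sum_n k1(n) e^{-i 2 pi f (n+1)}` and similarly for
#' `Gamma2`. The input-output transfer functions of the equivalent
#' Wiener-Volterra system follow the feedback relations
#' `H1(f) = 1 / (1 - Gamma1(f))` and
#' `H2(f1, f2) = H1(f1 + f2) Gamma2(f1, f2) H1(f1) H1(f2)`;
#' higher kernel orders are outside the quadratic scope and rejected.
#' Frequencies on the beat axis are mapped to Hz by `f_Hz = f_beat / mu`.
#'
#' @param params a [narl_parameters()] (quadratic at most).
#' @param basis the [laguerre_basis()] used in the fit.
#' @param freq_grid beat-axis frequency grid (cycles/beat, in
#'   [-0.5, 0.5]).
#' @param mu_rr instantaneous mean interval, seconds, for the Hz mapping.
#' @return object of class `kernel_transform`: `freq_beat`, `freq_hz`,
#'   complex `H1`, `gamma1`, and the functions `H1_at(fb)`,
#'   `gamma2_at(f1b, f2b)`, `H2_at(f1b, f2b)` evaluating the transfer at
#'   arbitrary beat frequencies.
#' @export
narl_to_kernels <- function(params, basis, freq_grid = NULL, mu_rr) {
  if (!is.null(params$g3) && any(params$g3 != 0))
    stop("kernel transform implemented up to order 2; cubic terms are ",
         "used only on the complexity path")
  if (mu_rr <= 0) stop("mu_rr must be > 0")
  if (is.null(freq_grid)) freq_grid <- seq(-0.5, 0.5, by = 1 / 512)
  phi <- basis$basis_matrix
  P1 <- length(params$g1)
  k1 <- if (P1 > 0)
    as.numeric(crossprod(phi[seq_len(P1), , drop = FALSE], params$g1))
  else rep(0, ncol(phi))
  K2 <- NULL
  if (!is.null(params$g2)) {
    P2 <- nrow(params$g2)
    ph2 <- phi[seq_len(P2), , drop = FALSE]
    K2 <- t(ph2) %*% params$g2 %*% ph2
  }
  lags <- seq_len(ncol(phi))              # lag n+1 for n = 0..T-1
  efun <- function(fb) exp(-2i * pi * outer(fb, lags))
  gamma1_at <- function(fb) as.vector(efun(fb) %*% k1)
  H1_at <- function(fb) {
    g <- gamma1_at(fb)
    den <- 1 - g
    if (any(Mod(den) < 1e-8)) {
      bad <- fb[which(Mod(den) < 1e-8)[1]]
      stop(sprintf(
        "near-nonstationary pole: |1 - Gamma1| < 1e-8 at beat frequency %.5f",
        bad))
    }
    1 / den
  }
  gamma2_at <- function(f1b, f2b) {
    if (is.null(K2)) return(rep(0 + 0i, length(f1b)))
    E1 <- efun(f1b); E2 <- efun(f2b)
    rowSums((E1 %*% K2) * E2)
  }
  H2_at <- function(f1b, f2b) {
    if (is.null(K2)) return(rep(0 + 0i, length(f1b)))
    H1_at(f1b + f2b) * gamma2_at(f1b, f2b) * H1_at(f1b) * H1_at(f2b)
  }
  g1v <- gamma1_at(freq_grid)
  structure(list(freq_beat = freq_grid, freq_hz = freq_grid / mu_rr,
                 gamma1 = g1v, H1 = 1 / (1 - g1v),
                 k1 = k1, K2 = K2, mu_rr = mu_rr,
                 H1_at = H1_at, gamma1_at = gamma1_at,
                 gamma2_at = gamma2_at, H2_at = H2_at),
            class = "kernel_transform")
}

#' Spectral band definitions (Hz)
#' @export
hrv_bands <- function() {
  list(vlf = c(0.01, 0.05), lf = c(0.05, 0.15), hf = c(0.15, 0.5))
}

# trapezoidal integral of y(x) over [a, b] with linear interpolation at
# the band edges; bands closed on the left, open on the right
band_integral <- function(x, y, a, b) {
  b <- min(b, max(x)); a <- max(a, min(x))
  if (b <= a) return(0)
  xs <- unique(sort(c(a, x[x > a & x < b], b)))
  ys <- stats::approx(x, y, xout = xs)$y
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Instantaneous power spectrum and band powers
#'
#' At each converged grid time the one-sided spectral density of the
#' interval series is evaluated as
#' \deqn{S(f, t) = 2\, \mu_{RR}(t)\, \sigma_{RR}^2(t)\, |H_1(f \mu_{RR}(t))|^2}
#' (s^2/Hz on f in Hz). The normalization is pinned by a Parseval-type
#' convention: for the null model (flat `|H1| = 1`) the integral of
#' `S(f, t)` over the full one-sided band `[0, 0.5/mu_rr]` equals the
#' fitted interval variance `sigma_rr^2(t)`. Band powers (VLF
#' 0.01-0.05, LF 0.05-0.15, HF 0.15-0.5 Hz) are trapezoidal integrals;
#' the LF/HF ratio guards the HF denominator with a floor.
#'
#' @param traj a `parameter_trajectory` (quadratic or linear model).
#' @param n_freq number of beat-axis frequencies on (0, 0.5].
#' @param stride evaluate every `stride`-th grid time (1 = all).
#' @param hf_floor denominator floor for the LF/HF ratio.
#' @return object of class `spectral_surface`: `times`, data.frame
#'   `bands` (vlf, lf, hf, lf_hf), and the beat-frequency grid with
#'   `|H1|^2` rows in `h1sq`.
#' @export
instantaneous_spectrum <- function(traj, n_freq = 256, stride = 1,
                                   hf_floor = 1e-12) {
  if (n_freq < 8) stop("empty or degenerate frequency grid")
  idx <- seq(1, length(traj$grid_times), by = stride)
  fb <- seq(0, 0.5, length.out = n_freq)
  phi <- traj$basis$basis_matrix
  P1 <- traj$P1
  lags <- seq_len(ncol(phi))
  E <- exp(-2i * pi * outer(fb, lags))    # n_freq x lags
  # map packed theta -> k1 for all selected times at once
  G1 <- if (P1 > 0) {
    K1 <- traj$theta[idx, 1 + seq_len(P1), drop = FALSE] %*%
      phi[seq_len(P1), , drop = FALSE]    # times x lags
    K1 %*% t(E)                           # times x n_freq (complex)
  } else matrix(0 + 0i, length(idx), n_freq)
  H1sq <- 1 / Mod(1 - G1)^2
  bands <- hrv_bands()
  out <- matrix(NA_real_, length(idx), 4,
                dimnames = list(NULL, c("vlf", "lf", "hf", "lf_hf")))
  for (r in seq_along(idx)) {
    k <- idx[r]
    mu <- traj$mu_rr[k]; sg <- traj$sigma_rr[k]
    if (!traj$converged[k] || !is.finite(mu) || !is.finite(sg)) next
    # S density on the Hz axis equals 2*mu*sigma^2*|H1|^2; integrating in
    # beat frequency removes one mu factor
    dens <- 2 * sg^2 * H1sq[r, ]
    vlf <- band_integral(fb, dens, bands$vlf[1] * mu, bands$vlf[2] * mu)
    lf <- band_integral(fb, dens, bands$lf[1] * mu, bands$lf[2] * mu)
    hf <- band_integral(fb, dens, bands$hf[1] * mu, bands$hf[2] * mu)
    out[r, ] <- c(vlf, lf, hf, lf / max(hf, hf_floor))
  }
  structure(list(times = traj$grid_times[idx],
                 bands = as.data.frame(out),
                 freq_beat = fb, h1sq = H1sq),
            class = "spectral_surface")
}

#' Instantaneous bispectrum and band integrals
#'
#' Analytic bispectrum of the fitted quadratic Volterra system driven by
#' white Gaussian innovations of variance `sigma_rr^2(t)`: the sum over
#' the three canonical pairings
#' \deqn{Bis(f_1, f_2) = 2\sigma^4 [ H_1(f_1) H_1(f_2) \overline{H_2(f_1, f_2)}
#'  + H_1(f_2) \overline{H_1(f_1+f_2)} H_2(-f_2, f_1+f_2)
#'  + H_1(f_1) \overline{H_1(f_1+f_2)} H_2(-f_1, f_1+f_2) ],}
#' evaluated on the beat axis and scaled by `mu_rr^2` for the Hz-axis
#' density. `|Bis|` is integrated over LF x LF (LL), LF x HF (LH) and
#' HF x HF (HH).
#'
#' @param traj a `parameter_trajectory` with quadratic coefficients.
#' @param df frequency resolution in Hz of the integration grid.
#' @param stride evaluate every `stride`-th grid time.
#' @return object of class `bispectral_surface`: `times` and data.frame
#'   `bands` (ll, lh, hh).
#' @export
instantaneous_bispectrum <- function(traj, df = 0.02, stride = 1) {
  if (traj$P2 < 1) stop("bispectrum requires quadratic coefficients")
  idx <- seq(1, length(traj$grid_times), by = stride)
  bands <- hrv_bands()
  f_lf <- seq(bands$lf[1], bands$lf[2], by = df)
  f_hf <- seq(bands$hf[1], bands$hf[2], by = df)
  out <- matrix(NA_real_, length(idx), 3,
                dimnames = list(NULL, c("ll", "lh", "hh")))
  d <- ncol(traj$theta)
  for (r in seq_along(idx)) {
    k <- idx[r]
    mu <- traj$mu_rr[k]; sg <- traj$sigma_rr[k]
    if (!traj$converged[k] || !is.finite(mu) || !is.finite(sg)) next
    # region must stay inside the beat Nyquist after Hz mapping
    if (bands$hf[2] * mu > 0.5)
      stop("frequency region exceeds the kernel grid (beat Nyquist)")
    par <- theta_to_params(traj$theta[k, ], traj$P1, traj$P2)
    kt <- narl_to_kernels(par, traj$basis, freq_grid = c(0), mu_rr = mu)
    surf <- function(f1, f2) {
      bis_surface(kt, f1 * mu, f2 * mu, sg^2) * mu^2
    }
    out[r, "ll"] <- bis_band(surf, f_lf, f_lf)
    out[r, "lh"] <- bis_band(surf, f_lf, f_hf)
    out[r, "hh"] <- bis_band(surf, f_hf, f_hf)
  }
  structure(list(times = traj$grid_times[idx],
                 bands = as.data.frame(out)),
            class = "bispectral_surface")
}

# complex bispectrum on the outer grid of beat frequencies
bis_surface <- function(kt, f1b, f2b, sig2) {
  n1 <- length(f1b); n2 <- length(f2b)
  F1 <- matrix(f1b, n1, n2)
  F2 <- matrix(f2b, n1, n2, byrow = TRUE)
  v1 <- as.vector(F1); v2 <- as.vector(F2)
  H1a <- kt$H1_at(v1); H1b <- kt$H1_at(v2); H1s <- kt$H1_at(v1 + v2)
  t1 <- H1a * H1b * Conj(kt$H2_at(v1, v2))
  t2 <- H1b * Conj(H1s) * kt$H2_at(-v2, v1 + v2)
  t3 <- H1a * Conj(H1s) * kt$H2_at(-v1, v1 + v2)
  matrix(2 * sig2^2 * (t1 + t2 + t3), n1, n2)
}

# 2-d trapezoid of |surf| over the Hz rectangle
bis_band <- function(surf, fx, fy) {
  M <- Mod(surf(fx, fy))
  wx <- trap_weights(fx); wy <- trap_weights(fy)
  drop(t(wx) %*% M %*% wy)
}

trap_weights <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2; w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}
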
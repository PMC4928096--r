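#' The instantaneous estimator set used for classification
#'
#' The 13 per-time-point estimators summarized per stimulus: mean and SD
#' of the R-R interval, heart-rate SD, the LF and HF band powers and
#' their ratio, the three bispectral band integrals, approximate and
#' sample entropy, and the first two Lyapunov exponents.
#'
#' @return character vector of the 13 estimator names.
#' @export
estimator_set <- function() {
  c("mu_rr", "sigma_rr", "sigma_hr", "lf", "hf", "lf_hf",
    "ll", "lh", "hh", "a_i", "s_i", "lambda1", "lambda2")
}

#' Assemble the instantaneous estimate table
#'
#' Runs the spectral, bispectral and complexity estimators on a fitted
#' trajectory and joins them (nearest preceding value for estimators
#' computed on a strided grid) into one data.frame with a `time` column
#' and the 13 columns of [estimator_set()].
#'
#' @param traj a `parameter_trajectory` from [fit_trajectory()].
#' @param events the underlying [event_series()].
#' @param spectral_stride,bispectral_stride,complexity_stride strides
#'   (in grid steps) at which the heavier estimators are evaluated and
#'   then carried forward to the full grid.
#' @param complexity_window trailing window (seconds) of the entropy and
#'   Lyapunov estimators; shorter than the 90 s likelihood window so the
#'   complexity measures are defined early in the recording.
#' @param n_freq spectrum frequency resolution.
#' @param bis_df bispectrum integration resolution, Hz.
#' @return data.frame `time` + 13 estimator columns.
#' @export
instantaneous_estimates <- function(traj, events,
                                    spectral_stride = 1,
                                    bispectral_stride = 10,
                                    complexity_stride = 10,
                                    complexity_window = 45,
                                    n_freq = 128, bis_df = 0.025) {
  sp <- instantaneous_spectrum(traj, n_freq = n_freq,
                               stride = spectral_stride)
  bis <- instantaneous_bispectrum(traj, df = bis_df,
                                  stride = bispectral_stride)
  ent <- instantaneous_entropy(traj, events, stride = complexity_stride,
                               window = complexity_window)
  lya <- lyapunov_spectrum(events, traj, stride = complexity_stride,
                           window = complexity_window)
  grid <- traj$grid_times
  # carry the last finite strided value forward to the full grid
  locf <- function(times, vals) {
    keep <- is.finite(vals)
    if (!any(keep)) return(rep(NA_real_, length(grid)))
    i <- findInterval(grid, times[keep])
    out <- rep(NA_real_, length(grid))
    ok <- i >= 1
    out[ok] <- vals[keep][i[ok]]
    out
  }
  data.frame(
    time = grid,
    mu_rr = traj$mu_rr,
    sigma_rr = traj$sigma_rr,
    sigma_hr = traj$sigma_hr,
    lf = locf(sp$times, sp$bands$lf),
    hf = locf(sp$times, sp$bands$hf),
    lf_hf = locf(sp$times, sp$bands$lf_hf),
    ll = locf(bis$times, bis$bands$ll),
    lh = locf(bis$times, bis$bands$lh),
    hh = locf(bis$times, bis$bands$hh),
    a_i = locf(ent$times, ent$approx_entropy),
    s_i = locf(ent$times, ent$sample_entropy),
    lambda1 = locf(lya$times, lya$lambda1),
    lambda2 = locf(lya$times, lya$lambda2))
}

#' Stimulus-locked feature extraction
#'
#' For each annotated stimulus and each of the 13 estimators: restrict
#' the estimate series to the last second of the stimulus, divide
#' pointwise by the estimator's baseline (its median over the first 10 s
#' of the initial rest), and record the maximum, median, and median
#' absolute deviation over that window — 13 x 3 = 39 dimensions per
#' stimulus, named `estimator__summary` (e.g. `lf_hf__mad`).
#'
#' @param estimates data.frame from [instantaneous_estimates()].
#' @param annotations stimulus table (onset, offset, force, velocity,
#'   subject).
#' @param rest_window `c(start, end)` of the initial rest used for the
#'   baseline; the first `baseline_seconds` of its covered portion are
#'   used (estimates only exist after the fitting window and burn-in, so
#'   the baseline is anchored at the first covered rest time).
#' @param baseline_seconds length of the baseline window, default 10.
#' @return data.frame: subject, stimulus id, force/velocity labels
#'   (low/high), and 39 feature columns.
#' @export
extract_stimulus_features <- function(estimates, annotations,
                                      rest_window,
                                      baseline_seconds = 10) {
  est_names <- estimator_set()
  miss <- setdiff(est_names, names(estimates))
  if (length(miss)) stop("estimates missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(annotations$offset - annotations$onset < 1))
    stop("stimulus shorter than 1 s cannot provide a last-second window")
  allfin <- rowSums(!is.finite(as.matrix(estimates[, est_names]))) == 0
  covered <- estimates$time[allfin]
  covered <- covered[covered >= rest_window[1] & covered < rest_window[2]]
  if (length(covered) == 0)
    stop("no estimate coverage of the rest baseline window")
  b0 <- covered[1]; b1 <- min(b0 + baseline_seconds, rest_window[2])
  bsel <- estimates$time >= b0 & estimates$time < b1
  if (!any(bsel)) stop("no estimate coverage of the rest baseline window")
  baseline <- vapply(est_names, function(v) {
    x <- estimates[[v]][bsel]
    x <- x[is.finite(x)]
    if (length(x) == 0) stop("no finite baseline values for ", v)
    stats::median(x)
  }, numeric(1))

  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    sel <- estimates$time >= a$offset - 1 & estimates$time < a$offset
    if (!any(sel)) stop("no estimate coverage of the last second of ",
                        "stimulus ", i)
    vals <- lapply(est_names, function(v) {
      x <- estimates[[v]][sel]
      if (any(!is.finite(x)))
        stop(sprintf("non-finite %s inside the last second of stimulus %d",
                     v, i))
      den <- baseline[[v]]
      if (abs(den) < 1e-12) den <- sign(den + (den == 0)) * 1e-12
      x <- x / den
      c(max = max(x), median = stats::median(x),
        mad = stats::mad(x, constant = 1))
    })
    out <- unlist(vals)
    names(out) <- as.vector(outer(c("max", "median", "mad"), est_names,
                                  function(s, e) paste0(e, "__", s)))
    data.frame(subject = a$subject, stimulus = i,
               force_class = if (a$force > 4) "high" else "low",
               velocity_class = if (a$velocity > 30) "high" else "low",
               as.list(out), check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Names of the 39 feature columns in a feature table
#' @param df a feature table from [extract_stimulus_features()].
#' @export
feature_columns <- function(df) {
  setdiff(names(df), c("subject", "stimulus", "force_class",
                       "velocity_class"))
}

#' Remove multivariate outliers by the z-score screen
#'
#' A row is removed iff the conventional z-score (mean/SD over rows) of
#' any of its dimensions exceeds `z_max` in absolute value;
#' zero-variance dimensions are skipped.
#'
#' @param feature_table data.frame with feature columns.
#' @param z_max threshold, default 4.
#' @return list `table` (filtered) and `removed` (row indices removed).
#' @export
remove_outliers <- function(feature_table, z_max = 4) {
  if (nrow(feature_table) < 3) stop("need at least 3 rows")
  fc <- feature_columns(feature_table)
  X <- as.matrix(feature_table[, fc])
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  keepdim <- sd > 0
  Z <- sweep(sweep(X[, keepdim, drop = FALSE], 2, mu[keepdim]), 2,
             sd[keepdim], "/")
  bad <- which(apply(abs(Z) > z_max, 1, any))
  list(table = if (length(bad)) feature_table[-bad, , drop = FALSE]
       else feature_table,
       removed = bad)
}

#' Paired Wilcoxon signed-rank screen per feature
#'
#' Two-sided signed-rank p-value per feature for subject-matched
#' condition pairs; exact distribution for n <= 25 without ties/zeros,
#' normal approximation with tie and zero corrections otherwise
#' (delegated to [stats::wilcox.test()]). All-zero difference vectors
#' are reported as p = 1.
#'
#' @param x,y matrices or data.frames of paired samples (rows = pairs,
#'   columns = features), equal dimensions.
#' @return named numeric vector of p-values.
#' @export
wilcoxon_screen <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("paired samples of unequal size")
  p <- vapply(seq_len(ncol(x)), function(j) {
    d <- x[, j] - y[, j]
    if (all(d == 0)) return(1)
    suppressWarnings(
      stats::wilcox.test(x[, j], y[, j], paired = TRUE,
                         exact = nrow(x) <= 25)$p.value)
  }, numeric(1))
  names(p) <- colnames(x)
  p
}
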
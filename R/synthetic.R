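#' Simulate an event series from the inverse-Gaussian NARL model
#'
#' Runs the generative model forward: at each beat the conditional mean
#' of the next interval is the most recent interval plus the NARL
#' polynomial in the Laguerre-filtered differenced history, and the
#' interval is drawn from the inverse-Gaussian with the mean and shape
#' active at that time. Deterministic given the RNG state.
#'
#' Because the model is autoregressive on the *differenced* series, its
#' level carries a structural unit root: a constant-parameter run is a
#' martingale in the interval length. Keep `shape` large (weak noise) or
#' durations moderate so that the positivity invariant of the timeline
#' holds; for long stationary recordings with a fixed mean use
#' [simulate_ig_timeline()], the renewal member of the family.
#'
#' @param params a [narl_parameters()], or a function `f(t)` returning
#'   one (a piecewise/smooth parameter timeline).
#' @param duration recording length, seconds; 0 gives an empty series.
#' @param basis a [laguerre_basis()] for the history filter.
#' @param initial_history seed intervals, seconds (recycled to cover the
#'   filter burn-in), default 0.8 s throughout.
#' @param seed optional integer seed set via `set.seed`.
#' @return an [event_series()] with `t_end = duration`, or `NULL` when
#'   `duration` is 0.
#' @export
simulate_ig_narl <- function(params, duration,
                             basis = laguerre_basis(0.2, 3),
                             initial_history = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (duration <= 0) return(NULL)
  par_at <- if (is.function(params)) params else function(t) params
  Tn <- basis$truncation
  rr <- rep(initial_history, length.out = Tn + 2)
  drr <- diff(rr)
  times <- cumsum(rr)
  t_cur <- times[length(times)]
  phi <- basis$basis_matrix
  nlag <- ncol(phi)
  repeat {
    p <- par_at(t_cur)
    l <- as.numeric(phi %*% drr[length(drr) - (0:(nlag - 1))])
    mu <- conditional_mean(p, l, last_rr = rr[length(rr)])
    if (!is.finite(mu) || mu <= 0)
      stop(sprintf("non-positive conditional mean at t = %.3f s", t_cur))
    w <- rinvgauss(1, as.numeric(mu), p$shape)
    t_cur <- t_cur + w
    if (t_cur > duration) break
    times <- c(times, t_cur)
    drr <- c(drr, w - rr[length(rr)])
    rr <- c(rr, w)
    if (length(drr) > 4 * nlag) {
      drr <- drr[(length(drr) - 2 * nlag):length(drr)]
      rr <- rr[(length(rr) - 2 * nlag):length(rr)]
    }
  }
  if (length(times) < 2) stop("duration too short: fewer than two beats")
  event_series(times, t_start = 0, t_end = duration)
}

#' Null (renewal) parameter set
#'
#' All kernels zero: the conditional mean reduces to the most recent
#' interval (plus `g0`).
#'
#' @param shape inverse-Gaussian shape.
#' @param P1,P2 model orders of the returned parameter set.
#' @param g0 zero-order coefficient, seconds.
#' @export
null_params <- function(shape = 1500, P1 = 3, P2 = 2, g0 = 0) {
  narl_parameters(shape = shape, g0 = g0,
                  g1 = rep(0, P1),
                  g2 = if (P2 > 0) matrix(0, P2, P2) else NULL)
}

#' Simulate a (possibly time-varying) renewal inverse-Gaussian series
#'
#' Independent intervals drawn from the inverse-Gaussian with mean
#' `mu_fun(t)` and shape `shape_fun(t)` evaluated at the opening beat of
#' each interval — the constant/piecewise-mean member of the model
#' family, used for recovery and coverage studies and as the carrier of
#' condition-dependent effects in the simulated protocol.
#'
#' @param mu_fun scalar or function of time returning the mean interval.
#' @param shape_fun scalar or function of time returning the IG shape.
#' @param duration recording length, seconds.
#' @param seed optional seed.
#' @return an [event_series()].
#' @export
simulate_ig_timeline <- function(mu_fun, shape_fun, duration,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mf <- if (is.function(mu_fun)) mu_fun else function(t) mu_fun
  sf <- if (is.function(shape_fun)) shape_fun else function(t) shape_fun
  t_cur <- 0
  times <- numeric(0)
  repeat {
    w <- rinvgauss(1, mf(t_cur), sf(t_cur))
    t_cur <- t_cur + w
    if (t_cur > duration) break
    times <- c(times, t_cur)
  }
  event_series(times, t_start = 0, t_end = duration)
}

#' @rdname simulate_ig_timeline
#' @param mu,shape constants for the fixed-parameter renewal series.
#' @export
simulate_ig_renewal <- function(mu, shape, duration, seed = NULL) {
  simulate_ig_timeline(mu, shape, duration, seed = seed)
}

#' Chaotic-map surrogate R-R interval sequences
#'
#' Iterates the logistic (`x' = r x (1 - x)`) or Henon map and affinely
#' maps the states to positive pseudo R-R intervals — fixtures with a
#' known dominant Lyapunov exponent for validating the exponent
#' estimator (logistic at r = 4: `ln 2` nats per iteration).
#'
#' @param map `"logistic"` or `"henon"`.
#' @param n number of intervals, >= 100.
#' @param params map parameters (`r`, or `a`/`b` for Henon).
#' @param offset_seconds,scale affine map: interval = offset + scale * x.
#' @param seed optional seed (randomizes the initial condition).
#' @return list `intervals` (seconds), `states`, `lyapunov_exact` (nats
#'   per iteration; NA where no closed form exists).
#' @export
simulate_chaotic_rr <- function(map = c("logistic", "henon"), n,
                                params = list(), offset_seconds = 0.8,
                                scale = 0.1, seed = NULL) {
  map <- match.arg(map)
  if (n < 100) stop("n must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  if (map == "logistic") {
    r <- params$r %||% 4
    x <- stats::runif(1, 0.2, 0.8)
    states <- numeric(n)
    for (i in seq_len(n)) { x <- r * x * (1 - x); states[i] <- x }
    lam <- if (r == 4) log(2) else NA_real_
  } else {
    a <- params$a %||% 1.4; b <- params$b %||% 0.3
    x <- stats::runif(1, -0.1, 0.1); y <- stats::runif(1, -0.1, 0.1)
    states <- numeric(n)
    for (i in seq_len(n)) {
      xn <- 1 - a * x^2 + y; y <- b * x; x <- xn
      states[i] <- x
    }
    lam <- if (a == 1.4 && b == 0.3) 0.419 else NA_real_  # literature value
  }
  iv <- offset_seconds + scale * states
  if (any(iv <= 0)) stop("offset/scale imply non-positive intervals")
  list(intervals = iv, states = states, lyapunov_exact = lam)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Protocol specification for the simulated stimulation study
#'
#' Emulates the study design: a 2-minute initial rest, a randomized
#' sequence of caress-like stimuli crossing 2 force levels (2, 6 N) with
#' 2 velocity levels (9.4, 65 mm/s), each stimulus flanked by 35 s
#' pre/post intervals, and a closing 2-minute rest. Stimulus duration is
#' tied to velocity (25 s at the slow velocity, 4.3 s at the fast one,
#' inside the administered 4.3-25 s range). Condition-dependent autonomic
#' effects are injected as parameter modulations localized to the
#' stimulus windows: the defaults shift the mean interval and rescale the
#' shape with velocity, and more weakly with force. Effect sizes are
#' synthetic calibration choices, not estimates of physiological effects.
#'
#' @param n_subjects number of simulated subjects.
#' @param reps_per_type repetitions of each of the 4 stimulus types.
#' @param rest_duration rest length at both ends, seconds.
#' @param pre_post pre- and post-stimulus gap, seconds.
#' @param durations named durations per velocity level, seconds.
#' @param mean_rr,shape baseline interval mean / IG shape.
#' @param effect_spec list of per-condition modulations applied during a
#'   stimulus: `d_mu(force, velocity)` added to the mean interval and
#'   `shape_factor(force, velocity)` multiplying the shape.
#' @return list of class `protocol_spec`.
#' @export
protocol_spec <- function(n_subjects = 4, reps_per_type = 1,
                          rest_duration = 120, pre_post = 35,
                          durations = c(slow = 25, fast = 4.3),
                          mean_rr = 0.8, shape = 1500,
                          effect_spec = NULL) {
  if (is.null(effect_spec)) {
    effect_spec <- list(
      d_mu = function(force, velocity) {
        (if (velocity > 30) -0.07 else 0.05) +
          (if (force > 4) -0.012 else 0.012)
      },
      shape_factor = function(force, velocity) {
        (if (velocity > 30) 2.5 else 0.55) * (if (force > 4) 1.2 else 1)
      })
  }
  structure(list(n_subjects = n_subjects, reps_per_type = reps_per_type,
                 rest_duration = rest_duration, pre_post = pre_post,
                 durations = durations, mean_rr = mean_rr, shape = shape,
                 effect_spec = effect_spec),
            class = "protocol_spec")
}

#' Simulate a full stimulation protocol
#'
#' Per subject: initial rest, randomized stimuli (each of the four
#' force-by-velocity types `reps_per_type` times) separated by pre/post
#' gaps, closing rest. Effects are injected only inside stimulus windows,
#' so outside them the timeline equals the rest baseline.
#'
#' @param spec a [protocol_spec()].
#' @param seed integer seed; subject s uses `seed + s`.
#' @return list with one element per subject: `events`
#'   ([event_series()]), `annotations` (data.frame onset, offset, force,
#'   velocity, subject) and `rest_windows` (2 x 2 matrix of start/end).
#' @export
simulate_protocol <- function(spec = protocol_spec(), seed = 1) {
  forces <- c(2, 6); velocities <- c(9.4, 65)
  types <- expand.grid(force = forces, velocity = velocities)
  lapply(seq_len(spec$n_subjects), function(s) {
    set.seed(seed + s)
    order_idx <- sample(rep(seq_len(nrow(types)), spec$reps_per_type))
    onset <- offset <- force <- velocity <- numeric(0)
    t_cur <- spec$rest_duration
    for (k in order_idx) {
      t_cur <- t_cur + spec$pre_post
      dur <- unname(
        if (types$velocity[k] > 30) spec$durations[["fast"]]
        else spec$durations[["slow"]])
      onset <- c(onset, t_cur); offset <- c(offset, t_cur + dur)
      force <- c(force, types$force[k])
      velocity <- c(velocity, types$velocity[k])
      t_cur <- t_cur + dur + spec$pre_post
    }
    total <- t_cur + spec$rest_duration
    ann <- data.frame(onset = onset, offset = offset, force = force,
                      velocity = velocity,
                      subject = sprintf("S%02d", s))
    stim_at <- function(t) {
      hit <- which(t >= ann$onset & t < ann$offset)
      if (length(hit)) hit[1] else 0L
    }
    mu_fun <- function(t) {
      h <- stim_at(t)
      if (h == 0L) spec$mean_rr
      else spec$mean_rr + spec$effect_spec$d_mu(ann$force[h],
                                                ann$velocity[h])
    }
    shape_fun <- function(t) {
      h <- stim_at(t)
      if (h == 0L) spec$shape
      else spec$shape * spec$effect_spec$shape_factor(ann$force[h],
                                                      ann$velocity[h])
    }
    ev <- simulate_ig_timeline(mu_fun, shape_fun, total)
    list(events = ev, annotations = ann,
         rest_windows = rbind(c(0, spec$rest_duration),
                              c(total - spec$rest_duration, total)))
  })
}
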
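# heartpp

Instantaneous analysis of heartbeat dynamics through inhomogeneous
inverse-Gaussian point-process models.

## The problem

Heart rate variability carries autonomic information, but classical HRV
measures need 30 s to 5 min of data, while many stimuli of interest
(here: caress-like haptic stimuli of 4.3–25 s) are much shorter.
Modeling the R-wave events as a point process solves this: a predictive
probability density for the *next* beat is defined in continuous time,
so mean, variance, spectra, bispectra and complexity measures can be
read off at any instant, without interpolating the unevenly sampled
interval series. `heartpp` is aimed at physiologists and biomedical
signal-processing researchers who want these instantaneous estimators,
their goodness-of-fit, and the downstream stimulus-classification chain
in one reproducible package.

## The model

Given R-wave events \(u_1 < u_2 < \dots\) with intervals
\(RR_j = u_j - u_{j-1}\), the waiting time since the last beat follows
an inverse-Gaussian density

\[ f(w \mid \mathcal{H}_t) = \sqrt{\frac{\xi_0}{2\pi w^3}}
   \exp\!\Big\{ -\frac{\xi_0 (w - \mu_{RR}(t))^2}{2\,\mu_{RR}(t)^2 w}
   \Big\}, \]

whose mean is a Nonlinear Autoregressive model with Laguerre expansion
(NARL) of the Wiener–Volterra kernels, driven by the *differenced*
interval series \(dRR_j = RR_j - RR_{j-1}\):

\[ \mu_{RR}(t) = RR_{\tilde N(t)} + g_0 + \sum_i g_1(i)\, l_i(t)
   + \sum_{i,j} g_2(i,j)\, l_i(t)\, l_j(t) + \dots \]

with \(l_i(t) = \sum_n \phi_i(n)\, dRR_{\tilde N(t) - n}\) the outputs of
discrete orthonormal Laguerre filters. The time-varying parameters
\((\xi_0, g_0, g_1, g_2)\) are tracked by maximizing an exponentially
weighted local likelihood over a sliding 90-s window on a fine time
grid (Newton–Raphson, warm-started from the previous grid time).

From the fitted model the package derives, at every grid time, the 13
estimators used for classification: \(\mu_{RR}, \sigma_{RR},
\sigma_{HR}\); LF and HF band powers and LF/HF from
\(S(f,t) \propto \mu_{RR}\sigma_{RR}^2 |H_1(f,t)|^2\); the bispectral
band integrals LL, LH, HH of the quadratic Volterra system; the first
two Lyapunov exponents of a cubic NAR map refitted by fast orthogonal
search; and the inhomogeneous point-process approximate and sample
entropies, whose phase-space metric is the Kolmogorov–Smirnov distance
between predictive densities. Model adequacy is assessed by the
time-rescaling theorem (KS plot and autocorrelation of the transformed
intervals).

A synthetic module simulates event series from the same model family
and a full stimulation protocol (2-min rests, randomized 2 force × 2
velocity stimulus types, 35-s pre/post gaps), so the entire chain —
fit → estimate → features → classify — runs end-to-end without any
recordings.

## Worked example

```r
library(heartpp)

ev <- simulate_ig_renewal(mu = 0.8, shape = 1500, duration = 300, seed = 1)
print(ev)
#> event_series: 374 beats over (0.000, 300.000] s
#>   mean RR 0.800 s, range [0.748, 0.850] s, flags: ok

traj <- fit_trajectory(ev, fit_config(step_delta = 0.1))
print(traj)
#> parameter_trajectory: 2640 grid times (36.100..300.000 s, step 0.1 s)
#>   converged 99.7%; median mu_RR 0.801 s

gof <- time_rescale(ev, traj)
print(gof)
#> gof: n = 328, KS distance 0.0436 (95% bound 0.0751), 96.7% ACF lags in band

est <- instantaneous_estimates(traj, ev, bispectral_stride = 20,
                               complexity_stride = 20)
round(colMeans(est[est$time > 150, -1], na.rm = TRUE), 4)
#>    mu_rr sigma_rr sigma_hr       lf       hf    lf_hf       ll       lh
#>   0.8011   0.0197   0.0307   0.0000   0.0004   0.0235   0.0000   0.0000
#>       hh      a_i      s_i  lambda1  lambda2
#>   0.0000   0.7076   0.8328  -0.2221  -0.5499
```

Reading the output: the tracker recovers the generating mean interval
(0.801 s vs 0.8) and interval SD (0.0197 s vs
\(\sqrt{0.8^3/1500} = 0.0185\)); the KS distance sits well inside its
95% bound, so the fitted density explains the events; the renewal
series has (as it should) almost no LF power, near-zero bispectral
integrals, and negative Lyapunov exponents.

For a full simulated study, use the pipeline:

```r
cfg <- run_config("out", seed = 1, protocol = list(n_subjects = 4))
run_pipeline(cfg, "all")   # writes trajectories, estimates, features,
                           # confusion matrices, and a run manifest
```

or the command-line front end `inst/cli/heartpp.R`
(`Rscript heartpp.R all --out out --seed 1`).

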
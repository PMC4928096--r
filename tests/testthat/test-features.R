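# minimal synthetic estimate table covering rest + stimuli
toy_estimates <- function(dt = 0.05, total = 120) {
  tt <- seq(0, total, by = dt)
  est <- data.frame(time = tt)
  set.seed(19)
  for (v in estimator_set()) {
    est[[v]] <- 1 + 0.1 * sin(2 * pi * tt / 37) + rnorm(length(tt), 0, 0.01)
  }
  est
}

test_that("extraction yields 39 named dimensions per stimulus", {
  ann <- data.frame(onset = c(40, 70), offset = c(44.3, 95),
                    force = c(2, 6), velocity = c(65, 9.4),
                    subject = "S01")
  ft <- extract_stimulus_features(toy_estimates(), ann,
                                  rest_window = c(0, 30))
  expect_equal(nrow(ft), 2)
  fc <- feature_columns(ft)
  expect_equal(length(fc), 39)
  expect_setequal(
    fc, as.vector(outer(estimator_set(), c("max", "median", "mad"),
                        paste, sep = "__")))
  expect_equal(ft$force_class, c("low", "high"))
  expect_equal(ft$velocity_class, c("high", "low"))
})

test_that("constant estimator gives MAD zero and max equal to median", {
  est <- toy_estimates()
  est$lf <- 2                              # constant series
  ann <- data.frame(onset = 40, offset = 50, force = 2, velocity = 9.4,
                    subject = "S01")
  ft <- extract_stimulus_features(est, ann, rest_window = c(0, 30))
  expect_equal(ft[["lf__mad"]], 0)
  expect_equal(ft[["lf__max"]], ft[["lf__median"]])
  expect_equal(ft[["lf__median"]], 1)      # rest-normalized
})

test_that("short stimuli and missing coverage are rejected", {
  ann_short <- data.frame(onset = 40, offset = 40.5, force = 2,
                          velocity = 9.4, subject = "S01")
  expect_error(extract_stimulus_features(toy_estimates(), ann_short,
                                         c(0, 30)),
               "shorter than 1 s")
  est <- toy_estimates()
  est$s_i[est$time >= 49 & est$time < 50] <- NA
  ann <- data.frame(onset = 40, offset = 50, force = 2, velocity = 9.4,
                    subject = "S01")
  expect_error(extract_stimulus_features(est, ann, c(0, 30)),
               "non-finite s_i")
})

test_that("z-score outlier screen removes exactly the planted row", {
  set.seed(23)
  tab <- data.frame(subject = "S", stimulus = 1:30,
                    force_class = "low", velocity_class = "low",
                    check.names = FALSE)
  tab$a <- rnorm(30); tab$b <- rnorm(30); tab$const <- 1
  out0 <- remove_outliers(tab)
  expect_equal(nrow(out0$table), 30)

  # plant one row far out on dimension a; fixed-point iteration lands it
  # at z = 6 under the contaminated mean/SD
  tab2 <- tab
  tab2$a[7] <- 0
  for (it in 1:200) {
    z <- (tab2$a[7] - mean(tab2$a)) / sd(tab2$a)
    if (abs(z - 6) < 1e-10) break
    tab2$a[7] <- tab2$a[7] + (6 - z) * sd(tab2$a)
  }
  # verify by the direct z formula which rows the screen must flag
  zcol <- (tab2$a - mean(tab2$a)) / sd(tab2$a)
  expect_equal(which(abs(zcol) > 4), 7L)
  out <- remove_outliers(tab2)
  expect_equal(unname(out$removed), 7L)
  expect_equal(nrow(out$table), 29)
  expect_error(remove_outliers(tab[1:2, ]), "3 rows")
})

test_that("wilcoxon screen: nulls, power, and the exact enumeration", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("u", "v")))
  p_null <- wilcoxon_screen(x, x)
  expect_equal(unname(p_null), c(1, 1))
  expect_error(wilcoxon_screen(x, x[1:5, ]), "unequal")

  # exact n = 5 case against full enumeration of the 2^5 sign flips
  set.seed(9)
  d <- c(0.3, -0.1, 0.25, 0.4, -0.05)
  x1 <- matrix(d, 5, 1); y1 <- matrix(0, 5, 1)
  p <- wilcoxon_screen(x1, y1)
  rk <- rank(abs(d))
  Wobs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 5))
  Wall <- as.matrix(signs) %*% rk
  mu_w <- sum(rk) / 2
  p_enum <- mean(abs(Wall - mu_w) >= abs(Wobs - mu_w) - 1e-12)
  expect_equal(unname(p), p_enum, tolerance = 1e-12)

  # 1-SD planted shift, n = 32 pairs: detected in >= 90/100 runs
  hits <- 0
  for (s in 1:100) {
    set.seed(300 + s)
    a <- rnorm(32); b <- a + rnorm(32) + 1
    if (wilcoxon_screen(matrix(a), matrix(b))[1] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
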
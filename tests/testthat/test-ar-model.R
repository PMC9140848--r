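# Generative autoregressive models: configuration, reproducibility, and
# agreement with independently coded reference recursions.

test_that("configuration invariants are enforced", {
  expect_error(ar_model(lag = 0), "lags")
  expect_error(ar_model(lag = c(9, 10), lag_probs = c(0.6, 0.6)), "sum to 1")
  expect_error(ar_model(noise_var = -1), "noise_var")
  expect_error(ar_model(n_timepoints = 10, lag = 10), "exceed")
  expect_error(ar_model(n_channels = 4), "2 or 3")
  m <- ar_model_nonmarkovian()
  expect_equal(m$form, "accumulation")
  expect_equal(m$lag, c(9L, 10L, 11L))
})

test_that("coefficient-free models reduce to pure noise at the stated variance", {
  for (form_args in list(list(), list(lag = c(9, 10, 11),
                                      lag_probs = c(0.25, 0.5, 0.25)))) {
    m <- do.call(ar_model, c(list(self = 0, cross = 0, noise_var = 0.5,
                                  n_timepoints = 20000, n_runs = 1), form_args))
    x <- simulate(m, seed = 5)[[1]]
    # sample variance of n iid draws has SE ~ var * sqrt(2/n)
    se_var <- 0.5 * sqrt(2 / ncol(x))
    se_mean <- sqrt(0.5 / ncol(x))
    for (ch in 1:2) {
      expect_lt(abs(var(x[ch, ]) - 0.5), 3 * se_var)
      expect_lt(abs(mean(x[ch, ])), 3 * se_mean)
    }
  }
})

test_that("runs are bit-identical under a repeated seed", {
  m <- ar_model_nonmarkovian(n_timepoints = 1500, n_runs = 3)
  a <- simulate(m, seed = 11)
  b <- simulate(m, seed = 11)
  for (k in seq_along(a)) expect_identical(unclass(a[[k]]), unclass(b[[k]]))
  c1 <- simulate(m, seed = 12)
  expect_false(identical(unclass(a[[1]]), unclass(c1[[1]])))
})

test_that("with the gate always open the recurrence equals a plain linear VAR", {
  # independent reference: naive per-timepoint VAR(l) recursion on the
  # same noise draws
  n <- 3000; l <- 10L
  m <- ar_model(self = -0.1, cross = 0.9, threshold = -Inf, lag = l,
                noise_var = 0.5, n_timepoints = n, n_runs = 1)
  x <- simulate(m, seed = 21)[[1]]
  set.seed(21)
  eps <- matrix(rnorm(2 * n, sd = sqrt(0.5)), 2, n)
  ref <- eps
  for (t in (l + 1):n) {
    ref[1, t] <- eps[1, t] - 0.1 * ref[1, t - l] + 0.9 * ref[2, t - l]
    ref[2, t] <- eps[2, t] - 0.1 * ref[2, t - l] + 0.9 * ref[1, t - l]
  }
  expect_equal(unclass(x), ref, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the threshold gate zeroes sub-threshold cross-contributions", {
  # reference recursion with the gate written out explicitly
  n <- 2000; l <- 10L; th <- 0.9
  m <- ar_model_nonlinear(n_timepoints = n, n_runs = 1)
  x <- simulate(m, seed = 31)[[1]]
  set.seed(31)
  eps <- matrix(rnorm(2 * n, sd = sqrt(0.5)), 2, n)
  ref <- eps
  for (t in (l + 1):n) {
    b <- if (ref[2, t - l] > th) 0.9 else 0
    d <- if (ref[1, t - l] > th) 0.9 else 0
    ref[1, t] <- eps[1, t] - 0.1 * ref[1, t - l] + b * ref[2, t - l]
    ref[2, t] <- eps[2, t] - 0.1 * ref[2, t - l] + d * ref[1, t - l]
  }
  expect_equal(unclass(x), ref, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("accumulation form matches a naive scalar reference implementation", {
  # reference: literal per-timepoint, per-connection accumulation with
  # the same pre-drawn lags and noise (no chunking)
  n <- 600
  m <- ar_model_nonmarkovian(n_timepoints = n, n_runs = 1)
  x <- simulate(m, seed = 41)[[1]]
  set.seed(41)
  eps <- matrix(rnorm(2 * n, sd = sqrt(0.5)), 2, n)
  support <- c(9L, 10L, 11L)
  ldraw <- array(support[sample.int(3, 2 * 2 * n, replace = TRUE,
                                    prob = c(0.25, 0.5, 0.25))],
                 dim = c(2, 2, n))
  ref <- eps
  for (t in 1:n) {
    for (j in 1:2) {
      for (i in 1:2) {
        tt <- t + ldraw[i, j, t]
        if (tt > n) next
        coef <- if (i == j) -0.1 else if (ref[j, t] > 0.9) 0.9 else 0
        ref[i, tt] <- ref[i, tt] + coef * ref[j, t]
      }
    }
  }
  expect_equal(unclass(x), ref, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("channels are uncorrelated at lags shorter than the coupling lag", {
  m <- ar_model_nonlinear(n_timepoints = 20000, n_runs = 1)
  x <- simulate(m, seed = 51)[[1]]
  n <- ncol(x)
  # lag 0 is excluded: X(t) and Y(t) share the ancestors X(t-l), Y(t-l);
  # strictly intermediate lags 0 < k < l have no common ancestry
  for (k in 1:5) {
    r <- cor(x[1, 1:(n - k)], x[2, (1 + k):n])
    expect_lt(abs(r), 4 / sqrt(n))  # consistent with zero
  }
  # at the coupling lag the dependence is real
  r10 <- cor(x[1, 1:(n - 10)], x[2, 11:n])
  expect_gt(abs(r10), 10 / sqrt(n))
})

test_that("a diverging configuration aborts with a diagnostic", {
  m <- ar_model(self = 2.5, cross = 0, threshold = Inf, lag = 2,
                noise_var = 1, n_timepoints = 400, n_runs = 1, guard = 1e6)
  expect_error(simulate(m, seed = 61), "blow-up.*run 1", perl = TRUE)
})

test_that("burn-in discards initial timepoints", {
  m <- ar_model_nonlinear(n_timepoints = 500, n_runs = 1, burn_in = 100)
  x <- simulate(m, seed = 71)[[1]]
  expect_equal(ncol(x), 400)
})
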
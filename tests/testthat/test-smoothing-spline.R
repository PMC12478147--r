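# csaps-style cubic smoothing spline.

test_that("the smoothing spline solves the penalized least-squares problem", {
  set.seed(4)
  x <- sort(stats::runif(12)); y <- stats::rnorm(12); p <- 0.3
  f <- morphoring:::csaps_fit(x, y, p)
  # brute-force quadratic program over the smoothed values
  h <- diff(x); n <- 12L
  i <- 1:(n - 2L)
  Qm <- matrix(0, n, n - 2L)
  for (k in i) {
    Qm[k, k] <- 1 / h[k]
    Qm[k + 1L, k] <- -(1 / h[k] + 1 / h[k + 1L])
    Qm[k + 2L, k] <- 1 / h[k + 1L]
  }
  Tm <- diag((h[i] + h[i + 1L]) / 3)
  for (k in 1:(n - 3L)) Tm[k, k + 1L] <- Tm[k + 1L, k] <- h[k + 1L] / 6
  obj <- function(a) {
    g <- solve(Tm, t(Qm) %*% a)
    p * sum((y - a)^2) + (1 - p) * as.numeric(t(g) %*% Tm %*% g)
  }
  o <- stats::optim(y, obj, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(f(x), o$par, tolerance = 1e-6)
})

test_that("the parameter limits give interpolation and the fitted line", {
  set.seed(5)
  x <- sort(stats::runif(15)); y <- stats::rnorm(15)
  expect_equal(morphoring:::csaps_fit(x, y, 1)(x), y, tolerance = 1e-12)
  f0 <- morphoring:::csaps_fit(x, y, 1e-12)
  line <- stats::lm(y ~ x)
  expect_equal(f0(x), unname(stats::fitted(line)), tolerance = 1e-4)
})
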
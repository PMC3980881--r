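test_that("flat and linear windows are fitted exactly", {
  expect_equal(dep_slope(rep(4.2, 7)), 0)
  expect_equal(dep_intercept(rep(4.2, 7)), 4.2)
  x <- 0:9
  expect_equal(dep_slope(x), 1)
  x20 <- 0:19
  expect_equal(dep_slope(2 * x20 + 5), 2, tolerance = 1e-9)
  expect_equal(dep_intercept(2 * x20 + 5), 5, tolerance = 1e-9)
  expect_error(dep_slope(c(1, 2)), "at least 3")
  expect_error(dep_intercept(c(1, 2)), "at least 3")
})

test_that("closed-form slope equals the general least-squares fit", {
  set.seed(61)
  worst <- 0
  for (i in 1:300) {
    n <- sample(3:100, 1)
    e <- switch(sample(3, 1),
                rnorm(n, sd = 10),
                rexp(n),
                cumsum(rnorm(n)))
    fit <- stats::lm(e ~ x, data = data.frame(x = 0:(n - 1), e = e))
    worst <- max(worst,
                 abs(dep_slope(e) - unname(stats::coef(fit)[2])),
                 abs(dep_intercept(e) - unname(stats::coef(fit)[1])))
  }
  expect_lt(worst, 1e-9)
})

test_that("the fitted line minimizes the residual sum of squares", {
  set.seed(62)
  rss <- function(a, b, e) sum((e - (a * (0:(length(e) - 1)) + b))^2)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    e <- rnorm(n, sd = 3)
    a <- dep_slope(e); b <- dep_intercept(e)
    best <- rss(a, b, e)
    for (j in 1:100) {
      expect_lte(best,
                 rss(a + rnorm(1, sd = 0.05), b + rnorm(1, sd = 0.05), e))
    }
  }
})

test_that("equilibrium detection triggers on flat traces only", {
  w <- equilibrium_window(n = 10, epsilon = 0.5)
  for (e in rep(3, 9)) w <- dep_observe(w, e)
  expect_false(dep_converged(w))  # under-filled: never signals
  w <- dep_observe(w, 3)
  expect_true(dep_converged(w))
  # unit ramp exceeds epsilon = 0.5
  w2 <- equilibrium_window(n = 10, epsilon = 0.5)
  for (e in 0:9) w2 <- dep_observe(w2, e)
  expect_false(dep_converged(w2))
  # sliding: window keeps only the most recent n energies
  for (e in rep(1, 10)) w2 <- dep_observe(w2, e)
  expect_identical(w2$energies, rep(1, 10))
  expect_true(dep_converged(w2))
})

test_that("convergence on noise windows becomes likelier as epsilon grows", {
  set.seed(63)
  hit <- function(eps) {
    mean(replicate(300, {
      abs(dep_slope(rnorm(30, sd = 1))) < eps
    }))
  }
  p <- c(hit(1e-3), hit(1e-2), hit(1e-1))
  expect_true(all(diff(p) > 0))
  expect_lt(p[1], 0.10)
  expect_gt(p[3], 0.80)
})
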
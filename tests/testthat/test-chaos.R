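test_that("map evaluation matches the closed forms", {
  m1 <- chaotic_map("M1")
  expect_equal(eval_chaotic_map(m1, 2 / pi), 1.0)
  expect_equal(eval_chaotic_map(m1, 1 / pi), 0.0, tolerance = 1e-12)
  # independent evaluation of the product form at an interior point
  m4 <- chaotic_map("M4")
  expect_equal(eval_chaotic_map(m4, 0.5), sin(2) * sin(10))
  expect_equal(eval_chaotic_map(m4, 0.5), -0.4946770, tolerance = 1e-6)
  m2 <- chaotic_map("M2")
  expect_equal(eval_chaotic_map(m2, 0.5), sin(4))
  m3 <- chaotic_map("M3")
  expect_equal(eval_chaotic_map(m3, 0.5), sin(400))
})

test_that("singular points are rejected, never clamped", {
  m1 <- chaotic_map("M1")
  expect_error(eval_chaotic_map(m1, 0), "guard")
  expect_error(eval_chaotic_map(m1, 1e-9), "guard")
  expect_silent(eval_chaotic_map(m1, 1))  # 1 is regular for M1
  for (id in c("M2", "M3", "M4")) {
    expect_error(eval_chaotic_map(chaotic_map(id), 1), "guard")
  }
})

test_that("all four maps stay within [-1, 1] over dense sampling", {
  set.seed(11)
  x <- runif(1e4, 1e-3, 1 - 1e-3)
  for (id in c("M1", "M2", "M3", "M4")) {
    y <- eval_chaotic_map(chaotic_map(id), x)
    expect_true(all(abs(y) <= 1))
  }
})

test_that("chaotic iteration is reproducible and non-degenerate", {
  run_chain <- function(n) {
    set.seed(5)
    st <- chaos_state("M1", x0 = 0.3)
    xs <- numeric(n); ys <- numeric(n)
    for (i in seq_len(n)) {
      step <- advance_chaos(st)
      st <- step$state
      xs[i] <- st$x; ys[i] <- step$y
    }
    list(xs = xs, ys = ys)
  }
  a <- run_chain(1000)
  b <- run_chain(1000)
  expect_identical(a, b)
  expect_true(all(abs(a$ys) <= 1))
  expect_true(all(a$xs > 1e-6 & a$xs < 1 - 1e-6))
  expect_true(all(diff(a$xs) != 0))  # no two consecutive iterates equal
})

test_that("chaotic perturbation moves exactly one coordinate, in range", {
  set.seed(21)
  st <- chaos_state("M2", x0 = 0.4, amplitude_deg = 90)
  sigma <- random_conformation(12)
  for (i in 1:50) {
    out <- chaotic_perturb(sigma, st)
    st <- out$state
    expect_lte(sum(out$sigma != sigma), 1L)
    expect_true(all(out$sigma > -180 & out$sigma <= 180))
    sigma <- out$sigma
  }
})

test_that("zero amplitude is the identity and wrapping is circular", {
  set.seed(3)
  st0 <- chaos_state("M1", amplitude_deg = 0)
  sigma <- random_conformation(5)
  expect_identical(chaotic_perturb(sigma, st0)$sigma, sigma)
  expect_identical(wrap_angle(179 + 2), -179)
  expect_identical(wrap_angle(-180), 180)
  expect_error(chaotic_perturb(numeric(0), st0), "at least one")
})
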
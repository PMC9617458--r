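test_that("log-partition closed forms match trivial cases", {
  expect_equal(conditional_log_partition(0, 0, 1), 0)
  expect_equal(conditional_log_partition(1, 0, 1), log(exp(1) - 1),
               tolerance = 1e-12)
  # quadrature-anchored case with a genuine quadratic term
  expect_equal(conditional_log_partition(1, -2, 0.7),
               quad_log_partition(1, -2, 0.7), tolerance = 1e-10)
  expect_equal(conditional_log_partition(0, 0, 0), -Inf)
  expect_error(conditional_log_partition(0, 0, -0.1), "nonnegative")
  expect_error(conditional_log_partition(Inf, 0, 1), "finite")
})

test_that("log-partition agrees with quadrature across all branches", {
  grid <- expand.grid(
    a = c(-20, -5, -1, 0, 0.5, 5, 20),
    b = c(-50, -5, -0.5, -1e-3, -1e-7, 0, 1e-7, 1e-3, 0.5, 5, 50),
    u = c(1e-3, 0.1, 0.5, 1)
  )
  got <- conditional_log_partition(grid$a, grid$b, grid$u)
  want <- mapply(quad_log_partition, grid$a, grid$b, grid$u)
  expect_lt(max(abs(got - want) / pmax(abs(want), 1)), 1e-10)
})

test_that("conditional densities integrate to one and match closed forms", {
  # flat conditional: log-density is -log(upper)
  tl0 <- tilde_parameters(c(0, 0), matrix(0, 2, 2))
  ctx <- conditional_context(1, 0.4)
  expect_equal(conditional_log_density(0.3, ctx, tl0), -log(0.6))

  # normalization to 1 by quadrature for random tilde and contexts
  set.seed(23)
  for (rep in 1:10) {
    tl <- random_tilde(3, scale = 4)
    ctx <- conditional_context(sample(2, 1), stats::runif(1, 0, 0.9))
    total <- stats::integrate(
      function(x) vapply(x, function(xi)
        exp(conditional_log_density(xi, ctx, tl)), numeric(1)),
      0, ctx$upper, rel.tol = 1e-10
    )$value
    expect_equal(total, 1, tolerance = 1e-8)
  }

  # N = 2 truncated exponential: mean of e^{2s} on [0,1]
  tl2 <- tilde_parameters(2, matrix(0, 1, 1))
  ctx2 <- conditional_context(1, numeric(0))
  m <- stats::integrate(
    function(x) vapply(x, function(xi)
      xi * exp(conditional_log_density(xi, ctx2, tl2)), numeric(1)),
    0, 1, rel.tol = 1e-10
  )$value
  expect_equal(m, 1 / (1 - exp(-2)) - 1 / 2, tolerance = 1e-8)

  expect_error(conditional_log_density(0.7, ctx, tl0), "upper")
})

test_that("conditional moments match quadrature-based expectations", {
  set.seed(41)
  cases <- expand.grid(a = c(-15, -2, 0, 2, 15),
                       b = c(-30, -1, 0, 1, 30),
                       u = c(0.05, 0.4, 1))
  cp <- compmaxent:::.cond_partition(cases$a, cases$b, cases$u)
  for (k in seq_len(nrow(cases))) {
    f <- function(s) exp(cases$a[k] * s + 0.5 * cases$b[k] * s^2 -
                           cp$logZ[k])
    m1 <- stats::integrate(function(s) s * f(s), 0, cases$u[k],
                           rel.tol = 1e-11)$value
    m2 <- stats::integrate(function(s) s^2 * f(s), 0, cases$u[k],
                           rel.tol = 1e-11)$value
    expect_equal(cp$E1[k], m1, tolerance = 1e-8)
    expect_equal(cp$E2[k], m2, tolerance = 1e-8)
  }
})
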
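test_that("the density exponent evaluates hand-checked cases", {
  p0 <- cme_parameters(c(0, 0, 0), matrix(0, 3, 3))
  expect_equal(log_unnormalized_density(c(0.2, 0.3, 0.5), p0), 0)

  p1 <- cme_parameters(c(1, 0), matrix(0, 2, 2))
  expect_equal(log_unnormalized_density(c(0.25, 0.75), p1), 0.25)

  K <- matrix(0, 3, 3); K[1, 2] <- K[2, 1] <- 2
  p2 <- cme_parameters(c(0, 0, 0), K)
  expect_equal(log_unnormalized_density(c(0.5, 0.5, 0), p2), 0.5)

  expect_error(log_unnormalized_density(c(0.5, 0.5), p2), "length")
})

test_that("tilde reduction matches its hand evaluation", {
  K <- matrix(0, 3, 3); K[1, 3] <- K[3, 1] <- 1
  p <- cme_parameters(c(0, 0, 0), K)
  tl <- tilde_from_refined(p)
  expect_equal(tl$h_tilde, c(1, 0))
  expect_equal(tl$K_tilde, matrix(c(-2, -1, -1, 0), 2))

  # zero map
  tl0 <- tilde_from_refined(cme_parameters(c(0, 0, 0), matrix(0, 3, 3)))
  expect_equal(tl0$h_tilde, c(0, 0))
  expect_equal(tl0$K_tilde, matrix(0, 2, 2))
})

test_that("refinement inverts the tilde reduction and fixes the gauge", {
  # hand case: feeding the reduced parameters back recovers K_13 = 1, h = 0
  p <- refine_parameters(tilde_parameters(c(1, 0), matrix(c(-2, -1, -1, 0), 2)))
  expect_equal(p$h, c(0, 0, 0))
  expect_equal(p$K[1, 3], 1)
  expect_equal(p$K[1, 2], 0)

  # simple symmetric case reduces to the average
  p2 <- refine_parameters(tilde_parameters(c(0, 0),
                                           matrix(c(0, 0.7, 0.7, 0), 2)))
  expect_equal(p2$K[1, 2], 0.7)

  # round trip on random refined models, to 1e-10
  set.seed(31)
  for (N in c(2, 3, 5, 8)) {
    p <- random_cme(N)
    p_back <- refine_parameters(tilde_from_refined(p))
    expect_lt(max(abs(p_back$K - p$K)), 1e-10)
    expect_lt(max(abs(p_back$h - p$h)), 1e-10)
  }

  # arbitrary asymmetric tilde input still yields a valid gauge
  for (N in c(3, 5)) {
    p <- refine_parameters(random_tilde(N))
    expect_equal(p$K, t(p$K))
    expect_equal(unname(diag(p$K)), rep(0, N))
    expect_equal(p$h[N], 0)
  }
})

test_that("the exponent is invariant under the tilde reparameterization", {
  # with s_N eliminated, the refined and tilde exponents differ by a
  # constant only; check the spread of the difference over random draws
  set.seed(17)
  for (N in c(3, 4)) {
    p <- random_cme(N)
    tl <- tilde_from_refined(p)
    g <- matrix(stats::rgamma(30 * N, 1), 30)
    s <- g / rowSums(g)
    full <- apply(s, 1, log_unnormalized_density, params = p)
    red <- vapply(seq_len(30), function(d) {
      x <- s[d, -N]
      Ksym <- (tl$K_tilde + t(tl$K_tilde)) / 2
      off <- Ksym; diag(off) <- 0
      sum((tl$h_tilde + 0.5 * diag(tl$K_tilde) * x + 0.5 * off %*% x) * x)
    }, numeric(1))
    expect_lt(stats::sd(full - red), 1e-10)
  }
})

test_that("influence weights are a shift-invariant softmax", {
  expect_equal(influence_weights(c(5, 5, 5)), rep(1 / 3, 3))
  expect_equal(influence_weights(c(log(2), 0)), c(2 / 3, 1 / 3))
  set.seed(5)
  h <- stats::rnorm(6, sd = 3)
  expect_equal(influence_weights(h), influence_weights(h + 17.3))
  expect_equal(sum(influence_weights(h)), 1)
  expect_true(all(influence_weights(c(-800, 0, 800)) >= 0))
})

test_that("parameter validation enforces the gauge", {
  expect_error(cme_parameters(c(1, 1), matrix(0, 2, 2)), "gauge")
  expect_error(cme_parameters(c(1, 0), matrix(c(1, 0, 0, 0), 2)), "diagonal")
  expect_error(cme_parameters(c(1, 0), matrix(c(0, 1, 2, 0), 2)), "symmetric")
  # reference other than the last component
  p <- cme_parameters(c(0, 1, 2), matrix(0, 3, 3), reference = 1)
  expect_equal(p$reference, 1L)
  tl <- tilde_from_refined(p)
  expect_equal(tl$h_tilde, c(1, 2))
})
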
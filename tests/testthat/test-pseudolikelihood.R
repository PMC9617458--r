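test_that("the objective equals the average conditional log-density", {
  set.seed(13)
  for (N in c(2, 3, 5)) {
    tab <- rdirichlet_table(40, stats::runif(N, 0.5, 2))
    tl <- random_tilde(N, scale = 3)
    s <- unclass(tab)
    for (i in seq_len(N - 1)) {
      direct <- pseudolikelihood_objective(i, tl, tab)
      avg <- mean(vapply(seq_len(nrow(s)), function(d) {
        ctx <- conditional_context(i, s[d, setdiff(seq_len(N - 1), i)])
        conditional_log_density(s[d, i], ctx, tl)
      }, numeric(1)))
      expect_equal(direct, avg, tolerance = 1e-10)
    }
  }
})

test_that("tilde all zero gives the log-volume objective (zero for N = 2)", {
  set.seed(3)
  tab <- rdirichlet_table(50, c(1, 1))
  tl <- tilde_parameters(0, matrix(0, 1, 1))
  expect_equal(pseudolikelihood_objective(1, tl, tab), 0)

  tab3 <- rdirichlet_table(50, c(1, 1, 1))
  tl3 <- tilde_parameters(c(0, 0), matrix(0, 2, 2))
  s <- unclass(tab3)
  expect_equal(pseudolikelihood_objective(1, tl3, tab3),
               -mean(log(1 - s[, 2])), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(29)
  for (N in c(2, 3, 4)) {
    tab <- rdirichlet_table(30, stats::runif(N, 0.5, 2))
    s <- unclass(tab)
    nd <- compmaxent:::.node_data(s, 1L)
    for (rep in 1:3) {
      th <- stats::runif(N, -4, 4)
      g <- compmaxent:::.node_gradient(th, nd, ridge = 0.1)
      gfd <- vapply(seq_along(th), function(k) {
        e <- numeric(length(th)); e[k] <- 1e-6
        (compmaxent:::.node_objective(th + e, nd, 0.1) -
           compmaxent:::.node_objective(th - e, nd, 0.1)) / 2e-6
      }, numeric(1))
      expect_equal(g, gfd, tolerance = 1e-6)
    }
  }
})

test_that("the fitted point is a maximum of each node objective", {
  set.seed(37)
  tab <- rdirichlet_table(300, c(2, 1, 1.5))
  ft <- cme_fit(tab)
  s <- unclass(tab)
  for (i in 1:2) {
    nd <- compmaxent:::.node_data(s, i)
    rest <- setdiff(1:2, i)
    th_hat <- c(ft$tilde$h_tilde[i], ft$tilde$K_tilde[i, i],
                ft$tilde$K_tilde[i, rest])
    f_hat <- compmaxent:::.node_objective(th_hat, nd, 0)
    for (k in seq_along(th_hat)) {
      e <- numeric(length(th_hat)); e[k] <- 0.05
      expect_lt(compmaxent:::.node_objective(th_hat + e, nd, 0), f_hat)
      expect_lt(compmaxent:::.node_objective(th_hat - e, nd, 0), f_hat)
    }
  }
})

test_that("flat-simplex data fit to near-zero parameters", {
  set.seed(43)
  ft <- cme_fit(rdirichlet_table(5000, c(1, 1, 1)))
  expect_true(all(ft$converged))
  expect_lt(max(abs(ft$params$h)), 0.6)
  expect_lt(max(abs(ft$params$K)), 1.2)
})

test_that("the refined fit does not depend materially on the reference component", {
  # the estimand (refined K, Q) is reference-free, but each reference uses a
  # different subset of conditionals, so finite-sample estimates agree only
  # up to O(1/sqrt(D)); check they converge toward each other as D grows
  set.seed(47)
  K <- matrix(0, 3, 3); K[1, 2] <- K[2, 1] <- 3; K[1, 3] <- K[3, 1] <- -1
  truep <- cme_parameters(c(0.5, -0.2, 0), K)
  gap <- vapply(c(500, 4000), function(D) {
    tab <- cme_sample(truep, sampler_config(D, thin = 20, seed = 9))
    f3 <- cme_fit(tab)
    f1 <- cme_fit(tab, reference = 1)
    expect_equal(f1$reference, "c1")
    expect_lt(max(abs(f3$params$Q - f1$params$Q)), 0.05)
    max(abs(f3$params$K - f1$params$K))
  }, numeric(1))
  expect_lt(gap[2], gap[1])
  expect_lt(gap[2], 0.25)
})

test_that("degenerate data require ridge regularization", {
  s <- cbind(rep(0.5, 20), rep(0.3, 20), rep(0.2, 20))
  tab <- composition_table(s)
  expect_error(cme_fit(tab), "ridge")
  expect_warning(ftr <- cme_fit(tab, ridge = 1e-3), "degenerate")
  expect_true(all(is.finite(ftr$params$K)))
})

test_that("recovery error of a known model shrinks with sample size", {
  set.seed(53)
  K <- matrix(0, 3, 3); K[1, 2] <- K[2, 1] <- 5
  truep <- cme_parameters(c(0, 0, 0), K)
  err <- vapply(c(300, 3000), function(D) {
    dat <- cme_sample(truep, sampler_config(D, thin = 40, seed = 61))
    abs(cme_fit(dat)$params$K[1, 2] - 5)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2] / 5, 0.15)
})
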
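test_that("single-species dynamics reduce to logistic growth", {
  cfg <- clv_config(N = 1L, alpha = matrix(1, 1, 1), t_max = 30)
  tr <- integrate_clv(cfg, 0.01)
  expect_equal(tr$abundances[length(tr$times)], 1, tolerance = 1e-6)
  # the fixed point is stationary
  expect_equal(utils::tail(tr$abundances, 2)[1],
               utils::tail(tr$abundances, 2)[2], tolerance = 1e-9)
})

test_that("symmetric mutualism converges to the coexistence fixed point", {
  cfg <- clv_config(alpha_offdiag = 0.6, t_max = 80)
  tr <- integrate_clv(cfg, c(0.2, 0.5, 0.9))
  endpoint <- tr$abundances[nrow(tr$abundances), ]
  expect_equal(endpoint, rep(1 / 2.2, 3), tolerance = 1e-5)
  # normalized fixed point is equal shares
  comp <- normalize_composition(tr)
  expect_equal(unname(unclass(comp)[nrow(comp), ]), rep(1 / 3, 3),
               tolerance = 1e-6)
})

test_that("strong competition is winner-take-all with an IC-dependent winner", {
  cfg <- clv_config(alpha_offdiag = 4, t_max = 100)
  e1 <- integrate_clv(cfg, c(0.2, 0.5, 0.9))
  e1 <- e1$abundances[nrow(e1$abundances), ]
  expect_equal(sort(e1), c(0, 0, 1), tolerance = 1e-6)
  expect_equal(which.max(e1), 3L)      # largest initial abundance wins
  e2 <- integrate_clv(cfg, c(0.9, 0.5, 0.2))
  expect_equal(which.max(e2$abundances[nrow(e2$abundances), ]), 1L)
})

test_that("halving dt changes endpoints negligibly", {
  cfg1 <- clv_config(alpha_offdiag = 0.9, t_max = 20, dt = 0.01)
  cfg2 <- clv_config(alpha_offdiag = 0.9, t_max = 20, dt = 0.005)
  s0 <- c(0.3, 0.6, 0.1)
  e1 <- integrate_clv(cfg1, s0)$abundances
  e2 <- integrate_clv(cfg2, s0)$abundances
  expect_lt(max(abs(e1[nrow(e1), ] - e2[nrow(e2), ])), 1e-6)
})

test_that("normalization maps rows onto the simplex and keeps boundaries", {
  expect_equal(unname(unclass(normalize_composition(rbind(c(2, 2, 2))))[1, ]),
               rep(1 / 3, 3))
  expect_equal(unname(unclass(normalize_composition(rbind(c(1, 0, 0))))[1, ]),
               c(1, 0, 0))
  expect_error(normalize_composition(rbind(c(0, 0, 0))), "all-zero")
})

test_that("datasets are seeded, on-simplex, and symmetric in species", {
  cfg <- clv_preset("mutualism", n_samples = 500L, seed = 3L)
  d1 <- clv_dataset(cfg)
  d2 <- clv_dataset(cfg)
  expect_identical(unclass(d1), unclass(d2))
  expect_lt(max(abs(rowSums(d1) - 1)), 1e-12)
  # permutation symmetry of the species: equal means within sampling error
  expect_equal(unname(colMeans(d1)), rep(1 / 3, 3), tolerance = 0.05)
})

test_that("noiseless single-trajectory sampling collapses to the fixed point", {
  cfg <- clv_config(alpha_offdiag = 0.6, noise_sd = 0, n_samples = 50L,
                    n_trajectories = 1L, t_max = 200, seed = 8L)
  d <- clv_dataset(cfg)
  expect_lt(max(apply(unclass(d), 2, stats::sd)), 1e-6)
  expect_equal(unname(unclass(d)[1, ]), rep(1 / 3, 3), tolerance = 1e-4)
})

test_that("the modality classifier resolves clear regimes", {
  set.seed(2)
  # unimodal: one central hump
  x_uni <- stats::rbeta(2000, 8, 16)
  expect_equal(count_abundance_modes(x_uni), 1L)
  # bimodal at the simplex vertices (competition marginal)
  x_bi <- c(stats::rbeta(700, 40, 2), stats::rbeta(1300, 2, 40))
  expect_equal(count_abundance_modes(x_bi), 2L)
  # shallow lumps below the prominence threshold do not count
  x_lump <- c(stats::rnorm(1800, 0.4, 0.08), stats::rnorm(200, 0.7, 0.02))
  expect_equal(count_abundance_modes(x_lump), 1L)
})
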
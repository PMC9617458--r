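# Competitive Lotka-Volterra (cLV) synthetic-data generator.
#
# Species abundances evolve as
#   ds_i/dt = r_i s_i (1 - sum_j alpha_ij s_j / kappa_i),
# are perturbed with Gaussian observation noise, clamped at zero,
# normalized to relative abundances, and sampled at random times across
# independent trajectories.  With symmetric interactions alpha and
# r = kappa = alpha_ii = 1 the model has three regimes: mutualism
# (alpha < 1, stable coexistence), neutralism (alpha near the critical
# value), and competition (alpha >> 1, winner-take-all), which appear in
# the composition distribution as a unimodal-to-multimodal transition.

#' Competitive Lotka-Volterra configuration
#'
#' Defaults follow the canonical symmetric three-species setup: growth
#' rates, carrying capacities and self-interactions all 1, equal
#' off-diagonal interaction `alpha_offdiag`.  Presets: `"mutualism"`
#' (alpha = 0.6), `"neutralism"` (alpha = 1.2), `"competition"`
#' (alpha = 4.0).
#'
#' @param N species count.
#' @param r length-N growth rates (1/time).
#' @param kappa length-N carrying capacities (abundance units).
#' @param alpha N x N interaction matrix (dimensionless); if missing, built
#'   from `alpha_offdiag` with unit diagonal.
#' @param alpha_offdiag scalar off-diagonal interaction used when `alpha`
#'   is not given.
#' @param t_max integration time span.
#' @param dt fixed integrator step.
#' @param noise_sd Gaussian observation-noise standard deviation, in raw
#'   abundance units before normalization.
#' @param n_samples number of sampled time points in the dataset.
#' @param n_trajectories independent random initial conditions.
#' @param transient_frac leading fraction of each trajectory excluded from
#'   sampling so draws reflect (quasi-)stationary behavior.
#' @param seed integer seed.
#' @return an object of class `clv_config`.
#' @export
clv_config <- function(N = 3L, r = rep(1, N), kappa = rep(1, N),
                       alpha = NULL, alpha_offdiag = 0.6,
                       t_max = 100, dt = 0.01, noise_sd = 0.05,
                       n_samples = 2000L, n_trajectories = 100L,
                       transient_frac = 0.5, seed = 1L) {
  if (is.null(alpha)) {
    alpha <- matrix(alpha_offdiag, N, N)
    diag(alpha) <- 1
  }
  alpha <- as.matrix(alpha)
  if (!all(dim(alpha) == N)) stop("alpha must be N x N")
  if (any(r <= 0) || any(kappa <= 0)) stop("r and kappa must be positive")
  if (dt <= 0 || t_max <= dt) stop("need 0 < dt < t_max")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (any(!is.finite(alpha))) stop("alpha must be finite")
  if (transient_frac < 0 || transient_frac >= 1) stop("transient_frac in [0,1)")
  structure(list(N = as.integer(N), r = r, kappa = kappa, alpha = alpha,
                 t_max = t_max, dt = dt, noise_sd = noise_sd,
                 n_samples = as.integer(n_samples),
                 n_trajectories = as.integer(n_trajectories),
                 transient_frac = transient_frac, seed = as.integer(seed)),
            class = "clv_config")
}

#' @rdname clv_config
#' @param preset one of `"mutualism"`, `"neutralism"`, `"competition"`.
#' @param ... overrides passed to [clv_config()].
#' @export
clv_preset <- function(preset = c("mutualism", "neutralism", "competition"),
                       ...) {
  preset <- match.arg(preset)
  a <- c(mutualism = 0.6, neutralism = 1.2, competition = 4.0)[[preset]]
  clv_config(alpha_offdiag = a, ...)
}

# RK4 derivative; rows are trajectories.  Negative states are treated as 0.
.clv_deriv <- function(S, r, kappa, alpha) {
  S <- pmax(S, 0)
  growth <- 1 - (S %*% t(alpha)) / rep(kappa, each = nrow(S))
  S * rep(r, each = nrow(S)) * growth
}

#' Integrate competitive Lotka-Volterra dynamics
#'
#' Fixed-step classical 4th-order Runge-Kutta integration of the cLV
#' equations from one initial abundance vector, clamping negative
#' excursions to zero after each step.  Deterministic given its inputs.
#'
#' @param config a [clv_config()].
#' @param s0 length-N vector of positive initial abundances.
#' @return an object of class `clv_trajectory`: list with `times` and the
#'   `T x N` abundance matrix `abundances`.
#' @export
integrate_clv <- function(config, s0) {
  stopifnot(inherits(config, "clv_config"))
  if (length(s0) != config$N || any(s0 <= 0)) {
    stop("s0 must be a positive length-N vector")
  }
  traj <- .integrate_clv_multi(config, matrix(s0, nrow = 1L))
  structure(list(times = traj$times, abundances = traj$ab[, 1L, ]),
            class = "clv_trajectory")
}

# Batched RK4 over n_traj trajectories at once; returns times and a
# [time, trajectory, species] array.
.integrate_clv_multi <- function(config, S0) {
  nt <- nrow(S0)
  N <- config$N
  steps <- ceiling(config$t_max / config$dt)
  times <- seq(0, by = config$dt, length.out = steps + 1L)
  ab <- array(0, dim = c(steps + 1L, nt, N))
  S <- S0
  ab[1L, , ] <- S
  dt <- config$dt
  r <- config$r; kappa <- config$kappa; alpha <- config$alpha
  lim <- 10 * max(kappa)
  for (k in seq_len(steps)) {
    k1 <- .clv_deriv(S, r, kappa, alpha)
    k2 <- .clv_deriv(S + 0.5 * dt * k1, r, kappa, alpha)
    k3 <- .clv_deriv(S + 0.5 * dt * k2, r, kappa, alpha)
    k4 <- .clv_deriv(S + dt * k3, r, kappa, alpha)
    S <- S + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    S <- pmax(S, 0)                      # clamp negative excursions
    if (any(S > lim)) {
      stop("integration unstable (abundance exceeded 10 * max carrying ",
           "capacity); try a smaller dt")
    }
    ab[k + 1L, , ] <- S
  }
  list(times = times, ab = ab)
}

#' Normalize a trajectory to relative abundances
#'
#' Divides each time point's abundances by their total, mapping raw
#' populations onto the simplex.
#'
#' @param traj a `clv_trajectory` (or a plain `T x N` abundance matrix).
#' @return a [composition_table()] with one row per time point.
#' @export
normalize_composition <- function(traj) {
  ab <- if (inherits(traj, "clv_trajectory")) traj$abundances else as.matrix(traj)
  tot <- rowSums(ab)
  if (any(tot <= 0)) stop("cannot normalize a time point with all-zero abundances")
  composition_table(ab / tot, renorm_tol = 1e-9)
}

#' Generate a synthetic compositional dataset from cLV dynamics
#'
#' Runs `n_trajectories` integrations from i.i.d. uniform(0, 1) initial
#' abundances, picks `n_samples` (trajectory, time) pairs uniformly at
#' random from the post-transient window, perturbs the raw abundances with
#' i.i.d. Gaussian noise, clamps at zero (redrawing the noise in the rare
#' all-zero case) and normalizes.  Deterministic given the seed.
#'
#' @param config a [clv_config()].
#' @return a [composition_table()] of `n_samples` compositions.
#' @export
clv_dataset <- function(config) {
  stopifnot(inherits(config, "clv_config"))
  set.seed(config$seed)
  N <- config$N
  S0 <- matrix(stats::runif(config$n_trajectories * N, 0, 1),
               config$n_trajectories, N)
  S0 <- pmax(S0, 1e-6)
  traj <- .integrate_clv_multi(config, S0)
  n_t <- length(traj$times)
  first_ok <- ceiling(config$transient_frac * n_t) + 1L
  pick_t <- sample(seq.int(first_ok, n_t), config$n_samples, replace = TRUE)
  pick_traj <- sample.int(config$n_trajectories, config$n_samples,
                          replace = TRUE)
  raw <- traj$ab[cbind(rep(pick_t, N), rep(pick_traj, N),
                       rep(seq_len(N), each = config$n_samples))]
  raw <- matrix(raw, config$n_samples, N)
  noisy <- pmax(raw + matrix(stats::rnorm(length(raw), 0, config$noise_sd),
                             nrow(raw), N), 0)
  bad <- rowSums(noisy) <= 0
  while (any(bad)) {                     # redraw noise for all-zero rows
    k <- which(bad)
    noisy[k, ] <- pmax(raw[k, , drop = FALSE] +
                         matrix(stats::rnorm(length(k) * N, 0, config$noise_sd),
                                length(k), N), 0)
    bad[k] <- rowSums(noisy[k, , drop = FALSE]) <= 0
  }
  composition_table(noisy / rowSums(noisy),
                    component_names = paste0("sp", seq_len(N)),
                    renorm_tol = 1e-9)
}

#' Count modes of a marginal abundance distribution
#'
#' Kernel density estimate of one species' relative abundance on [0, 1]
#' (with boundary reflection so modes at the simplex vertices are not
#' flattened), followed by peak counting with a prominence filter: a local
#' maximum counts as a mode only if it stands above the deepest valley
#' separating it from a taller peak by at least `prominence` times the
#' density maximum.
#'
#' @param x numeric vector of marginal relative abundances in [0, 1].
#' @param bw kernel bandwidth; the default is Silverman's rule with a floor
#'   of 0.05, since the features that matter (vertex modes versus a central
#'   hump) are separated by about half the unit interval while
#'   finite-ensemble lumpiness lives at much smaller scales.
#' @param prominence minimum relative prominence of a reported mode.
#' @return integer number of modes.
#' @export
count_abundance_modes <- function(x, bw = NULL, prominence = 0.1) {
  x <- x[is.finite(x)]
  xr <- c(x, -x, 2 - x)                  # reflect at both boundaries
  if (is.null(bw)) bw <- max(stats::bw.nrd0(x), 0.05)
  d <- stats::density(xr, bw = bw, from = 0, to = 1, n = 512L)
  y <- d$y
  n <- length(y)
  # local maxima (plateau-safe via run-length collapse)
  r <- rle(y)
  vy <- r$values
  pos_end <- cumsum(r$lengths)
  is_max <- c(vy[1] > vy[2],
              vy[seq(2, length(vy) - 1)] > vy[seq(1, length(vy) - 2)] &
                vy[seq(2, length(vy) - 1)] > vy[seq(3, length(vy))],
              vy[length(vy)] > vy[length(vy) - 1])
  peaks <- pos_end[is_max]
  if (length(peaks) <= 1L) return(length(peaks))
  ph <- y[peaks]
  keep <- logical(length(peaks))
  for (k in seq_along(peaks)) {
    taller <- which(ph > ph[k])
    if (length(taller) == 0L) { keep[k] <- TRUE; next }
    # deepest valley between this peak and the nearest taller peak
    prom <- min(vapply(taller, function(tk) {
      rng <- if (peaks[tk] < peaks[k]) seq(peaks[tk], peaks[k]) else seq(peaks[k], peaks[tk])
      ph[k] - min(y[rng])
    }, numeric(1)))
    keep[k] <- prom >= prominence * max(y)
  }
  sum(keep)
}

#' Locate the unimodal-to-multimodal transition of symmetric cLV
#'
#' Sweeps the symmetric off-diagonal interaction strength, generates a cLV
#' composition dataset at each value, classifies the single-species
#' marginal distribution as unimodal or multimodal, and reports the
#' interval over which the classification flips together with its
#' midpoint (the estimated critical interaction strength).
#'
#' @param alphas increasing vector of off-diagonal interaction strengths.
#' @param n_samples samples per dataset.
#' @param seed integer seed (one independent dataset per alpha).
#' @param species which species' marginal to classify.
#' @param ... further overrides passed to [clv_config()].
#' @return a list with `table` (data frame of alpha, n_modes,
#'   classification), `flip_interval`, and `alpha_critical` (midpoint).
#' @export
critical_alpha_sweep <- function(alphas = c(0.6, 0.8, 1.0, 1.2, 1.5, 2.0, 4.0),
                                 n_samples = 2000L, seed = 1L, species = 1L,
                                 ...) {
  alphas <- sort(alphas)
  modes <- integer(length(alphas))
  for (k in seq_along(alphas)) {
    cfg <- clv_config(alpha_offdiag = alphas[k], n_samples = n_samples,
                      seed = seed + k, ...)
    tab <- clv_dataset(cfg)
    modes[k] <- count_abundance_modes(unclass(tab)[, species])
  }
  multi <- modes > 1L
  tbl <- data.frame(alpha = alphas, n_modes = modes,
                    classification = ifelse(multi, "multimodal", "unimodal"))
  flip <- which(!multi[-length(multi)] & multi[-1L])
  if (length(flip) == 0L) {
    return(list(table = tbl, flip_interval = c(NA_real_, NA_real_),
                alpha_critical = NA_real_))
  }
  k <- flip[length(flip)]                # last unimodal -> multimodal flip
  iv <- c(alphas[k], alphas[k + 1L])
  list(table = tbl, flip_interval = iv, alpha_critical = mean(iv))
}
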
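# Shared fixtures, built in code at test time.

# One-cycle schedule (3 segments + 3 breaks, 75 s, 150 frames at 2 fps).
short_schedule <- function() build_default_schedule(cycles = 1)

# Phantom with every stochastic component switched off (each overridable).
quiet_config <- function(jitter_sd = c(tx = 0, ty = 0, theta = 0, scale = 0),
                         noise_sd = 0, roi_fluctuation_sd = 0,
                         drift_per_min = 0, between_subject_sd = 0, ...) {
  phantom_config(jitter_sd = jitter_sd, noise_sd = noise_sd,
                 roi_fluctuation_sd = roi_fluctuation_sd,
                 drift_per_min = drift_per_min,
                 between_subject_sd = between_subject_sd, ...)
}

# Cheap GA settings for tests that assert behaviour, not precision.
fast_ga <- function(seed = 1, population = 30, generations = 25, ...) {
  ga_config(population = population, generations = generations, seed = seed,
            ...)
}

# Small asymmetric warm blob on a cold background; unique registration
# optimum, usable at any size.
blob_frame <- function(n = 16) {
  f <- matrix(27, n, n)
  r <- seq(round(n * 0.3), round(n * 0.75))
  c <- seq(round(n * 0.25), round(n * 0.7))
  f[r, c] <- 30 + outer(seq_along(r), seq_along(c), function(i, j) 0.3 * i + 0.17 * j)
  f
}

# Independent Hotelling T^2 oracle for the two-group MANOVA F.
# T2 = (n1 n2 / N) d' S^-1 d with S the pooled covariance;
# F = (N - k - 1) / ((N - 2) k) * T2 on (k, N - k - 1) df.
hotelling_f <- function(X, g) {
  g <- factor(g)
  stopifnot(nlevels(g) == 2)
  X1 <- X[g == levels(g)[1], , drop = FALSE]
  X2 <- X[g == levels(g)[2], , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2); N <- n1 + n2; k <- ncol(X)
  d <- colMeans(X1) - colMeans(X2)
  S <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) / (N - 2)
  t2 <- (n1 * n2 / N) * drop(t(d) %*% solve(S, d))
  list(f = (N - k - 1) / ((N - 2) * k) * t2, df1 = k, df2 = N - k - 1)
}

# Random two-group feature_matrix for statistical unit tests.
random_block <- function(n1 = 18, n2 = 17, p = 9, seed = 1, shift = 0) {
  withr::with_seed(seed, {
    X <- matrix(rnorm((n1 + n2) * p), n1 + n2, p)
    X[seq_len(n1), ] <- X[seq_len(n1), ] + shift
    thermoface:::new_feature_matrix(
      X, factor(c(rep("moderate", n1), rep("marked", n2)),
                levels = c("moderate", "marked")),
      "forehead", "LVHA")
  })
}
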
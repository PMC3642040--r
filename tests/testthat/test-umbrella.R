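test_that("window seeds are picked at even spacing with boosted subsets", {
  # monotone synthetic path: 120 frames of a single atom moving in x
  xs <- seq(0, 3, length.out = 120)
  traj <- gd_traj(cbind(xs, 0, 0))
  cv <- collective_vector(1L, matrix(c(0, 0, 0), 1), c(1, 0, 0))
  w <- make_windows(traj, cv, n_windows = 39, default_k = 1,
                    boosted_k = 100, boosted_set = c(10, 20, 30),
                    projections = xs)
  expect_equal(nrow(w), 39)
  expect_true(all(diff(w$center) > 0))
  expect_equal(sum(w$k == 100), 3)
  expect_true(all(w$k[-c(10, 20, 30)] == 1))
  # no boosting
  w0 <- make_windows(traj, cv, n_windows = 10, projections = xs)
  expect_true(all(w0$k == 1))
  # degenerate single window at the path midpoint
  w1 <- make_windows(traj, cv, n_windows = 1, projections = xs)
  expect_equal(w1$center, 1.5, tolerance = 0.02)
  expect_error(make_windows(gd_traj(cbind(0:4, 0, 0)), cv,
                            n_windows = 39, projections = 0:4),
               "fewer frames")
})

test_that("window sampling matches the analytic biased minimum", {
  # harmonic landscape (one Gaussian well is locally quadratic at its
  # center; use a wide well so the quadratic term dominates)
  flat <- analytic_landscape(numeric(0), numeric(0), numeric(0),
                             domain = c(-5, 8))
  w <- sample_window(flat, center = 2, k = 25, n_samples = 2e4, seed = 5)
  expect_s3_class(w, "gd_window")
  expect_equal(mean(w$samples), 2, tolerance = 0.02)
  expect_equal(var(w$samples), kT(310) / 25, tolerance = 0.05)
  expect_equal(length(w$samples), 1e4)   # half discarded by default
  # determinism
  w2 <- sample_window(flat, 2, 25, 2e4, seed = 5)
  expect_identical(w$samples, w2$samples)
  expect_error(sample_window(flat, 2, 25, 10,
                             discard_first_fraction = 0.999),
               "no samples")
})

test_that("biased BD window equilibrates at the combined-quadratic mean", {
  # toy: tether to 0 with k1 plus umbrella at s0 with k2 along x of a
  # single bead; minimizer of the quadratic sum is k2 s0 / (k1 + k2)
  k1 <- 100; k2 <- 400; s0 <- 0.6
  en <- list(fn = function(x) 0.5 * k1 * sum(x^2),
             gr = function(x) k1 * x)
  cv <- collective_vector(1L, matrix(0, 1, 3), c(1, 0, 0))
  w <- sample_window(list(energy = en, cv = cv,
                          start = matrix(0, 1, 3), fit = FALSE),
                     center = s0, k = k2, n_samples = 4e4,
                     discard_first_fraction = 0.5, seed = 8, dt = 1e-3)
  expect_equal(mean(w$samples), k2 * s0 / (k1 + k2), tolerance = 0.01)
})

test_that("WHAM recovers a flat landscape and pools identical windows", {
  flat <- analytic_landscape(numeric(0), numeric(0), numeric(0),
                             domain = c(0, 2))
  w <- umbrella_window(1, 0, sample_biased_1d(flat, 0, 0, 4e5, seed = 1))
  p <- wham(list(w), n_bins = 50)
  expect_lt(diff(range(p$free_energy, na.rm = TRUE)), 0.2)
  # two identical windows behave like one window with pooled samples
  p2 <- wham(list(w, w), n_bins = 50)
  pooled <- umbrella_window(1, 0, c(w$samples, w$samples))
  p1 <- wham(list(pooled), n_bins = 50)
  expect_equal(p2$free_energy, p1$free_energy, tolerance = 1e-6)
})

test_that("WHAM is invariant to window order", {
  L <- triple_well_landscape()
  centers <- seq(0, 11, length.out = 12)
  wins <- lapply(seq_along(centers), function(i)
    sample_window(L, centers[i], k = 30, n_samples = 3000,
                  seed = 50 + i))
  p <- wham(wins, n_bins = 80)
  set.seed(1)
  p_perm <- wham(sample(wins), n_bins = 80)
  expect_equal(p_perm$free_energy, p$free_energy, tolerance = 1e-5)
})

test_that("a disjoint window warns and leaves covered bins unchanged", {
  flat <- analytic_landscape(numeric(0), numeric(0), numeric(0),
                             domain = c(0, 30))
  w1 <- umbrella_window(1, 50, sample_biased_1d(flat, 1, 50, 2e4,
                                                seed = 2))
  w2 <- umbrella_window(2, 50, sample_biased_1d(flat, 2, 50, 2e4,
                                                seed = 3))
  far <- umbrella_window(25, 50, sample_biased_1d(flat, 25, 50, 2e4,
                                                  seed = 4))
  # identical bin grids: widths of 0.05 nm over pinned ranges
  p12 <- wham(list(w1, w2), n_bins = 60, range = c(0, 3), tol = 1e-9)
  expect_warning(p_far <- wham(list(w1, w2, far), n_bins = 520,
                               range = c(0, 26), tol = 1e-9),
                 "non-overlapping")
  shared <- match(round(p12$bin_centers, 6),
                  round(p_far$bin_centers, 6))
  ok <- is.finite(p12$free_energy) & !is.na(shared)
  d <- p_far$free_energy[shared[ok]] - p12$free_energy[ok]
  # relative profile over the connected component is unchanged
  expect_lt(diff(range(d, na.rm = TRUE)), 1e-6)
})

test_that("bootstrap errors are reproducible and shrink with sampling", {
  L <- analytic_landscape(c(1, 3), c(8, 6), c(0.7, 0.7),
                          domain = c(-1, 5))
  mk <- function(n) lapply(seq(0, 4, length.out = 8), function(c0)
    sample_window(L, c0, k = 30, n_samples = n,
                  seed = 60 + round(10 * c0)))
  w_small <- mk(1500); w_big <- mk(6000)
  b1 <- bootstrap_pmf(w_small, n_boot = 25, seed = 1, n_bins = 60)
  b1b <- bootstrap_pmf(w_small, n_boot = 25, seed = 1, n_bins = 60)
  expect_identical(b1$se, b1b$se)
  b2 <- bootstrap_pmf(w_big, n_boot = 25, seed = 2, n_bins = 60)
  expect_lt(median(b2$se, na.rm = TRUE), median(b1$se, na.rm = TRUE))
  expect_warning(b0 <- bootstrap_pmf(w_small, n_boot = 0),
                 "zero-length")
  expect_length(b0$se, 0)
})

test_that("state ensembles shade disjoint wells on the toy coordinate", {
  fx <- toy_fixture()
  closed_tr <- run_bd(fx$toy$energy, fx$toy$closed, n_steps = 600,
                      dt = 2e-4, seed = 31, save_every = 3L)
  open_tr <- run_bd(fx$toy$energy, fx$toy$open, n_steps = 600,
                    dt = 2e-4, seed = 32, save_every = 3L)
  sh <- shade_states(NULL, list(closed = closed_tr, open = open_tr),
                     fx$cv)
  expect_equal(nrow(sh), 2)
  cl <- sh[sh$state == "closed", ]; op <- sh[sh$state == "open", ]
  expect_true(cl$min < 0.1 && cl$max > -0.2)  # interval straddles 0
  expect_lt(cl$max, op$min)                   # disjoint
  expect_error(shade_states(NULL, list(closed = numeric(0)), fx$cv),
               "empty")
})
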
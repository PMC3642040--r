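test_that("analytic landscape density normalizes and wells sit as laid out", {
  L <- triple_well_landscape()
  dens <- L$density(310)
  Z <- integrate(dens, L$domain[1], L$domain[2], subdivisions = 2000,
                 rel.tol = 1e-9)$value
  expect_equal(Z, 1, tolerance = 1e-6)
  # closed well deepest; two barriers between the three wells
  s <- seq(L$domain[1], L$domain[2], 0.005)
  U <- L$U(s)
  wells <- vapply(c(1.2, 5.4, 10.1), function(w)
    min(U[abs(s - w) < 1.2]), numeric(1))
  expect_true(wells[1] < wells[2] && wells[1] < wells[3])
  b <- barrier_positions(L)
  expect_length(b, 2)
  expect_equal(b[1], 4, tolerance = 0.35)
  expect_equal(b[2], 9, tolerance = 0.35)
})

test_that("biased rejection sampler matches closed forms", {
  flat <- analytic_landscape(numeric(0), numeric(0), numeric(0),
                             domain = c(-6, 6))
  k <- 10
  s <- sample_biased_1d(flat, s0 = 1.5, k = k, n = 5e4, seed = 1)
  expect_equal(mean(s), 1.5, tolerance = 0.02)
  expect_equal(var(s), kT(310) / k, tolerance = 0.01)
  expect_length(sample_biased_1d(flat, 0, 1, 0), 0)
})

test_that("unbiased sampling reproduces the exact Boltzmann density", {
  L <- analytic_landscape(0, 12, 0.8, domain = c(-4, 4))
  s <- sample_biased_1d(L, 0, 0, n = 1e5, seed = 2)
  dens <- L$density(310)
  cdf <- function(q) vapply(q, function(x)
    integrate(dens, -4, x, subdivisions = 2000)$value, numeric(1))
  ks <- ks.test(s, cdf)
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("Brownian dynamics samples the harmonic stationary variance", {
  k <- 20; dt <- 0.001
  en <- list(fn = function(x) 0.5 * k * sum(x^2),
             gr = function(x) k * x)
  tr <- run_bd(en, matrix(0, 1, 3), n_steps = 5e5, dt = dt,
               temperature = 310, seed = 1)
  v <- mean(apply(tr$xyz, 2, var))
  # Euler-Maruyama inflates the variance by 1/(1 - k dt / 2), ~1 % here
  expect_equal(v, kT(310) / k, tolerance = 0.05)
})

test_that("zero-temperature BD is gradient descent to the minimum", {
  fx <- toy_fixture()
  set.seed(3)
  x0 <- fx$toy$closed$xyz + matrix(rnorm(3 * n_atoms(fx$toy$closed),
                                         sd = 0.03), ncol = 3)
  tr <- run_bd(fx$toy$energy, x0, n_steps = 3000, dt = 5e-4,
               temperature = 0)
  xf <- traj_frame(tr, n_frames(tr))
  expect_lt(rmsd(xf, fx$toy$closed$xyz, fit = FALSE), 1e-8)
})

test_that("BD trajectories are reproducible by seed and diverge on huge dt", {
  en <- list(fn = function(x) 0.5 * 20 * sum(x^2),
             gr = function(x) 20 * x)
  t1 <- run_bd(en, matrix(1, 2, 3), 500, seed = 9)
  t2 <- run_bd(en, matrix(1, 2, 3), 500, seed = 9)
  expect_identical(t1$xyz, t2$xyz)
  expect_error(run_bd(en, matrix(1, 2, 3), 5000, dt = 1,
                      temperature = 0), "diverged")
})

test_that("toy channel endpoints are C4 symmetric with a wider open gate", {
  fx <- toy_fixture()
  Rz <- rotation_matrix(c(0, 0, 1), pi / 2)
  c4op <- function(x, atoms) {
    rot <- x %*% t(Rz)
    perm <- order(match(atoms$chain_id, c("D", "A", "B", "C")),
                  atoms$serial)
    rot[perm, ]
  }
  for (m in list(fx$toy$closed, fx$toy$open))
    expect_lt(max(abs(c4op(m$xyz, m$atoms) - m$xyz)), 1e-8)
  # energy invariant under the C4 operation applied to any configuration
  set.seed(5)
  x <- fx$toy$closed$xyz + matrix(rnorm(3 * n_atoms(fx$toy$closed),
                                        sd = 0.1), ncol = 3)
  expect_equal(fx$toy$energy$fn(c4op(x, fx$toy$closed$atoms)),
               fx$toy$energy$fn(x), tolerance = 1e-9)
  gate <- function(m) opposite_distance(m, residue_seq = 112L)$mean_ang
  expect_lt(gate(fx$toy$closed), gate(fx$toy$open))
})

test_that("endpoint geometries are the two minima of the blended energy", {
  fx <- toy_fixture()
  set.seed(4)
  for (i in 1:10) {
    start <- if (i %% 2 == 0) fx$toy$closed$xyz else fx$toy$open$xyz
    x0 <- start + matrix(rnorm(length(start), sd = 0.02), ncol = 3)
    tr <- run_bd(fx$toy$energy, x0, n_steps = 3000, dt = 5e-4,
                 temperature = 0)
    xf <- traj_frame(tr, n_frames(tr))
    d_c <- rmsd(xf, fx$toy$closed$xyz, fit = FALSE)
    d_o <- rmsd(xf, fx$toy$open$xyz, fit = FALSE)
    expect_lt(min(d_c, d_o), 1e-6)
  }
  # closed basin deeper than open by construction
  expect_lt(fx$toy$energy$fn(fx$toy$closed$xyz),
            fx$toy$energy$fn(fx$toy$open$xyz))
})

test_that("dihedral traces follow the two-state Markov chain", {
  # absorbing up state
  tr <- gen_dihedral_trace(0, 0.5, n_steps = 500, seed = 1, start = "up")
  expect_true(all(tr$states == "up"))
  expect_true(all(abs(tr$angles - (-63.5)) < 60))
  # symmetric rates: occupancy 50 % within binomial error
  tr2 <- gen_dihedral_trace(0.05, 0.05, n_steps = 2e4, seed = 2)
  p_up <- mean(tr2$states == "up")
  # effective sample size ~ n / (2/p_switch); generous 5-sigma band
  expect_lt(abs(p_up - 0.5), 0.05)
  # reproducibility
  tr3 <- gen_dihedral_trace(0.05, 0.05, n_steps = 2e4, seed = 2)
  expect_identical(tr2$angles, tr3$angles)
  expect_error(gen_dihedral_trace(1.5, 0), "p_up_to_down")
})

test_that("angles wrap to the (-180, 180] convention", {
  expect_equal(wrap_angle(c(-184, 190, 360, -360, 180, -180)),
               c(176, -170, 0, 0, 180, 180))
})
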
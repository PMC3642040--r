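test_that("dihedral angles match analytic constructions", {
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)),
               0)
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                        c(-1, 1, 0)), 180)
  for (target in c(-63.5, -175.5, 37, 120)) {
    a <- target * pi / 180
    p4 <- c(cos(a), 1, sin(a))
    expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), p4),
                 target, tolerance = 1e-6)
  }
})

test_that("chi1 reads the N-CA-CB-CG dihedral off a built residue", {
  target <- -63.5; a <- target * pi / 180
  atoms <- data.frame(serial = 1:4,
                      atom_name = c("N", "CA", "CB", "CG"),
                      residue_name = "PHE", residue_seq = 103L,
                      chain_id = "A",
                      element = c("N", "C", "C", "C"))
  xyz <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
               c(cos(a), 1, sin(a)))
  m <- gd_structure(atoms, xyz)
  expect_equal(chi1(m, chain_id = "A", residue_seq = 103L), target,
               tolerance = 1e-6)
  # chi1 invariant under rigid motion
  Rr <- rotation_matrix(c(2, -1, 0.5), 1.1)
  m2 <- gd_structure(atoms, sweep(xyz %*% t(Rr), 2, c(1, 2, 3), `+`))
  expect_equal(chi1(m2, chain_id = "A", residue_seq = 103L), target,
               tolerance = 1e-6)
  # missing gamma atom: NaN with warning
  m3 <- gd_structure(atoms[1:3, ], xyz[1:3, ])
  expect_warning(v <- chi1(m3, chain_id = "A", residue_seq = 103L),
                 "lacks atom")
  expect_true(is.nan(v))
})

test_that("rotamer classifier reproduces the printed range semantics", {
  expect_equal(classify_rotamer(-70), "up")
  expect_equal(classify_rotamer(-63.5), "up")
  expect_equal(classify_rotamer(-180), "down")
  expect_equal(classify_rotamer(176), "down")   # wrap of -184
  expect_equal(classify_rotamer(-120), "unassigned")
  expect_equal(classify_rotamer(-120, mode = "nearest"), "down")
  # strict and nearest agree everywhere inside the printed ranges
  inside <- c(seq(-72, -55, 0.5), seq(-180, -166, 0.5), seq(175, 180, 0.5))
  expect_identical(classify_rotamer(inside),
                   classify_rotamer(inside, mode = "nearest"))
})

test_that("state fractions recover Markov occupancy and edge cases", {
  up_all <- rep("up", 50)
  fr <- state_fractions(list(up_all, up_all))
  expect_true(all(fr$pct_up == 100))
  mixed <- state_fractions(list(rep("up", 4), rep("up", 4),
                                rep("up", 4), rep("down", 4)))
  expect_true(all(mixed$pct_up == 75) && all(mixed$pct_down == 25))
  # generated two-state chains: stationary occupancy p_du/(p_ud + p_du)
  p_ud <- 0.02; p_du <- 0.01
  traces <- lapply(1:8, function(i)
    gen_dihedral_trace(p_ud, p_du, n_steps = 4000, seed = 70 + i)$angles)
  fr2 <- state_fractions(traces, mode = "nearest")
  occ <- mean(fr2$pct_up) / 100
  expect_equal(occ, p_du / (p_ud + p_du), tolerance = 0.06)
  expect_error(state_fractions(list()), "no rotamer traces")
  expect_error(state_fractions(list(rep("up", 3), rep("up", 4))),
               "time grid")
})

test_that("opposite distances follow square geometry and symmetry", {
  atoms <- data.frame(serial = 1:4, atom_name = "CA",
                      residue_name = "THR", residue_seq = 112L,
                      chain_id = c("A", "B", "C", "D"), element = "C")
  sq <- gd_structure(atoms, rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                  c(0, 1, 0)))
  d <- opposite_distance(sq, residue_seq = 112L)
  expect_equal(d$d_ac, sqrt(2) * 10, tolerance = 1e-9)
  expect_equal(d$d_bd, sqrt(2) * 10, tolerance = 1e-9)
  expect_error(opposite_distance(sq, residue_seq = 50L), "missing")
})

test_that("gate distance grows monotonically during a toy opening", {
  fx <- toy_fixture()
  prot <- ed_protocol(fx$cv, n_steps = 1200, success_rmsd = 0.2)
  run <- run_ed(fx$toy$energy, fx$toy$closed, prot,
                reference = fx$toy$open, temperature = 0,
                save_every = 60L)
  g <- vapply(seq_len(n_frames(run$traj)), function(i)
    opposite_distance(traj_frame(run$traj, i), fx$toy$closed$atoms,
                      residue_seq = 112L)$mean_ang, numeric(1))
  # driven phase: monotone increase (zero-temperature, so no noise)
  expect_true(all(diff(g[1:13]) > -1e-6))
  expect_gt(g[length(g)] - g[1], 10)
})

test_that("hydrogen-bond counting applies both geometric cutoffs", {
  lin <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.29, 0, 0))
  expect_equal(hbond_count(lin, matrix(c(1, 2), 1), 3), 1L)
  far <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.40, 0, 0))
  expect_equal(hbond_count(far, matrix(c(1, 2), 1), 3), 0L)
  bent <- rbind(c(0, 0, 0),
                0.1 * c(cos(pi / 3), sin(pi / 3), 0),
                c(0.30, 0, 0))
  expect_equal(hbond_count(bent, matrix(c(1, 2), 1), 3), 0L)
  expect_warning(n0 <- hbond_count(lin, matrix(integer(0), 0, 2), 3),
                 "empty")
  expect_equal(n0, 0L)
  # symmetric under relabeling of equivalent donors
  two <- rbind(lin, lin + rep(c(0, 1, 0), each = 3))
  d2 <- matrix(c(1, 2, 4, 5), 2, byrow = TRUE)
  expect_equal(hbond_count(two, d2, c(3, 6)),
               hbond_count(two, d2[2:1, ], c(6, 3)))
})

test_that("RMSD time series report Angstroms against a fixed reference", {
  fx <- toy_fixture()
  ref <- fx$toy$closed
  const <- gd_traj(rbind(as.vector(t(ref$xyz)), as.vector(t(ref$xyz))))
  s <- rmsd_timeseries(const, ref)
  expect_equal(s, c(0, 0), tolerance = 1e-10)
  avg <- rmsd_replica_average(list(c(1, 2), c(3, 4)))
  expect_equal(avg$mean, c(2, 3))
  expect_equal(avg$sd, c(sd(c(1, 3)), sd(c(2, 4))))
})
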
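test_that("Kabsch fit recovers a known rigid transform", {
  set.seed(42)
  ref <- matrix(rnorm(30), 10, 3)
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  t <- c(0.4, -1.1, 2.0)
  mobile <- sweep(ref %*% t(R), 2, t, `+`)
  fit <- kabsch_fit(mobile, ref)
  expect_lt(max(abs(fit$coords - ref)), 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_lt(fit$rmsd, 1e-8)
  # identity case
  fit0 <- kabsch_fit(ref, ref)
  expect_lt(max(abs(fit0$rotation - diag(3))), 1e-10)
})

test_that("degenerate fit sets are refused", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line), "collinear")
  expect_error(kabsch_fit(matrix(rnorm(6), 2, 3),
                          matrix(rnorm(6), 2, 3)), "at least 3")
})

test_that("rmsd is symmetric, translation-invariant, and matches bio3d", {
  set.seed(7)
  a <- matrix(rnorm(60), 20, 3)
  b <- a + matrix(rnorm(60, sd = 0.1), 20, 3)
  expect_equal(rmsd(a, b), rmsd(b, a), tolerance = 1e-12)
  expect_lt(rmsd(a, sweep(a, 2, c(1, 2, 3), `+`)), 1e-12)
  expect_equal(rmsd(a, a), 0)
  expect_error(rmsd(a, b, indices = integer(0)), "empty")
  # independent cross-check of the superposed RMSD
  ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
  expect_equal(rmsd(a, b), ref, tolerance = 2e-3)  # bio3d rounds to 3 dp
})

test_that("two-conformation covariance PCA has rank one", {
  fx <- toy_fixture()
  idx <- resolve_selection(fx$toy$closed, fx$toy$selection)
  two <- gd_traj(rbind(as.vector(t(fx$toy$closed$xyz)),
                       as.vector(t(fx$toy$open$xyz))))
  pca <- covariance_pca(two, idx)
  expect_equal(pca_rank(pca$values, tol = 1e-10), 1)
  # leading mode parallel to the normalized fitted difference
  xc <- fx$toy$closed$xyz[idx, ]
  xo <- kabsch_fit(fx$toy$open$xyz, fx$toy$closed$xyz, idx)$coords[idx, ]
  d <- as.vector(t(xo - xc)); d <- d / sqrt(sum(d^2))
  cosang <- abs(sum(pca$vectors[, 1] * d))
  expect_gt(cosang, 1 - 1e-8)
  # repeated frames do not raise the rank
  rep5 <- gd_traj(rbind(matrix(rep(as.vector(t(fx$toy$closed$xyz)), 5),
                               5, byrow = TRUE),
                        as.vector(t(fx$toy$open$xyz))))
  expect_equal(pca_rank(covariance_pca(rep5, idx)$values), 1)
  expect_error(covariance_pca(gd_traj(matrix(0, 1, 9)), 1:3), "2 frames")
})

test_that("difference eigenvector projects end states to 0 and |dx|", {
  fx <- toy_fixture()
  cv <- fx$cv
  L <- attr(cv, "path_length")
  expect_equal(sqrt(sum(cv$direction^2)), 1, tolerance = 1e-10)
  expect_lt(abs(project_cv(fx$toy$closed$xyz, cv)), 1e-9)
  expect_equal(project_cv(fx$toy$open$xyz, cv), L, tolerance = 1e-9)
  # midpoint projects to L/2 (linearity)
  mid <- (fx$toy$closed$xyz + fx$toy$open$xyz) / 2
  expect_equal(project_cv(mid, cv), L / 2, tolerance = 1e-8)
  # swapping the end states mirrors the coordinate
  cv_rev <- build_difference_ev(fx$toy$open, fx$toy$closed,
                                fx$toy$selection)
  expect_equal(project_cv(fx$toy$closed$xyz, cv_rev),
               attr(cv_rev, "path_length"), tolerance = 1e-9)
  expect_equal(max(abs(cv_rev$direction + cv$direction)), 0,
               tolerance = 1e-9)
})

test_that("subunit-restricted coordinates live on the driven chains", {
  fx <- toy_fixture()
  sp <- selection_spec(segments = fx$toy$selection$segments,
                       backbone_atoms = "CA", chains = c("A", "B"))
  cv <- build_difference_ev(fx$toy$closed, fx$toy$open, sp)
  on_chains <- fx$toy$closed$atoms$chain_id[cv$atom_indices]
  expect_true(all(on_chains %in% c("A", "B")))
  expect_lt(attr(cv, "path_length"), attr(fx$cv, "path_length"))
})

test_that("projection is invariant to rigid motion and orthogonal moves", {
  fx <- toy_fixture()
  cv <- fx$cv
  x <- fx$toy$closed$xyz
  set.seed(11)
  for (i in 1:5) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, pi))
    t <- rnorm(3)
    moved <- sweep(x %*% t(R), 2, t, `+`)
    expect_equal(project_cv(moved, cv), project_cv(x, cv),
                 tolerance = 1e-8)
  }
  # displacement orthogonal to the direction leaves projection unchanged
  set.seed(12)
  w <- rnorm(length(cv$direction))
  w <- w - sum(w * cv$direction) * cv$direction
  xo <- x
  xo[cv$atom_indices, ] <- xo[cv$atom_indices, ] +
    0.01 * matrix(w, ncol = 3, byrow = TRUE)
  expect_equal(project_cv(xo, cv, fit = FALSE),
               project_cv(x, cv, fit = FALSE), tolerance = 1e-8)
})

test_that("collective vectors survive a serialization round trip", {
  fx <- toy_fixture()
  f <- withr::local_tempfile(fileext = ".txt")
  write_cv(fx$cv, f)
  cv2 <- read_cv(f)
  expect_equal(cv2$direction, fx$cv$direction, tolerance = 1e-12)
  expect_equal(cv2$reference_coords, fx$cv$reference_coords,
               tolerance = 1e-12)
  expect_identical(cv2$atom_indices, fx$cv$atom_indices)
  expect_equal(attr(cv2, "path_length"), attr(fx$cv, "path_length"),
               tolerance = 1e-12)
  expect_equal(project_cv(fx$toy$open$xyz, cv2),
               project_cv(fx$toy$open$xyz, fx$cv), tolerance = 1e-10)
})

test_that("mismatched end-state atoms are reported", {
  fx <- toy_fixture()
  open2 <- fx$toy$open
  open2$atoms$residue_seq[1] <- 49L   # break the match
  expect_error(build_difference_ev(fx$toy$closed, open2,
                                   fx$toy$selection), "do not match")
})
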